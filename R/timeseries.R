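#' Component time-series container
#'
#' Holds a T x C matrix of network component signals together with the
#' repetition time (TR, seconds) of the acquisition.
#'
#' @param values Numeric T x C matrix (T time points, C components).
#' @param tr_seconds Repetition time in seconds (default 2.4).
#' @param component_names Optional component names; defaults to IC1..ICC.
#' @return Object of class \code{component_ts}.
#' @export
component_ts <- function(values, tr_seconds = 2.4, component_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 time points")
  if (anyNA(values)) stop("missing values not allowed")
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (is.null(component_names))
    component_names <- colnames(values) %||% paste0("IC", seq_len(ncol(values)))
  colnames(values) <- component_names
  structure(list(values = values, tr_seconds = tr_seconds,
                 component_names = component_names),
            class = "component_ts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.component_ts <- function(x, ...) {
  cat("Component time series:", nrow(x$values), "time points x",
      ncol(x$values), "components, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

# accept either a component_ts or a bare matrix (default TR)
as_component_ts <- function(x, tr_seconds = 2.4) {
  if (inherits(x, "component_ts")) x else component_ts(x, tr_seconds)
}

#' Expand a window-level state sequence to TR resolution
#'
#' The simulator draws its hidden state sequence at window resolution (one
#' label per sliding window the dFNC stage will produce). Each TR is assigned
#' the label of the window whose center lies nearest to it (ties toward the
#' earlier window): TR t gets the label of window
#' min(max(1, t - floor((W - 1) / 2)), Nw). This center alignment makes the
#' ground-truth label of window w govern the TRs its taper actually weights
#' most, so generator truth is directly comparable to pipeline output.
#'
#' @param seq Integer window-level state labels (length Nw).
#' @param n_timepoints Number of TRs T; must satisfy T = Nw + W under the
#'   window-count convention Nw = T - W.
#' @param window_length Window length W in TRs (default 18).
#' @return Integer vector of length \code{n_timepoints}.
#' @export
expand_state_sequence <- function(seq, n_timepoints, window_length = 18) {
  nw <- length(seq)
  if (n_timepoints != nw + window_length)
    stop("sequence length ", nw, " does not match T = ", n_timepoints,
         " under the Nw = T - W convention (expected Nw = ",
         n_timepoints - window_length, ")")
  offset <- (window_length - 1L) %/% 2L
  idx <- pmin(pmax(seq_len(n_timepoints) - offset, 1L), nw)
  seq[idx]
}

#' Simulate component time courses from a hidden state sequence
#'
#' At each TR, draws a C-vector from a zero-mean Gaussian whose correlation
#' matrix is the active state's archetype, then smooths temporally with an
#' AR(1) recursion whose innovations are rescaled so the stationary marginal
#' keeps unit variance.
#'
#' @param seq Window-level state sequence (integer labels indexing
#'   \code{archetypes}).
#' @param archetypes List of C x C correlation matrices (one per state).
#' @param n_timepoints Number of TRs T to generate.
#' @param window_length Window length W used for sequence expansion.
#' @param ar_coefficient AR(1) coefficient in [0, 1) (default 0.3).
#' @param seed Integer seed.
#' @param tr_seconds Repetition time (default 2.4 s).
#' @return A \code{\link{component_ts}}.
#' @export
sample_component_timeseries <- function(seq, archetypes, n_timepoints,
                                        window_length = 18,
                                        ar_coefficient = 0.3, seed,
                                        tr_seconds = 2.4) {
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must be in [0, 1)")
  if (max(seq) > length(archetypes))
    stop("sequence labels exceed the number of archetypes")
  if (!missing(seed)) set.seed(as.integer(seed))
  tr_labels <- expand_state_sequence(seq, n_timepoints, window_length)
  C <- nrow(archetypes[[1]])
  chols <- lapply(archetypes, function(M) chol(M + 1e-10 * diag(C)))
  Z <- matrix(stats::rnorm(n_timepoints * C), n_timepoints, C)
  X <- matrix(0, n_timepoints, C)
  innov_scale <- sqrt(1 - ar_coefficient^2)
  X[1, ] <- Z[1, ] %*% chols[[tr_labels[1]]]
  for (t in 2:n_timepoints) {
    X[t, ] <- ar_coefficient * X[t - 1, ] +
      innov_scale * (Z[t, ] %*% chols[[tr_labels[t]]])
  }
  colnames(X) <- colnames(archetypes[[1]]) %||% paste0("IC", seq_len(C))
  component_ts(X, tr_seconds)
}

#' Simulate a six-parameter head-motion trace
#'
#' Produces a T x 6 matrix (3 translations in mm, 3 rotations in degrees)
#' composed of a smooth random-walk drift plus sparse spikes, emulating
#' realignment parameter files.
#'
#' @param n_timepoints Number of TRs (>= 1).
#' @param drift_scale SD of the per-step random-walk increment (mm or deg).
#' @param spike_probability Per-sample probability of a motion spike.
#' @param spike_scale SD of spike amplitude (mm or deg).
#' @param seed Integer seed.
#' @return T x 6 numeric matrix with columns \code{trans_x_mm},
#'   \code{trans_y_mm}, \code{trans_z_mm}, \code{rot_x_deg}, \code{rot_y_deg},
#'   \code{rot_z_deg}.
#' @export
sample_motion_trace <- function(n_timepoints, drift_scale = 0.02,
                                spike_probability = 0.005, spike_scale = 0.5,
                                seed) {
  stopifnot(n_timepoints >= 1, drift_scale >= 0, spike_scale >= 0,
            spike_probability >= 0, spike_probability <= 1)
  if (!missing(seed)) set.seed(as.integer(seed))
  M <- sapply(1:6, function(j) {
    drift <- cumsum(stats::rnorm(n_timepoints, sd = drift_scale))
    spikes <- stats::rbinom(n_timepoints, 1, spike_probability) *
      stats::rnorm(n_timepoints, sd = spike_scale)
    drift + spikes
  })
  M <- matrix(M, nrow = n_timepoints)
  # realignment is relative to the first volume
  M <- sweep(M, 2, M[1, ])
  colnames(M) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                   "rot_x_deg", "rot_y_deg", "rot_z_deg")
  M
}
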