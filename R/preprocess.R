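#' Motion quality control
#'
#' Flags a session whose head motion, measured relative to the first time
#' point (the realignment reference), exceeds the exclusion thresholds:
#' more than 3 mm of translation or 1.5 degrees of rotation.
#'
#' @param trace T x 6 motion matrix (columns 1-3 translations in mm,
#'   4-6 rotations in degrees).
#' @param max_translation_mm Translation limit (default 3).
#' @param max_rotation_deg Rotation limit (default 1.5).
#' @return List with \code{passed}, \code{max_translation_mm},
#'   \code{max_rotation_deg} and \code{reason}.
#' @export
motion_qc <- function(trace, max_translation_mm = 3, max_rotation_deg = 1.5) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)")
  rel <- sweep(trace, 2, trace[1, ])
  max_trans <- max(abs(rel[, 1:3]))
  max_rot <- max(abs(rel[, 4:6]))
  trans_fail <- max_trans > max_translation_mm
  rot_fail <- max_rot > max_rotation_deg
  reason <- if (trans_fail && rot_fail) {
    sprintf("translation %.2f mm > %g mm; rotation %.2f deg > %g deg",
            max_trans, max_translation_mm, max_rot, max_rotation_deg)
  } else if (trans_fail) {
    sprintf("translation %.2f mm exceeds %g mm", max_trans, max_translation_mm)
  } else if (rot_fail) {
    sprintf("rotation %.2f deg exceeds %g deg", max_rot, max_rotation_deg)
  } else ""
  list(passed = !(trans_fail || rot_fail),
       max_translation_mm = max_trans,
       max_rotation_deg = max_rot,
       reason = reason)
}

#' Polynomial detrending
#'
#' Removes a least-squares polynomial of the given order from each component.
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix).
#' @param polynomial_order Order of the removed polynomial (default 1,
#'   i.e. linear trend plus intercept).
#' @return A \code{component_ts} of residuals.
#' @export
detrend <- function(ts, polynomial_order = 1) {
  if (polynomial_order < 0) stop("polynomial_order must be >= 0")
  ts <- as_component_ts(ts)
  X <- ts$values
  n <- nrow(X)
  if (n <= polynomial_order + 1) stop("series too short for this order")
  t_sc <- seq(-1, 1, length.out = n)
  basis <- outer(t_sc, 0:polynomial_order, "^")
  fit <- qr(basis)
  res <- X - basis %*% qr.coef(fit, X)
  component_ts(res, ts$tr_seconds, ts$component_names)
}

# running median over a centered window of half-width h (shrunk at edges)
running_median <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Despiking by running median and MAD
#'
#' Replaces samples that deviate from the local running median by more than
#' \code{mad_threshold} robust SDs (1.4826 x local MAD) with the running
#' median. Windows whose local MAD is zero fall back to the global robust
#' SD; if that is also zero, any nonzero deviation from the running median
#' counts as a spike (it is infinitely many robust SDs away).
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix).
#' @param window_half_width Half-width of the local window (default 5, i.e.
#'   an 11-sample window).
#' @param mad_threshold Number of robust SDs beyond which a sample is a spike
#'   (default 4).
#' @return Despiked \code{component_ts}.
#' @export
despike <- function(ts, window_half_width = 5, mad_threshold = 4) {
  ts <- as_component_ts(ts)
  X <- ts$values
  n <- nrow(X)
  if (n <= 2 * window_half_width) stop("series too short for despiking window")
  h <- window_half_width
  out <- apply(X, 2, function(x) {
    med <- running_median(x, h)
    dev <- abs(x - med)
    local_sd <- vapply(seq_len(n), function(i) {
      w <- x[max(1, i - h):min(n, i + h)]
      1.4826 * stats::median(abs(w - stats::median(w)))
    }, numeric(1))
    global_sd <- 1.4826 * stats::median(abs(x - stats::median(x)))
    sd_use <- ifelse(local_sd > 0, local_sd, global_sd)
    spike <- ifelse(sd_use > 0, dev > mad_threshold * sd_use, dev > 0)
    x[spike] <- med[spike]
    x
  })
  component_ts(out, ts$tr_seconds, ts$component_names)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and then reversed (zero net
#' phase shift, DC gain 1), with reflective edge padding to suppress
#' transients.
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix; TR then 2.4 s).
#' @param cutoff_hz High-frequency cutoff (default 0.15 Hz); must be below
#'   the Nyquist frequency 1/(2 TR).
#' @param order Filter order (default 5).
#' @return Filtered \code{component_ts}.
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.15, order = 5) {
  ts <- as_component_ts(ts)
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff %.4g Hz is not below Nyquist %.4g Hz",
                 cutoff_hz, nyquist))
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  pad <- 3 * order
  X <- ts$values
  n <- nrow(X)
  if (pad >= n) pad <- n - 1
  # filtering x - x[1] with zero initial state is exact for the constant
  # component (DC gain 1), so start-up transients come only from the
  # fluctuating part, which the reflective padding absorbs
  run <- function(x) {
    as.numeric(signal::filter(bf, x - x[1])) + x[1]
  }
  out <- apply(X, 2, function(x) {
    # reflect about the end points, filter forward then backward
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- run(xp)
    y <- rev(run(rev(y)))
    y[(pad + 1):(pad + n)]
  })
  component_ts(out, ts$tr_seconds, ts$component_names)
}

#' Temporal normalization
#'
#' Standardises each component time course to zero mean and unit standard
#' deviation.
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix).
#' @return Normalised \code{component_ts}.
#' @export
temporal_normalize <- function(ts) {
  ts <- as_component_ts(ts)
  X <- ts$values
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance component(s): ",
         paste(ts$component_names[sds == 0], collapse = ", "))
  out <- scale(X)
  attr(out, "scaled:center") <- attr(out, "scaled:scale") <- NULL
  component_ts(out, ts$tr_seconds, ts$component_names)
}

#' Regress head-motion parameters out of the component signals
#'
#' Per component, returns the ordinary least-squares residual after
#' projecting out the six motion columns plus an intercept. Rank-deficient
#' designs are handled by a pivoted QR (warning, not an error).
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix).
#' @param trace T x 6 motion matrix matching the series length.
#' @return Residual \code{component_ts}.
#' @export
regress_motion <- function(ts, trace) {
  ts <- as_component_ts(ts)
  trace <- as.matrix(trace)
  if (nrow(trace) != nrow(ts$values))
    stop("motion trace and time series lengths differ")
  D <- cbind(1, trace)
  fit <- qr(D)
  if (fit$rank < ncol(D))
    warning("rank-deficient motion design; using pivoted least squares")
  res <- qr.resid(fit, ts$values)
  component_ts(res, ts$tr_seconds, ts$component_names)
}

#' Full time-course post-processing chain
#'
#' Runs detrending, despiking, low-pass filtering and temporal
#' normalization in that order. Motion regression is applied separately at
#' the connectivity-estimation boundary (see
#' \code{\link{compute_subject_dfnc}}).
#'
#' @param ts A \code{\link{component_ts}} (or plain matrix).
#' @param polynomial_order Detrending order (default 1).
#' @param window_half_width,mad_threshold Despiking parameters.
#' @param cutoff_hz,filter_order Low-pass parameters (defaults 0.15 Hz,
#'   order 5).
#' @return Processed \code{component_ts}.
#' @export
preprocess_timeseries <- function(ts, polynomial_order = 1,
                                  window_half_width = 5, mad_threshold = 4,
                                  cutoff_hz = 0.15, filter_order = 5) {
  ts <- as_component_ts(ts)
  ts <- detrend(ts, polynomial_order)
  ts <- despike(ts, window_half_width, mad_threshold)
  ts <- lowpass_filter(ts, cutoff_hz, filter_order)
  temporal_normalize(ts)
}
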