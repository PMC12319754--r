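#' Enumerate sliding-window start indices
#'
#' Windows of length \code{W} TRs are advanced in steps of \code{step} TRs.
#' At step 1 the convention is \code{Nw = T - W} windows (the taper's
#' Gaussian tails extend one step past the rectangle, consuming the final
#' start), which yields 182 windows for the canonical 200-volume, 18-TR
#' configuration.
#'
#' @param n_timepoints Series length T.
#' @param window_length Window length W in TRs (default 18).
#' @param step Step in TRs (default 1).
#' @return Integer vector of 1-based start indices; window i covers
#'   \code{[start_i, start_i + W - 1]}.
#' @export
#' @examples
#' length(enumerate_windows(200, 18, 1))  # 182
enumerate_windows <- function(n_timepoints, window_length = 18, step = 1) {
  if (n_timepoints <= window_length) stop("series shorter than window")
  if (step < 1) stop("step must be >= 1")
  last_start <- n_timepoints - window_length   # leaves one TR of headroom
  seq.int(1L, last_start, by = step)
}

#' Build a tapered window (rectangle convolved with a Gaussian)
#'
#' The rectangular window of width \code{W} is convolved with a discrete
#' Gaussian of standard deviation \code{sigma_tr} TRs (truncated at four
#' sigma), producing smooth tapered weights that down-weight samples near the
#' window edges. Weights are normalised to sum to 1.
#'
#' @param window_length Rectangle width W in TRs (default 18).
#' @param sigma_tr Gaussian standard deviation in TRs (default 2).
#' @return Object of class \code{taper}: list with \code{weights} (length
#'   \code{W + 2 * ceiling(4 sigma)}), \code{window_length}, \code{sigma_tr}
#'   and \code{pad} (samples the taper extends beyond the rectangle on each
#'   side).
#' @export
make_taper <- function(window_length = 18, sigma_tr = 2) {
  stopifnot(window_length >= 2, sigma_tr > 0)
  pad <- ceiling(4 * sigma_tr)
  kern <- stats::dnorm(seq(-pad, pad), sd = sigma_tr)
  rect <- rep(1, window_length)
  w <- stats::convolve(c(rect, rep(0, 2 * pad)), rev(kern), type = "open")
  w <- w[seq_len(window_length + 2 * pad)]
  w <- pmax(w, 0)
  w <- w / sum(w)
  structure(list(weights = w, window_length = window_length,
                 sigma_tr = sigma_tr, pad = pad), class = "taper")
}

#' Weighted (tapered) covariance of a window segment
#'
#' Computes the weighted covariance
#' S = sum_t w_t (x_t - xbar_w)(x_t - xbar_w)' / (1 - sum_t w_t^2)
#' with weighted mean xbar_w, the weighted analogue of the unbiased sample
#' covariance.
#'
#' @param segment n x C matrix of samples in the window.
#' @param weights Nonnegative weights of length n summing to 1.
#' @return C x C symmetric PSD covariance matrix.
#' @export
tapered_covariance <- function(segment, weights) {
  segment <- as.matrix(segment)
  if (length(weights) != nrow(segment))
    stop("segment and weight lengths differ")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  denom <- 1 - sum(weights^2)
  if (denom <= 1e-12) stop("degenerate window: single effective sample")
  xbar <- colSums(segment * weights)
  Xc <- sweep(segment, 2, xbar)
  S <- crossprod(Xc * sqrt(weights)) / denom
  (S + t(S)) / 2
}

#' Graphical lasso: L1-penalized precision estimation
#'
#' Maximises log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
#' by block coordinate descent on the covariance estimate (the standard
#' graphical-lasso algorithm): each column's off-diagonal block is updated by
#' an L1-penalized regression solved with coordinate descent. The diagonal is
#' unpenalised.
#'
#' @param S Symmetric covariance matrix with positive diagonal.
#' @param lambda L1 penalty on off-diagonal precision entries (default 0.1).
#' @param max_iterations Maximum outer sweeps (default 200).
#' @param tolerance Convergence tolerance on the average absolute change of
#'   the covariance estimate (default 1e-8, relative to mean |off-diag S|).
#' @param warm Optional warm start: the value returned by a previous call on
#'   a nearby covariance (used by \code{\link{compute_subject_dfnc}}, where
#'   consecutive windows overlap almost entirely).
#' @return List with \code{precision} (Theta), \code{covariance} (its
#'   inverse, the regularized covariance), \code{iterations},
#'   \code{converged} and the internal regression coefficients \code{beta}
#'   reused for warm starts.
#' @export
graphical_lasso <- function(S, lambda = 0.1, max_iterations = 200,
                            tolerance = 1e-8, warm = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S)))
    stop("S must be symmetric")
  if (any(diag(S) <= 0)) stop("S must have positive diagonal")
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    Theta <- solve(S)
    return(list(precision = (Theta + t(Theta)) / 2, covariance = S,
                iterations = 0L, converged = TRUE, beta = NULL))
  }
  # diagonal is unpenalised, so diag(W) = diag(S) throughout; only the
  # regression coefficients are warm-started (a stale covariance estimate
  # from a neighbouring window can make the subproblems indefinite)
  B0 <- if (!is.null(warm) && !is.null(warm$beta) && nrow(warm$beta) == p) {
    warm$beta
  } else {
    matrix(0, p, p)
  }
  res <- glasso_cd(S, lambda, as.integer(max_iterations), tolerance, S, B0)
  if (!res$converged && !all(B0 == 0))   # retry cold before giving up
    res <- glasso_cd(S, lambda, as.integer(max_iterations), tolerance, S,
                     matrix(0, p, p))
  if (!res$converged)
    stop("graphical lasso did not converge in ", max_iterations, " sweeps")
  W <- (res$covariance + t(res$covariance)) / 2
  list(precision = res$precision, covariance = W,
       iterations = res$iterations, converged = TRUE, beta = res$beta)
}

#' Fisher z-transformation
#'
#' z = atanh(r), applied after clipping correlations to +/- 0.999999 so the
#' output stays finite.
#'
#' @param r Correlation value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -0.999999), 0.999999))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Fixed row-major pair order (1-2, 1-3, ..., 1-C, 2-3, ..., (C-1)-C),
#' matching the 21 IC-pair features for C = 7.
#'
#' @param M Symmetric C x C matrix.
#' @return Numeric vector of length C(C-1)/2 named by component pair.
#' @export
vectorize_upper <- function(M) {
  C <- nrow(M)
  pairs <- t(utils::combn(C, 2))
  v <- M[pairs]
  nms <- colnames(M) %||% paste0("IC", seq_len(C))
  names(v) <- paste(nms[pairs[, 1]], nms[pairs[, 2]], sep = "-")
  v
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of \code{\link{vectorize_upper}}; the diagonal is set to
#' \code{diag_value}.
#'
#' @param v Vector of length C(C-1)/2.
#' @param diag_value Diagonal fill (default 0).
#' @return Symmetric C x C matrix.
#' @export
unvectorize_upper <- function(v, diag_value = 0) {
  P <- length(v)
  C <- (1 + sqrt(1 + 8 * P)) / 2
  if (abs(C - round(C)) > 1e-9) stop("length is not C(C-1)/2 for integer C")
  C <- as.integer(round(C))
  M <- matrix(diag_value, C, C)
  pairs <- t(utils::combn(C, 2))
  M[pairs] <- v
  M[pairs[, c(2, 1)]] <- v
  M
}

#' Compute a subject-session's windowed connectivity features
#'
#' The full dFNC estimation chain for one session: motion regression,
#' sliding-window enumeration, tapered windowed covariance, graphical-lasso
#' regularization, correlation from the regularized covariance, Fisher
#' z-transformation, and row-major upper-triangle vectorization. The taper is
#' centered on each window's rectangle; weights falling outside the series
#' are dropped and the remainder re-normalised.
#'
#' @param ts Preprocessed \code{\link{component_ts}}.
#' @param trace Optional T x 6 motion matrix to regress out first.
#' @param window_length,step,sigma_tr Window parameters (defaults 18, 1, 2).
#' @param lambda Graphical-lasso penalty (default 0.1).
#' @return Object of class \code{window_series}: list with \code{features}
#'   (Nw x C(C-1)/2 matrix of Fisher-z values), \code{window_starts},
#'   \code{window_length}, \code{tr_seconds} and \code{lambda}.
#' @export
compute_subject_dfnc <- function(ts, trace = NULL, window_length = 18,
                                 step = 1, sigma_tr = 2, lambda = 0.1) {
  ts <- as_component_ts(ts)
  if (!is.null(trace)) ts <- regress_motion(ts, trace)
  X <- ts$values
  n <- nrow(X)
  C <- ncol(X)
  starts <- enumerate_windows(n, window_length, step)
  taper <- make_taper(window_length, sigma_tr)
  pad <- taper$pad
  feats <- matrix(NA_real_, length(starts), C * (C - 1) / 2)
  gl <- NULL
  for (i in seq_along(starts)) {
    s <- starts[i]
    lo <- s - pad
    hi <- s + window_length - 1 + pad
    keep <- lo:hi >= 1 & lo:hi <= n
    idx <- (lo:hi)[keep]
    w <- taper$weights[keep]
    w <- w / sum(w)
    Swin <- tapered_covariance(X[idx, , drop = FALSE], w)
    gl <- tryCatch(graphical_lasso(Swin, lambda, warm = gl),
                   error = function(e)
                     stop("window ", i, " (start ", s, "): ",
                          conditionMessage(e), call. = FALSE))
    Sig <- gl$covariance
    R <- Sig / sqrt(tcrossprod(diag(Sig)))
    feats[i, ] <- fisher_z(vectorize_upper(R))
  }
  M0 <- diag(1, C)
  dimnames(M0) <- list(colnames(X), colnames(X))
  colnames(feats) <- names(vectorize_upper(M0))
  stopifnot(all(is.finite(feats)))
  structure(list(features = feats, window_starts = starts,
                 window_length = window_length, tr_seconds = ts$tr_seconds,
                 lambda = lambda, sigma_tr = sigma_tr),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat("Window series:", nrow(x$features), "windows x", ncol(x$features),
      "component pairs (W =", x$window_length, "TR, lambda =", x$lambda,
      ")\n")
  invisible(x)
}
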