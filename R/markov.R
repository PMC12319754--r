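#' Build a k-state Markov chain with a prescribed stationary distribution
#'
#' Constructs the switching kernel P(i -> j) = c * pi_j for j != i and
#' P(i -> i) = 1 - c * (1 - pi_i). This chain is reversible with stationary
#' distribution exactly \code{pi}; \code{c} controls the overall switching
#' rate (the expected number of switches over n steps is
#' (n - 1) * c * (1 - sum(pi^2))).
#'
#' @param pi Probability vector of target state occupancies (entries > 0,
#'   summing to 1).
#' @param switch_rate Scalar c in (0, min_i 1/(1 - pi_i)]; larger values
#'   switch more often.
#' @return An object of class \code{markov_chain}: list with
#'   \code{transition_matrix}, \code{initial_distribution},
#'   \code{target_occupancy} and \code{switch_rate}.
#' @export
#' @examples
#' ch <- build_markov_chain(c(0.45, 0.22, 0.16, 0.17), 0.08)
#' round(ch$transition_matrix, 4)
build_markov_chain <- function(pi, switch_rate) {
  pi <- as.numeric(pi)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must have positive entries summing to 1")
  k <- length(pi)
  c_max <- if (k == 1) Inf else min(1 / (1 - pi))
  if (switch_rate <= 0 || switch_rate > c_max)
    stop("switch_rate must lie in (0, ", format(c_max), "] for this pi")
  P <- switch_rate * matrix(pi, k, k, byrow = TRUE)
  diag(P) <- 1 - switch_rate * (1 - pi)
  stopifnot(all(P >= -1e-12), max(abs(rowSums(P) - 1)) < 1e-12)
  structure(list(transition_matrix = P,
                 initial_distribution = pi,
                 target_occupancy = pi,
                 switch_rate = switch_rate),
            class = "markov_chain")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Returns the unique left eigenvector of P with eigenvalue 1, normalised to
#' sum to 1. Errors if the chain has no unique stationary distribution
#' (reducible chain).
#'
#' @param P Row-stochastic square matrix.
#' @param tol Tolerance for identifying the unit eigenvalue.
#' @return Probability vector of the same length as \code{nrow(P)}.
#' @export
stationary_distribution <- function(P, tol = 1e-10) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < -1e-12) ||
      max(abs(rowSums(P) - 1)) > 1e-8)
    stop("P must be a row-stochastic square matrix")
  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-6)
  if (length(unit) != 1)
    stop("chain has no unique stationary distribution (reducible?)")
  v <- Re(e$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -tol)) stop("stationary vector not nonnegative")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Sample a state sequence from a Markov chain
#'
#' Simulates a discrete-state trajectory, optionally discarding an initial
#' burn-in so that the retained sequence is (approximately) stationary.
#'
#' @param chain A \code{\link{build_markov_chain}} object (or any list with a
#'   \code{transition_matrix} and \code{initial_distribution}).
#' @param length Number of retained steps (>= 1).
#' @param burn_in Number of discarded initial steps (>= 0).
#' @param seed Integer seed; required for reproducibility.
#' @param init Optional fixed initial state index; default draws from the
#'   chain's initial distribution.
#' @return Integer vector of state labels in 1..k.
#' @export
sample_state_sequence <- function(chain, length, burn_in = 0, seed,
                                  init = NULL) {
  stopifnot(length >= 1, burn_in >= 0)
  if (!missing(seed)) set.seed(as.integer(seed))
  P <- chain$transition_matrix
  k <- nrow(P)
  total <- burn_in + length
  # row-wise cdf lookup: one uniform per step
  cdf <- t(apply(P, 1, cumsum))
  s <- integer(total)
  s[1] <- if (is.null(init)) {
    sample.int(k, 1, prob = chain$initial_distribution)
  } else as.integer(init)
  u <- stats::runif(total)
  if (total >= 2) {
    for (t in 2:total) {
      s[t] <- findInterval(u[t], cdf[s[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  s[(burn_in + 1L):total]
}
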