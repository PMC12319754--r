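# shared fixtures built in code

default_arch <- build_state_archetypes()

study_chain <- build_markov_chain(c(0.45, 0.22, 0.16, 0.17), 0.08)

# the t6/t7 transition matrix written out digit by digit
study_P <- rbind(c(0.9560, 0.0176, 0.0128, 0.0136),
                 c(0.0360, 0.9376, 0.0128, 0.0136),
                 c(0.0360, 0.0176, 0.9328, 0.0136),
                 c(0.0360, 0.0176, 0.0128, 0.9336))

# tiny session fixture: one subject-session worth of synthetic data
make_session <- function(seed = 7, n_timepoints = 200) {
  s <- sample_state_sequence(study_chain, n_timepoints - 18, burn_in = 1000,
                             seed = seed)
  list(seq = s,
       ts = sample_component_timeseries(s, default_arch, n_timepoints,
                                        ar_coefficient = 0.3,
                                        seed = seed + 1),
       motion = sample_motion_trace(n_timepoints, seed = seed + 2))
}

# brute-force maximiser of the bivariate penalized log-likelihood
# (independent oracle for graphical_lasso). With the diagonal unpenalised,
# stationarity pins Sigma_ii = S_ii, so the search runs over the single
# free covariance entry sig12 and evaluates the objective at Theta =
# solve(Sigma).
glasso_2x2_grid <- function(S, lambda, grid_n = 20001) {
  s11 <- S[1, 1]; s22 <- S[2, 2]
  lim <- sqrt(s11 * s22) * 0.999
  sig <- seq(-lim, lim, length.out = grid_n)
  best <- NULL; best_val <- -Inf
  for (x in sig) {
    Sig <- matrix(c(s11, x, x, s22), 2, 2)
    Th <- solve(Sig)
    val <- determinant(Th, logarithm = TRUE)$modulus -
      sum(S * Th) - lambda * 2 * abs(Th[1, 2])
    if (val > best_val) { best_val <- val; best <- x }
  }
  best
}
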