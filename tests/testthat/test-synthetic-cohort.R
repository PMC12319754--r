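test_that("archetypes have the documented block structure and are valid correlation matrices", {
  part <- network_partition()
  arch <- build_state_archetypes(part, 0.6, -0.4, 0.05)
  expect_named(arch, c("weak", "sn_neg", "strong", "dmn_neg"))
  dmn <- which(part$network_of == "DMN")
  sn <- which(part$network_of == "SN")
  ecn <- which(part$network_of == "ECN")

  off <- function(M) M[upper.tri(M)]
  expect_true(all(abs(off(arch$weak)) <= 0.05 + 1e-12))
  expect_true(all(abs(off(arch$strong) - 0.6) < 1e-9))
  expect_true(all(arch$sn_neg[sn, c(dmn, ecn)] < 0))
  expect_true(all(arch$sn_neg[dmn, ecn] > 0))
  expect_true(all(arch$dmn_neg[dmn, c(sn, ecn)] < 0))
  expect_true(all(off(arch$dmn_neg[dmn, dmn]) <= 0.05 + 1e-9))
  expect_true(all(arch$dmn_neg[sn, ecn] > 0))

  for (M in arch) {
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_equal(unname(diag(M)), rep(1, 7))
    expect_gte(min(eigen(M, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("archetype construction enforces level preconditions", {
  expect_error(build_state_archetypes(strong_level = 1.0), "0.95")
  expect_error(build_state_archetypes(negative_level = 0.2), "negative")
  expect_error(build_state_archetypes(weak_level = 0.7), "weak_level")
})

test_that("equicorrelation archetype is already PSD at the default level", {
  # min eigenvalue of 0.4 J + 0.6 I is 1 - 0.6
  arch <- build_state_archetypes()
  expect_equal(min(eigen(arch$strong)$values), 0.4, tolerance = 1e-10)
  expect_true(all(abs(arch$strong[upper.tri(arch$strong)] - 0.6) < 1e-12))
})

test_that("chain construction reproduces the hand-computed kernel and stationarity round-trips", {
  expect_equal(build_markov_chain(c(0.5, 0.5), 0.2)$transition_matrix,
               rbind(c(0.9, 0.1), c(0.1, 0.9)))
  ch <- build_markov_chain(c(0.45, 0.22, 0.16, 0.17), 0.08)
  expect_equal(ch$transition_matrix, study_P, tolerance = 1e-12)
  expect_equal(stationary_distribution(ch$transition_matrix),
               c(0.45, 0.22, 0.16, 0.17), tolerance = 1e-10)
  expect_equal(build_markov_chain(1.0, 0.5)$transition_matrix,
               matrix(1, 1, 1))
  expect_error(build_markov_chain(c(0.45, 0.22, 0.16, 0.17), 2.5),
               "switch_rate")
  expect_error(build_markov_chain(c(0.4, 0.4), 0.1), "sum")
})

test_that("stationary distribution matches closed forms and rejects reducible chains", {
  expect_equal(stationary_distribution(matrix(0.25, 4, 4)), rep(0.25, 4))
  # two-state balance: q/(p+q) with p = 0.1, q = 0.3
  expect_equal(stationary_distribution(rbind(c(0.9, 0.1), c(0.3, 0.7))),
               c(0.75, 0.25), tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "unique")
})

test_that("chain construction round-trips through the stationary distribution", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    pi <- as.numeric(stats::rgamma(k, 2)) + 0.05
    pi <- pi / sum(pi)
    cmax <- min(1 / (1 - pi))
    cc <- stats::runif(1, 0.01, cmax * 0.99)
    P <- build_markov_chain(pi, cc)$transition_matrix
    expect_equal(stationary_distribution(P), pi, tolerance = 1e-8)
  }
})

test_that("sampled sequences are reproducible and match occupancy and switch-rate expectations", {
  ch <- study_chain
  expect_identical(sample_state_sequence(ch, 182, 100, seed = 9),
                   sample_state_sequence(ch, 182, 100, seed = 9))
  # no-switching limit
  frozen <- build_markov_chain(c(0.45, 0.22, 0.16, 0.17), 1e-9)
  s <- sample_state_sequence(frozen, 182, 0, seed = 3)
  expect_equal(count_transitions(s), 0)

  nrep <- 300
  seqs <- lapply(seq_len(nrep), function(i)
    sample_state_sequence(ch, 182, burn_in = 1000, seed = 1000 + i))
  frac1 <- vapply(seqs, function(s) mean(s == 1), numeric(1))
  switches <- vapply(seqs, count_transitions, numeric(1))
  # 3-SE Monte-Carlo bands around pi_1 and 181 c (1 - sum pi^2)
  expect_lt(abs(mean(frac1) - 0.45), 3 * stats::sd(frac1) / sqrt(nrep))
  expected_switches <- 181 * 0.08 * (1 - sum(c(0.45, 0.22, 0.16, 0.17)^2))
  expect_lt(abs(mean(switches) - expected_switches),
            3 * stats::sd(switches) / sqrt(nrep))
})

test_that("single-state simulation converges to the archetype correlation", {
  s <- rep(3L, 50000 - 18)  # strong state
  ts <- sample_component_timeseries(s, default_arch, 50000,
                                    ar_coefficient = 0, seed = 21)
  R <- stats::cor(ts$values)
  expect_lt(max(abs(R - default_arch$strong)), 0.02)
  # identity archetype leaves components uncorrelated
  id_arch <- list(diag(7))
  ts0 <- sample_component_timeseries(rep(1L, 50000 - 18), id_arch, 50000,
                                     ar_coefficient = 0, seed = 22)
  R0 <- stats::cor(ts0$values)
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.02)
})

test_that("timeseries generation is seed-reproducible and validates its inputs", {
  s <- sample_state_sequence(study_chain, 182, 10, seed = 4)
  a <- sample_component_timeseries(s, default_arch, 200, seed = 5)
  b <- sample_component_timeseries(s, default_arch, 200, seed = 5)
  expect_identical(a$values, b$values)
  expect_error(sample_component_timeseries(s, default_arch, 150, seed = 5),
               "convention")
  expect_error(sample_component_timeseries(s, default_arch, 200,
                                           ar_coefficient = 1, seed = 5),
               "ar_coefficient")
})

test_that("AR(1) smoothing keeps unit marginal variance", {
  s <- rep(1L, 20000 - 18)
  ts <- sample_component_timeseries(s, list(diag(7)), 20000,
                                    ar_coefficient = 0.6, seed = 8)
  expect_equal(unname(apply(ts$values, 2, stats::sd)), rep(1, 7),
               tolerance = 0.05)
})

test_that("motion traces are reproducible, zero under zero scales, and can exceed QC limits", {
  z <- sample_motion_trace(100, drift_scale = 0, spike_probability = 0,
                           spike_scale = 0, seed = 1)
  expect_true(all(z == 0))
  a <- sample_motion_trace(200, seed = 12)
  expect_identical(a, sample_motion_trace(200, seed = 12))
  big <- sample_motion_trace(200, drift_scale = 0, spike_probability = 0.05,
                             spike_scale = 10, seed = 13)
  expect_gt(max(abs(big[, 1:3])), 3)
})

test_that("cohort generation honours the trial design", {
  coh <- generate_cohort(arm_sizes = c(meditation = 3, language = 4,
                                       control = 3), seed = 2)
  expect_equal(nrow(coh$manifest), 20)  # (3+4+3) x 2 visits
  expect_true(all(table(coh$manifest$subject_id) == 2))
  expect_equal(unique(nchar(names(coh$truth)) > 0), TRUE)
  expect_true(all(vapply(coh$truth, length, 1L) == 200 - 18))
  expect_true(all(coh$manifest$age >= 65))
  # null effects: visit chains identical => same marginal construction
  coh0 <- generate_cohort(arm_sizes = c(meditation = 2, language = 2,
                                        control = 2),
                          effects = list(), seed = 2)
  expect_equal(nrow(coh0$manifest), 12)
  # occupancy shift must keep probabilities positive
  expect_error(generate_cohort(
    arm_sizes = c(meditation = 2, language = 2, control = 2),
    effects = list(intervention_effect("meditation", c(-0.5, 0, 0.5, 0))),
    seed = 2), "non-positive")
})

test_that("meditation-arm occupancy shift lowers state-1 ground-truth time at visit 2", {
  coh <- generate_cohort(arm_sizes = c(meditation = 25, language = 2,
                                       control = 2),
                         effects = list(intervention_effect(
                           "meditation", c(-0.08, 0, 0.08, 0))),
                         seed = 31)
  man <- coh$manifest
  med <- man[man$arm == "meditation", ]
  f1 <- function(v) mean(vapply(coh$truth[med$record_id[med$visit == v]],
                                function(s) mean(s == 1), numeric(1)))
  expect_lt(f1("V3"), f1("V1"))
})

test_that("cohort round-trips through the TSV/CSV disk format", {
  coh <- generate_cohort(arm_sizes = c(meditation = 1, language = 1,
                                       control = 1), seed = 6)
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  back <- read_cohort(manifest_path)
  expect_equal(back$manifest$record_id, coh$manifest$record_id)
  id <- coh$manifest$record_id[1]
  expect_equal(back$timeseries[[id]]$values, coh$timeseries[[id]]$values,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(back$motion[[id]]), unname(coh$motion[[id]]),
               tolerance = 1e-10)
  expect_equal(back$truth[[id]], coh$truth[[id]])
})
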