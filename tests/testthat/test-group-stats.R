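# build a minimal outcome table directly (bypassing the imaging pipeline)
make_outcome_table <- function(n_per_arm = 20, sd_subject = 0.7,
                               sd_resid = 0.7, shift = c(meditation = 0,
                                                         language = 0,
                                                         control = 0),
                               seed = 1) {
  set.seed(seed)
  arms <- rep(names(shift), times = n_per_arm)
  n <- length(arms)
  b <- stats::rnorm(n, sd = sd_subject)
  d <- data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(n)), each = 2),
    arm = rep(arms, each = 2),
    visit = rep(c("V1", "V3"), n),
    age = rep(round(stats::rnorm(n, 69.3, 3.9), 1), each = 2),
    sex = rep(sample(c("M", "F"), n, replace = TRUE), each = 2),
    education = rep(round(stats::rnorm(n, 13.2, 3.1), 1), each = 2)
  )
  d$y <- rep(b, each = 2) + stats::rnorm(2 * n, sd = sd_resid) +
    ifelse(d$visit == "V3", shift[d$arm], 0)
  d
}

test_that("within-group change is zero for identical visits and sign-equivariant", {
  tab <- make_outcome_table(10, seed = 3)
  tab$y <- rep(tab$y[seq(1, nrow(tab), 2)], each = 2)  # V3 == V1
  # zero residual variance makes the optimizer grumble; estimates are exact
  m <- suppressWarnings(fit_outcome_model(tab, "y"))
  w <- within_group_change(m)
  expect_equal(w$estimate, rep(0, 3), tolerance = 1e-8)
  expect_equal(w$d, rep(0, 3), tolerance = 1e-8)

  tab2 <- make_outcome_table(10, shift = c(meditation = 1, language = 0,
                                           control = 0), seed = 4)
  m2 <- fit_outcome_model(tab2, "y")
  w2 <- within_group_change(m2)
  tab2$y <- -tab2$y
  w2f <- within_group_change(fit_outcome_model(tab2, "y"))
  expect_equal(w2f$d, -w2$d, tolerance = 1e-8)
  expect_true(all(w2$d >= w2$d_lower & w2$d <= w2$d_upper))
})

test_that("balanced designs reduce to cell-mean arithmetic (OLS oracle)", {
  tab <- make_outcome_table(12, shift = c(meditation = 0.8, language = 0.1,
                                          control = -0.2), seed = 5)
  m <- fit_outcome_model(tab, "y", covariates = FALSE)
  w <- within_group_change(m)
  cell <- tapply(tab$y, list(tab$arm, tab$visit), mean)
  chg <- cell[, "V3"] - cell[, "V1"]
  expect_equal(w$estimate[order(w$arm)], unname(chg[order(names(chg))]),
               tolerance = 1e-6)
  pw <- pairwise_differences(m)
  # contrasts are differences of the within-arm changes, and the three
  # estimates are linearly consistent
  expect_equal(sum(pw$estimate[1] - pw$estimate[2] + pw$estimate[3]), 0,
               tolerance = 1e-8)
})

test_that("interaction test is near-null for identical arms and detects injected interactions", {
  tab <- make_outcome_table(15, seed = 6)
  tab$y <- rep(1.5, nrow(tab))  # identical data everywhere
  m <- suppressWarnings(fit_outcome_model(tab, "y", covariates = FALSE))
  it <- suppressWarnings(interaction_test(m))
  expect_true(is.na(it$F) || it$F < 1e-6 || it$p > 0.99)

  tab2 <- make_outcome_table(40, shift = c(meditation = 1.5, language = 0,
                                           control = 0), seed = 7)
  it2 <- interaction_test(fit_outcome_model(tab2, "y"))
  expect_lt(it2$p, 0.01)
  expect_equal(it2$df1, 2)
})

test_that("pairwise differences in change single out the shifted arm", {
  tab <- make_outcome_table(40, shift = c(meditation = 1.5, language = 0,
                                          control = 0), seed = 8)
  pw <- pairwise_differences(fit_outcome_model(tab, "y"))
  med_rows <- grepl("meditation", pw$contrast)
  expect_true(all(pw$p[med_rows] < 0.05))
  expect_gt(pw$p[!med_rows], 0.05)
})

test_that("Tukey and BH adjustments dominate the raw p-values", {
  tab <- make_outcome_table(15, shift = c(meditation = 0.4, language = 0,
                                          control = 0.1), seed = 9)
  m <- fit_outcome_model(tab, "y")
  emm <- emmeans::emmeans(m, ~ visit | arm, lmer.df = "satterthwaite")
  chg <- emmeans::contrast(emm, "revpairwise")
  raw <- summary(emmeans::contrast(chg, "revpairwise", by = NULL),
                 adjust = "none")$p.value
  adj <- pairwise_differences(m)$p
  expect_true(all(adj >= raw - 1e-12))

  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.001, 0.01, 0.2, 0.8)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("metric correlations recover exact dependencies and compositional negativity", {
  tab <- make_outcome_table(15, seed = 10)
  tab$m1 <- stats::rnorm(nrow(tab))
  tab$m2 <- tab$m1
  tab$m3 <- -tab$m1
  r <- metric_correlations(tab, metrics = c("m1", "m2", "m3"), visit = "V1")
  expect_equal(r$r[r$metric1 == "m1" & r$metric2 == "m2"], 1)
  expect_equal(r$r[r$metric1 == "m1" & r$metric2 == "m3"], -1)

  coh <- generate_cohort(arm_sizes = c(meditation = 8, language = 8,
                                       control = 8), seed = 15)
  mt <- metrics_table(coh$truth, coh$manifest, k = 4)
  rr <- metric_correlations(mt, metrics = paste0("state", 1:4), visit = "V1")
  expect_true(any(rr$r < 0))  # fractions summing to 1 force a negative pair

  tab$flat <- 1
  expect_warning(metric_correlations(tab, metrics = c("m1", "flat"),
                                     visit = "V1"), "zero-variance")
})

test_that("the experienced-state filter drops whole subjects by the both-visits rule", {
  coh <- generate_cohort(arm_sizes = c(meditation = 5, language = 5,
                                       control = 5), seed = 16)
  tab <- metrics_table(coh$truth, coh$manifest, k = 4)
  all_pos <- experienced_state_filter(tab, 1)
  expect_lte(nrow(all_pos), nrow(tab))
  expect_true(all(table(all_pos$subject_id) == 2))

  tab2 <- tab
  tab2$state2[tab2$subject_id == tab2$subject_id[1] &
                tab2$visit == "V1"] <- 0
  f2 <- experienced_state_filter(tab2, 2)
  expect_false(tab2$subject_id[1] %in% f2$subject_id)
  f2e <- experienced_state_filter(tab2, 2, rule = "either")
  expect_true(tab2$subject_id[1] %in% f2e$subject_id)

  expect_error(experienced_state_filter(tab, 9), "out of range")
  tab3 <- tab; tab3$state3 <- 0
  expect_error(experienced_state_filter(tab3, 3), "inadvisable")
})

test_that("analyze_outcomes assembles the per-outcome summary tables with FDR", {
  coh <- generate_cohort(arm_sizes = c(meditation = 8, language = 8,
                                       control = 8), seed = 17)
  tab <- metrics_table(coh$truth, coh$manifest, k = 4)
  res <- suppressWarnings(analyze_outcomes(tab,
                                           outcomes = c("state1",
                                                        "transitions")))
  expect_equal(nrow(res$within), 6)      # 2 outcomes x 3 arms
  expect_equal(nrow(res$pairwise), 6)    # 2 outcomes x 3 pairs
  expect_equal(nrow(res$interaction), 2)
  expect_true(all(res$interaction$p_fdr >= res$interaction$p - 1e-12))
})
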