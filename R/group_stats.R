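#' Fit the random-intercept mixed model for one outcome
#'
#' Fits \code{outcome ~ visit * arm + age + sex + education + (1 | subject)}
#' by REML, with age and education mean-centered and sex as a two-level
#' factor. This is the per-outcome model behind all group-level contrasts.
#'
#' @param table Outcome table from \code{\link{metrics_table}} (columns
#'   \code{subject_id}, \code{arm}, \code{visit}, \code{age}, \code{sex},
#'   \code{education} plus outcome columns).
#' @param outcome Name of the outcome column (e.g. \code{"state1"} or
#'   \code{"transitions"}).
#' @param covariates Adjust for mean-centered age and education and for sex
#'   (default TRUE). Set FALSE for unadjusted designs (e.g. balanced
#'   constructions where the covariates are absent or constant).
#' @return A fitted \code{lmerModLmerTest} object with the analysis data in
#'   attribute \code{"model_data"}.
#' @export
fit_outcome_model <- function(table, outcome, covariates = TRUE) {
  if (!outcome %in% names(table)) stop("no column '", outcome, "' in table")
  d <- data.frame(
    y = table[[outcome]],
    subject = factor(table$subject_id),
    visit = factor(table$visit),
    arm = factor(table$arm)
  )
  if (covariates) {
    d$age_c <- table$age - mean(table$age)
    d$sex <- factor(table$sex)
    d$edu_c <- table$education - mean(table$education)
  }
  form <- if (covariates) {
    y ~ visit * arm + age_c + sex + edu_c + (1 | subject)
  } else {
    y ~ visit * arm + (1 | subject)
  }
  m <- lmerTest::lmer(form, data = d, REML = TRUE)
  if (lme4::isSingular(m, tol = 1e-5))
    warning("singular fit for outcome '", outcome,
            "' (random-intercept variance at boundary)")
  attr(m, "model_data") <- d
  m
}

# model-based subject-level SD: sqrt(random-intercept var + residual var)
model_total_sd <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  sqrt(sum(vc$vcov))
}

#' Within-group standardized change (post minus baseline)
#'
#' Estimated marginal-mean V3 - V1 contrast within each arm, standardized to
#' Cohen's d by the model-based subject-level SD
#' (sqrt of random-intercept variance + residual variance), with 95%
#' confidence intervals and p-values adjusted over the three-contrast family
#' (Sidak familywise bound; the within-arm change family is not a pairwise
#' family, so the studentized-range adjustment does not apply to it).
#'
#' @param model A \code{\link{fit_outcome_model}} fit.
#' @return Data frame with one row per arm: \code{arm}, \code{estimate},
#'   \code{d}, \code{d_lower}, \code{d_upper}, \code{p}.
#' @export
within_group_change <- function(model) {
  emm <- emmeans::emmeans(model, ~ visit | arm,
                          lmer.df = "satterthwaite")
  ct <- emmeans::contrast(emm, method = "revpairwise")
  s <- summary(ct, by = NULL, adjust = "sidak", infer = c(TRUE, TRUE),
               level = 0.95)
  sd_tot <- model_total_sd(model)
  data.frame(arm = as.character(s$arm),
             estimate = s$estimate,
             d = s$estimate / sd_tot,
             d_lower = s$lower.CL / sd_tot,
             d_upper = s$upper.CL / sd_tot,
             p = s$p.value,
             stringsAsFactors = FALSE)
}

#' Joint test of the group-by-visit interaction
#'
#' F test of the visit:arm terms with Satterthwaite denominator degrees of
#' freedom.
#'
#' @param model A \code{\link{fit_outcome_model}} fit.
#' @return List with \code{F}, \code{df1}, \code{df2} and \code{p}.
#' @export
interaction_test <- function(model) {
  a <- stats::anova(model, type = 3)
  row <- a["visit:arm", ]
  list(F = row[["F value"]], df1 = row[["NumDF"]], df2 = row[["DenDF"]],
       p = row[["Pr(>F)"]])
}

#' Pairwise between-arm differences in change
#'
#' The three arm-pair contrasts of the V3 - V1 change (difference in change),
#' with Tukey family-wise adjustment over the three pairs, on both the raw
#' and the Cohen's d scale.
#'
#' @param model A \code{\link{fit_outcome_model}} fit.
#' @return Data frame with one row per arm pair: \code{contrast},
#'   \code{estimate}, \code{d}, \code{d_lower}, \code{d_upper}, \code{p}.
#' @export
pairwise_differences <- function(model) {
  emm <- emmeans::emmeans(model, ~ visit | arm,
                          lmer.df = "satterthwaite")
  chg <- emmeans::contrast(emm, method = "revpairwise")
  pw <- emmeans::contrast(chg, method = "revpairwise", by = NULL)
  s <- summary(pw, adjust = "tukey", infer = c(TRUE, TRUE), level = 0.95)
  sd_tot <- model_total_sd(model)
  data.frame(contrast = as.character(s$contrast),
             estimate = s$estimate,
             d = s$estimate / sd_tot,
             d_lower = s$lower.CL / sd_tot,
             d_upper = s$upper.CL / sd_tot,
             p = s$p.value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across a family of tests.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (same length).
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise Pearson correlations between dFNC metrics
#'
#' Correlates the temporal metrics (per-state fractions and transitions)
#' across subjects at a single visit, with two-sided p-values from the t
#' distribution. Zero-variance metrics yield NA with a warning.
#'
#' @param table Outcome table restricted to one visit (or pass \code{visit}).
#' @param metrics Metric column names; default all \code{state*} fraction
#'   columns plus \code{transitions}.
#' @param visit Optional visit label to filter on.
#' @return Data frame with columns \code{metric1}, \code{metric2}, \code{r},
#'   \code{p}.
#' @export
metric_correlations <- function(table, metrics = NULL, visit = NULL) {
  if (!is.null(visit)) table <- table[table$visit == visit, , drop = FALSE]
  if (is.null(metrics))
    metrics <- c(grep("^state[0-9]+$", names(table), value = TRUE),
                 "transitions")
  if (nrow(table) < 3) stop("need at least 3 complete rows")
  pairs <- utils::combn(metrics, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance metric in pair ", pr[1], "-", pr[2])
      return(c(NA_real_, NA_real_))
    }
    ct <- stats::cor.test(x, y)
    c(ct$estimate, ct$p.value)
  })
  data.frame(metric1 = pairs[1, ], metric2 = pairs[2, ],
             r = res[1, ], p = res[2, ], stringsAsFactors = FALSE)
}

#' Restrict the cohort to participants who experienced a state
#'
#' Keeps only subjects whose time in the given state is positive; by default
#' positivity is required at both visits, and both of a subject's rows are
#' kept or dropped together.
#'
#' @param table Outcome table.
#' @param state State index (1..k).
#' @param rule \code{"both"} (default) requires time > 0 at both visits;
#'   \code{"either"} at at least one.
#' @return Filtered table.
#' @export
experienced_state_filter <- function(table, state, rule = c("both", "either")) {
  rule <- match.arg(rule)
  col <- paste0("state", state)
  if (!col %in% names(table)) stop("state index out of range: no column ", col)
  pos <- tapply(table[[col]] > 0, table$subject_id,
                if (rule == "both") all else any)
  keep_subjects <- names(pos)[pos]
  out <- table[table$subject_id %in% keep_subjects, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no subjects experienced state ", state, "; model fit inadvisable")
  rownames(out) <- NULL
  out
}

#' Full group-level analysis across outcomes
#'
#' For each outcome, fits the mixed model and computes within-group
#' standardized changes, the group-by-visit interaction F test, and Tukey
#' pairwise differences in change; interaction p-values are FDR-adjusted
#' across outcomes.
#'
#' @param table Outcome table from \code{\link{metrics_table}}.
#' @param outcomes Outcome column names; default all state fractions plus
#'   transitions.
#' @return List with \code{within} (Table-2-shaped: outcome x arm d, CI, p),
#'   \code{interaction} (outcome, F, p, p_fdr) and \code{pairwise}
#'   (Table-3-shaped: outcome x arm-pair d, CI, p).
#' @export
analyze_outcomes <- function(table, outcomes = NULL) {
  if (is.null(outcomes))
    outcomes <- c(grep("^state[0-9]+$", names(table), value = TRUE),
                  "transitions")
  within <- list(); pairwise <- list(); inter <- list()
  for (oc in outcomes) {
    m <- fit_outcome_model(table, oc)
    w <- within_group_change(m); w$outcome <- oc
    p <- pairwise_differences(m); p$outcome <- oc
    it <- interaction_test(m)
    within[[oc]] <- w
    pairwise[[oc]] <- p
    inter[[oc]] <- data.frame(outcome = oc, F = it$F, df1 = it$df1,
                              df2 = it$df2, p = it$p)
  }
  inter <- do.call(rbind, inter)
  inter$p_fdr <- fdr_adjust(inter$p)
  rownames(inter) <- NULL
  list(within = do.call(rbind, c(within, make.row.names = FALSE)),
       interaction = inter,
       pairwise = do.call(rbind, c(pairwise, make.row.names = FALSE)))
}
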