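#' Specify an intervention effect on the state dynamics
#'
#' Describes how one trial arm's hidden-state chain changes at the
#' post-intervention visit: an additive shift to the target occupancies and a
#' multiplier on the switching rate.
#'
#' @param arm Arm label (e.g. \code{"meditation"}).
#' @param occupancy_shift Length-k additive change to the occupancy vector at
#'   visit 2 (re-normalised after shifting; must keep all entries positive).
#' @param switch_rate_multiplier Positive multiplier on the switch rate at
#'   visit 2 (default 1).
#' @return Object of class \code{intervention_effect}.
#' @export
intervention_effect <- function(arm, occupancy_shift,
                                switch_rate_multiplier = 1) {
  if (switch_rate_multiplier <= 0) stop("switch_rate_multiplier must be > 0")
  structure(list(arm = arm, occupancy_shift = as.numeric(occupancy_shift),
                 switch_rate_multiplier = switch_rate_multiplier),
            class = "intervention_effect")
}

# apply an effect to a base chain, validating the shifted occupancies
shift_chain <- function(chain, effect) {
  pi2 <- chain$target_occupancy + effect$occupancy_shift
  if (any(pi2 <= 0))
    stop("occupancy_shift for arm '", effect$arm,
         "' produces non-positive probabilities")
  pi2 <- pi2 / sum(pi2)
  build_markov_chain(pi2, chain$switch_rate * effect$switch_rate_multiplier)
}

#' Generate a synthetic three-arm longitudinal cohort
#'
#' Simulates a full randomized-trial cohort of component time courses, motion
#' traces and ground-truth hidden-state sequences. Visit-1 records of all
#' arms share the base Markov chain; visit-2 records of each arm use the
#' arm's shifted chain (see \code{\link{intervention_effect}}). Covariates
#' emulate an older-adult trial population: age ~ N(69.3, 3.9^2) truncated at
#' 65, education years ~ N(13.2, 3.1^2), sex ~ Bernoulli(0.35) for male.
#'
#' @param arm_sizes Named integer vector of subjects per arm
#'   (default \code{c(meditation = 40, language = 43, control = 41)}).
#' @param n_timepoints TRs per session (default 200).
#' @param tr_seconds Repetition time (default 2.4 s).
#' @param window_length Window length W in TRs (default 18); the hidden-state
#'   sequence has length \code{n_timepoints - window_length}.
#' @param chain Base \code{\link{build_markov_chain}}; default has occupancies
#'   (0.45, 0.22, 0.16, 0.17) and switch rate 0.08.
#' @param archetypes State archetypes (default
#'   \code{\link{build_state_archetypes}()}).
#' @param effects List of \code{\link{intervention_effect}}s keyed by arm;
#'   arms without an effect keep the base chain at both visits. The default
#'   gives the meditation arm less state-1 time, more state-3 time and a
#'   higher switching rate at visit 2.
#' @param ar_coefficient AR(1) smoothness of the signals (default 0.3).
#' @param burn_in Markov burn-in steps per session (default 1000).
#' @param seed Integer master seed; per-session seeds are derived as
#'   \code{seed + 1000 * record_index} so each record is independently
#'   reproducible.
#' @return Object of class \code{synthetic_cohort}: list with \code{manifest}
#'   (data.frame: subject_id, arm, visit, age, sex, education), and parallel
#'   lists \code{timeseries} (\code{component_ts}), \code{motion} (T x 6
#'   matrices) and \code{truth} (window-level integer state sequences), all
#'   indexed by \code{record_id = subject_id x visit}.
#' @export
generate_cohort <- function(arm_sizes = c(meditation = 40, language = 43,
                                          control = 41),
                            n_timepoints = 200, tr_seconds = 2.4,
                            window_length = 18,
                            chain = build_markov_chain(
                              c(0.45, 0.22, 0.16, 0.17), 0.08),
                            archetypes = build_state_archetypes(),
                            effects = default_effects(),
                            ar_coefficient = 0.3,
                            burn_in = 1000,
                            seed = 1) {
  stopifnot(length(arm_sizes) >= 1, all(arm_sizes >= 1))
  if (is.null(names(arm_sizes)))
    names(arm_sizes) <- c("meditation", "language", "control")[seq_along(arm_sizes)]
  nw <- n_timepoints - window_length
  if (nw < 1) stop("n_timepoints must exceed window_length")

  effect_of <- list()
  for (e in effects) effect_of[[e$arm]] <- e
  visit2_chain <- lapply(names(arm_sizes), function(a) {
    if (!is.null(effect_of[[a]])) shift_chain(chain, effect_of[[a]]) else chain
  })
  names(visit2_chain) <- names(arm_sizes)

  n_sub <- sum(arm_sizes)
  arms <- rep(names(arm_sizes), arm_sizes)
  set.seed(as.integer(seed))
  age <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    repeat {
      a <- stats::rnorm(1, 69.3, 3.9)
      if (a >= 65) break
    }
    age[i] <- a
  }
  sex <- ifelse(stats::rbinom(n_sub, 1, 0.35) == 1, "M", "F")
  education <- pmax(stats::rnorm(n_sub, 13.2, 3.1), 7)

  manifest <- data.frame(
    subject_id = sprintf("S%03d", rep(seq_len(n_sub), each = 2)),
    arm = rep(arms, each = 2),
    visit = rep(c("V1", "V3"), n_sub),
    age = round(rep(age, each = 2), 1),
    sex = rep(sex, each = 2),
    education = round(rep(education, each = 2), 1),
    stringsAsFactors = FALSE
  )
  manifest$record_id <- paste(manifest$subject_id, manifest$visit, sep = "_")

  timeseries <- vector("list", nrow(manifest))
  motion <- vector("list", nrow(manifest))
  truth <- vector("list", nrow(manifest))
  names(timeseries) <- names(motion) <- names(truth) <- manifest$record_id
  for (r in seq_len(nrow(manifest))) {
    rec_chain <- if (manifest$visit[r] == "V1") chain else
      visit2_chain[[manifest$arm[r]]]
    rec_seed <- as.integer(seed) + 1000L * r
    truth[[r]] <- sample_state_sequence(rec_chain, nw, burn_in = burn_in,
                                        seed = rec_seed)
    timeseries[[r]] <- sample_component_timeseries(
      truth[[r]], archetypes, n_timepoints, window_length,
      ar_coefficient = ar_coefficient, seed = rec_seed + 1L,
      tr_seconds = tr_seconds)
    motion[[r]] <- sample_motion_trace(n_timepoints, seed = rec_seed + 2L)
  }
  structure(list(manifest = manifest, timeseries = timeseries,
                 motion = motion, truth = truth,
                 window_length = window_length, tr_seconds = tr_seconds,
                 k = length(chain$target_occupancy)),
            class = "synthetic_cohort")
}

#' Default intervention effects for the simulated trial
#'
#' The meditation arm shifts occupancy away from the weakly connected state
#' toward the strongly connected state and switches more often at visit 2;
#' the active-control (language) and passive-control arms are unchanged.
#'
#' @param occupancy_shift Meditation-arm occupancy shift (default
#'   \code{c(-0.06, 0, 0.06, 0)}).
#' @param switch_rate_multiplier Meditation-arm switch-rate multiplier at
#'   visit 2 (default 1.25).
#' @return List of \code{\link{intervention_effect}}s.
#' @export
default_effects <- function(occupancy_shift = c(-0.06, 0, 0.06, 0),
                            switch_rate_multiplier = 1.25) {
  list(intervention_effect("meditation", occupancy_shift,
                           switch_rate_multiplier))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "records (",
      length(unique(x$manifest$subject_id)), "subjects x 2 visits ),",
      x$k, "hidden states\n")
  print(table(arm = x$manifest$arm, visit = x$manifest$visit))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes per-record component time-course TSVs (columns IC1..ICC), motion
#' TSVs (columns trans_x_mm..rot_z_deg), a ground-truth window-label CSV and
#' a manifest CSV with file paths.
#'
#' @param cohort A \code{\link{generate_cohort}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$timeseries_path <- file.path(dir, paste0(man$record_id, "_ts.tsv"))
  man$motion_path <- file.path(dir, paste0(man$record_id, "_motion.tsv"))
  for (r in seq_len(nrow(man))) {
    utils::write.table(cohort$timeseries[[r]]$values, man$timeseries_path[r],
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cohort$motion[[r]], man$motion_path[r],
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- data.frame(record_id = rep(man$record_id,
                                      vapply(cohort$truth, length, 1L)),
                      window = unlist(lapply(cohort$truth, seq_along)),
                      state = unlist(cohort$truth), row.names = NULL)
  utils::write.csv(truth, file.path(dir, "ground_truth_states.csv"),
                   row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param manifest_path Path to \code{manifest.csv}.
#' @param tr_seconds Repetition time of the series (default 2.4 s).
#' @return A \code{synthetic_cohort}-shaped list (ground truth included when
#'   \code{ground_truth_states.csv} is present alongside the manifest).
#' @export
read_cohort <- function(manifest_path, tr_seconds = 2.4) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  ts <- lapply(man$timeseries_path, function(p)
    component_ts(as.matrix(utils::read.delim(p)), tr_seconds))
  mo <- lapply(man$motion_path, function(p) as.matrix(utils::read.delim(p)))
  names(ts) <- names(mo) <- man$record_id
  truth_path <- file.path(dirname(manifest_path), "ground_truth_states.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    tt <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    truth <- split(tt$state, factor(tt$record_id, levels = man$record_id))
  }
  structure(list(manifest = man, timeseries = ts, motion = mo, truth = truth,
                 tr_seconds = tr_seconds),
            class = "synthetic_cohort")
}
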