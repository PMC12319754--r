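#' Run the full dFNC state pipeline on a cohort
#'
#' End-to-end analysis: motion QC, time-course post-processing, windowed
#' graphical-lasso connectivity, pooled k-means state clustering (fixed k or
#' elbow-selected), per-session state assignment, temporal metrics and the
#' group-level mixed-model contrasts.
#'
#' @param cohort A \code{\link{generate_cohort}} result (or the equivalent
#'   structure read by \code{\link{read_cohort}}).
#' @param k Number of states; \code{NULL} selects k by the elbow criterion.
#' @param lambda Graphical-lasso penalty (default 0.1).
#' @param window_length,step,sigma_tr Sliding-window parameters.
#' @param seed Clustering seed (default 20160625).
#' @param restarts k-means restarts (default 10).
#' @param archetypes Archetype set used to label the fitted states; NULL
#'   skips matching.
#' @param run_group_stats Fit the group-level mixed models (default TRUE).
#' @return List with \code{qc} (per-record QC table), \code{features}
#'   (pooled feature matrix), \code{model} (labelled \code{state_model}),
#'   \code{selection} (elbow report or NULL), \code{sequences} (per-record
#'   state labels), \code{metrics} (outcome table) and \code{stats}
#'   (\code{\link{analyze_outcomes}} output or NULL).
#' @export
run_state_pipeline <- function(cohort, k = 4, lambda = 0.1,
                               window_length = 18, step = 1, sigma_tr = 2,
                               seed = 20160625, restarts = 10,
                               archetypes = build_state_archetypes(),
                               run_group_stats = TRUE) {
  man <- cohort$manifest
  tr <- cohort$tr_seconds %||% 2.4

  qc <- do.call(rbind, lapply(man$record_id, function(id) {
    q <- motion_qc(cohort$motion[[id]])
    data.frame(record_id = id, passed = q$passed,
               max_translation_mm = q$max_translation_mm,
               max_rotation_deg = q$max_rotation_deg,
               reason = q$reason, stringsAsFactors = FALSE)
  }))
  keep <- qc$record_id[qc$passed]
  man_keep <- man[man$record_id %in% keep, , drop = FALSE]

  ws <- lapply(man_keep$record_id, function(id) {
    ts <- preprocess_timeseries(cohort$timeseries[[id]])
    compute_subject_dfnc(ts, cohort$motion[[id]], window_length, step,
                         sigma_tr, lambda)
  })
  names(ws) <- man_keep$record_id
  features <- do.call(rbind, lapply(ws, function(w) w$features))

  selection <- NULL
  if (is.null(k)) {
    selection <- elbow_select(features, restarts = restarts, seed = seed)
    k <- selection$chosen_k
  }
  model <- fit_kmeans(features, k, restarts = restarts, seed = seed)
  if (!is.null(archetypes) && length(archetypes) == k)
    model <- match_states_to_archetypes(model, archetypes)

  sequences <- lapply(ws, assign_states, model = model)
  metrics <- metrics_table(sequences, man_keep, k, window_length, tr)
  stats_out <- if (run_group_stats) analyze_outcomes(metrics) else NULL

  list(qc = qc, features = features, model = model, selection = selection,
       sequences = sequences, metrics = metrics, stats = stats_out)
}
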