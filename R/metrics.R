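#' Fraction of time spent in each state
#'
#' Count of windows per state divided by the number of windows.
#'
#' @param seq Integer state sequence (labels in 1..k).
#' @param k Number of states.
#' @return Numeric vector of length k summing to 1.
#' @export
fraction_time <- function(seq, k) {
  seq <- as.integer(seq)
  if (any(seq < 1 | seq > k)) stop("labels outside 1..k")
  tabulate(seq, nbins = k) / length(seq)
}

#' Dwell-time runs per state
#'
#' Maximal runs of identical labels, their per-state lengths and mean dwell
#' time in windows. States never visited get \code{NA} (not zero).
#'
#' @param seq Integer state sequence.
#' @param k Number of states (default \code{max(seq)}).
#' @return List with \code{runs} (per-state list of run lengths) and
#'   \code{mean_dwell_windows} (length-k vector, NA for unvisited states).
#' @export
dwell_runs <- function(seq, k = max(seq)) {
  r <- rle(as.integer(seq))
  runs <- lapply(seq_len(k), function(s) r$lengths[r$values == s])
  mean_dwell <- vapply(runs, function(x)
    if (length(x)) mean(x) else NA_real_, numeric(1))
  list(runs = runs, mean_dwell_windows = mean_dwell)
}

#' Convert a dwell time in windows to seconds
#'
#' Uses the span convention: a run of n consecutive step-1 windows of length
#' W TRs spans (n + W - 1) TRs, i.e. (n + W - 1) * TR seconds from the first
#' TR of the first window to the last TR of the last window. With W = 18 and
#' TR = 2.4 s, 22 windows correspond to 93.6 s and 9 windows to 62.4 s.
#'
#' @param n_windows Dwell time in windows (>= 1).
#' @param window_length Window length W in TRs (default 18).
#' @param tr_seconds Repetition time (default 2.4 s).
#' @return Dwell time in seconds.
#' @export
#' @examples
#' dwell_to_seconds(22)  # 93.6
dwell_to_seconds <- function(n_windows, window_length = 18, tr_seconds = 2.4) {
  if (any(n_windows < 1)) stop("n_windows must be >= 1")
  (n_windows + window_length - 1) * tr_seconds
}

#' Number of transitions between states
#'
#' Number of adjacent window pairs with different labels.
#'
#' @param seq Integer state sequence.
#' @return Integer count (0 for a constant sequence).
#' @export
count_transitions <- function(seq) {
  sum(diff(as.integer(seq)) != 0L)
}

#' All temporal state metrics for one sequence
#'
#' @param seq Integer state sequence.
#' @param k Number of states.
#' @param window_length,tr_seconds Conversion parameters for dwell seconds.
#' @return List with \code{fraction_time}, \code{windows_in_state},
#'   \code{mean_dwell_windows}, \code{mean_dwell_seconds} and
#'   \code{n_transitions}.
#' @export
state_metrics <- function(seq, k, window_length = 18, tr_seconds = 2.4) {
  ft <- fraction_time(seq, k)
  dw <- dwell_runs(seq, k)$mean_dwell_windows
  sec <- rep(NA_real_, k)
  ok <- !is.na(dw)
  sec[ok] <- dwell_to_seconds(dw[ok], window_length, tr_seconds)
  list(fraction_time = ft,
       windows_in_state = tabulate(as.integer(seq), nbins = k),
       mean_dwell_windows = dw,
       mean_dwell_seconds = sec,
       n_transitions = count_transitions(seq))
}

#' Assemble the cohort outcome table
#'
#' One row per subject-visit with covariates, per-state fraction of time,
#' per-state window counts and the transition count; the long-format input
#' to the group-level mixed models.
#'
#' @param sequences Named list of state sequences, keyed by
#'   \code{record_id = subject_id_visit} matching the manifest.
#' @param manifest Data frame with columns \code{subject_id}, \code{arm},
#'   \code{visit}, \code{age}, \code{sex}, \code{education} and
#'   \code{record_id}.
#' @param k Number of states.
#' @param window_length,tr_seconds Dwell conversion parameters.
#' @return Data frame with one row per record: covariates, \code{state1} ..
#'   \code{statek} (fractions), \code{state1_windows} .., \code{transitions}.
#' @export
metrics_table <- function(sequences, manifest, k, window_length = 18,
                          tr_seconds = 2.4) {
  need <- c("subject_id", "arm", "visit", "record_id")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  if (anyDuplicated(manifest$record_id))
    stop("duplicated subject-visit records: ",
         paste(unique(manifest$record_id[duplicated(manifest$record_id)]),
               collapse = ", "))
  missing <- setdiff(manifest$record_id, names(sequences))
  if (length(missing))
    stop("missing sequences for: ", paste(missing, collapse = ", "))
  out <- manifest[order(manifest$record_id),
                  intersect(c("subject_id", "arm", "visit", "age", "sex",
                              "education", "record_id"), names(manifest)),
                  drop = FALSE]
  if (nrow(out) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, 2 * k + 1))
    names(empty) <- c(paste0("state", seq_len(k)),
                      paste0("state", seq_len(k), "_windows"), "transitions")
    return(cbind(out, empty))
  }
  mets <- lapply(out$record_id, function(id)
    state_metrics(sequences[[id]], k, window_length, tr_seconds))
  ft <- t(vapply(mets, `[[`, numeric(k), "fraction_time"))
  wc <- t(vapply(mets, `[[`, numeric(k), "windows_in_state"))
  colnames(ft) <- paste0("state", seq_len(k))
  colnames(wc) <- paste0("state", seq_len(k), "_windows")
  out <- cbind(out, ft, wc,
               transitions = vapply(mets, `[[`, numeric(1), "n_transitions"))
  rownames(out) <- NULL
  out
}
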