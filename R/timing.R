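# Viewing-time and completion-time measures.

#' Model viewing times with inclusion filter
#'
#' The viewing time of a sequence is its initial model dwell: summed model
#' gaze from the opening view up to the first resource visit (computed by
#' [segment_sequences()]).  A sequence is included in the viewing-time
#' analysis when its dwell lies within `bounds_ms` (closed interval) *and*
#' its feature count lies within `k_range`.
#'
#' @param scored table from [score_sequences()].
#' @param bounds_ms closed dwell bounds in ms.
#' @param k_range closed feature-count bounds.
#' @param exclude_truncated drop truncated sequences entirely.
#' @return data.table keyed like the sequence table with `dwell_ms` and
#'   `included`.
#' @export
viewing_times <- function(scored, bounds_ms = c(50, 2000), k_range = c(1L, 4L),
                          exclude_truncated = TRUE) {
  scored <- as.data.table(scored)
  if (exclude_truncated) scored <- scored[truncated == FALSE]
  vt <- scored[, .(participant, session, run, condition_deg, display, seq_id,
                   k, dwell_ms = initial_model_dwell_ms)]
  vt[, k_eligible := k >= k_range[1] & k <= k_range[2]]
  vt[, included := k_eligible & dwell_ms >= bounds_ms[1] &
       dwell_ms <= bounds_ms[2]]
  vt[]
}

#' Apply the viewing-time filter and report exclusions
#'
#' @param vts table from [viewing_times()].
#' @return list with `included` (the retained rows), `excluded_fraction`
#'   (fraction of in-range-k sequences dropped by the dwell bounds) and
#'   `n_total`.
#' @export
filter_viewing_times <- function(vts) {
  vts <- as.data.table(vts)
  keep <- vts[included == TRUE]
  # the dwell filter's bite, as a fraction of the k-eligible analysis set
  elig <- vts[k_eligible == TRUE]
  excl <- if (nrow(elig) > 0) 1 - nrow(keep) / nrow(elig) else NA_real_
  list(included = keep[], excluded_fraction = excl, n_total = nrow(vts))
}

#' Display completion times
#'
#' Completion time of a display is the sum of its sequence durations;
#' because adjacent sequences share their boundary model view, this equals
#' the time from the first model view to the last.  The display's mean
#' feature count is averaged over the same sequences that enter the
#' feature-probability table (0-feature and error sequences excluded by
#' default).
#'
#' @param scored table from [score_sequences()].
#' @param exclude_zero,exclude_errors exclusions applied to the mean-k
#'   computation (not to the time sum).
#' @param timeout_s displays whose span exceeds this are flagged.
#' @return one row per display: `total_s`, `mean_k_display`, `n_sequences`,
#'   `truncated`.
#' @export
completion_times <- function(scored, exclude_zero = TRUE,
                             exclude_errors = TRUE, timeout_s = 45) {
  scored <- as.data.table(scored)
  key <- c("participant", "session", "run", "condition_deg", "display")
  inc <- scored
  if (exclude_errors)
    inc <- inc[has_identity_error == FALSE & has_location_error == FALSE]
  if (exclude_zero) inc <- inc[k > 0L]
  mk <- inc[, .(mean_k_display = mean(k)), by = key]
  ct <- scored[, .(total_s = sum(duration_s), n_sequences = .N,
                   truncated = any(truncated)), by = key]
  ct[mk, mean_k_display := i.mean_k_display, on = key]
  ct[, timed_out := total_s > timeout_s + 1e-9]
  ct[]
}
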