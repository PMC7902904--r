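# Features-in-memory scoring: per-sequence feature counts, per-display
# tallies, per-condition probability tables, and error rates.
#
# One feature = one unit of information acted upon before gaze returned to
# the model: an object's identity (evidenced by a non-corrective pickup of
# a model object) or its location (evidenced by a non-corrective correct
# placement).  Corrective actions and distractor pickups earn nothing but
# set error flags.

#' Count the features used in one sequence
#'
#' @param events event table (rows of one sequence) with columns `kind`,
#'   `is_model_object`, `correct_location`, `is_corrective`.
#' @return list with `k`, `n_identity`, `n_location`.
#' @export
count_features <- function(events) {
  events <- as.data.table(events)
  n_id <- sum(events$kind == "PICKUP" & events$is_model_object &
                !events$is_corrective)
  n_loc <- sum(events$kind == "PLACE" & !events$is_corrective &
                 events$correct_location %in% TRUE)
  list(k = n_id + n_loc, n_identity = n_id, n_location = n_loc)
}

#' Score sequences with feature counts and error flags
#'
#' @param sequences table from [segment_sequences()].
#' @param events events with `seq_id`, from [assign_actions()].
#' @return the sequence table with columns added: `n_identity`,
#'   `n_location`, `k` (= identity + location), `n_pickups`, `n_places`,
#'   `has_identity_error` (any non-corrective pickup of a non-model
#'   object), `has_location_error` (any non-corrective incorrect placement
#'   of a model object).
#' @export
score_sequences <- function(sequences, events) {
  sequences <- as.data.table(sequences)
  events <- as.data.table(events)
  key <- c("participant", "run", "display", "seq_id")
  if (nrow(events) > 0) {
    per_seq <- events[, .(
      n_identity = sum(kind == "PICKUP" & is_model_object & !is_corrective),
      n_location = sum(kind == "PLACE" & !is_corrective &
                         correct_location %in% TRUE),
      n_pickups = sum(kind == "PICKUP"),
      n_places = sum(kind == "PLACE"),
      has_identity_error = any(kind == "PICKUP" & !is_model_object &
                                 !is_corrective),
      has_location_error = any(kind == "PLACE" & is_model_object &
                                 !is_corrective & correct_location %in% FALSE)
    ), by = key]
    scored <- merge(sequences, per_seq, by = key, all.x = TRUE, sort = FALSE)
  } else {
    scored <- copy(sequences)
    scored[, `:=`(n_identity = NA_integer_, n_location = NA_integer_,
                  n_pickups = NA_integer_, n_places = NA_integer_,
                  has_identity_error = NA, has_location_error = NA)]
  }
  for (col in c("n_identity", "n_location", "n_pickups", "n_places"))
    scored[is.na(get(col)), (col) := 0L]
  for (col in c("has_identity_error", "has_location_error"))
    scored[is.na(get(col)), (col) := FALSE]
  scored[, k := n_identity + n_location]
  setorderv(scored, c("participant", "run", "display", "seq_id"))
  scored[]
}

#' Per-display feature tallies
#'
#' Sums credited features over each display's sequences and checks the
#' conservation identity: a completed display contributes 2 features per
#' object (identity + location), i.e. 16 for the standard 8-object display,
#' provided no features were lost to errors (corrective placements are
#' never credited).
#'
#' @param scored table from [score_sequences()].
#' @param events event table (used to determine completion: every model
#'   object of the display has a correct placement).
#' @param features_per_display expected total for a clean complete display.
#' @return one row per display: `total_features`, `n_sequences`, `complete`,
#'   `error_free`, `truncated`.
#' @export
tally_displays <- function(scored, events, features_per_display = 16L) {
  scored <- as.data.table(scored)
  events <- as.data.table(events)
  key <- c("participant", "session", "run", "condition_deg", "display")
  tal <- scored[, .(
    total_features = sum(k),
    n_sequences = .N,
    error_free = !any(has_identity_error) && !any(has_location_error),
    truncated = any(truncated)
  ), by = key]
  done <- events[kind == "PLACE" & is_model_object & correct_location %in% TRUE,
                 .(n_placed = uniqueN(object_id)),
                 by = c("participant", "run", "display")]
  tal[, complete := FALSE]
  tal[done, complete := i.n_placed >= features_per_display / 2L,
      on = c("participant", "run", "display")]
  bad <- tal[complete & error_free & !truncated &
               total_features != features_per_display]
  if (nrow(bad) > 0)
    stop("internal consistency error: ", nrow(bad), " complete, error-free ",
         "display(s) do not total ", features_per_display, " features",
         call. = FALSE)
  tal[]
}

#' Per-condition feature-count probability table
#'
#' Computes, per participant x condition, the percentage of sequences using
#' each number of features, and the mean count.  By default 0-feature
#' sequences, truncated sequences and error-flagged sequences are excluded
#' from the table (each exclusion has a switch); counts above `k_cap` are
#' pooled into a `">4"` bin for reporting but retained at face value in
#' `mean_k`.
#'
#' @param scored table from [score_sequences()].
#' @param exclude_zero drop k = 0 sequences from the denominators.
#' @param exclude_errors drop error-flagged sequences.
#' @param exclude_truncated drop truncated sequences.
#' @param k_cap largest individually reported count.
#' @return list with `cells` (participant x condition x k_bin percentages,
#'   plus `mean_k` and `n_seq` per cell), and `group` (unweighted mean over
#'   participants per condition x k_bin).  Cells with zero sequences are
#'   excluded with a warning.
#' @export
feature_probabilities <- function(scored, exclude_zero = TRUE,
                                  exclude_errors = TRUE,
                                  exclude_truncated = TRUE,
                                  k_cap = 4L) {
  scored <- as.data.table(scored)
  inc <- scored
  if (exclude_truncated) inc <- inc[truncated == FALSE]
  if (exclude_errors)
    inc <- inc[has_identity_error == FALSE & has_location_error == FALSE]
  if (exclude_zero) inc <- inc[k > 0L]
  if (nrow(inc) == 0) stop("no sequences left after exclusions", call. = FALSE)

  inc[, k_bin := fifelse(k > k_cap, paste0(">", k_cap), as.character(k))]
  bins <- c(as.character(if (exclude_zero) 1L:k_cap else 0L:k_cap),
            paste0(">", k_cap))
  cells <- inc[, {
    n <- .N
    cnt <- table(factor(k_bin, levels = bins))
    list(k_bin = bins, pct = as.numeric(cnt) / n * 100,
         mean_k = mean(k), n_seq = n)
  }, by = .(participant, condition_deg)]

  all_cells <- CJ(participant = unique(scored$participant),
                  condition_deg = unique(scored$condition_deg))
  have <- unique(cells[, .(participant, condition_deg)])
  missing_cells <- all_cells[!have, on = c("participant", "condition_deg")]
  if (nrow(missing_cells) > 0)
    warning(nrow(missing_cells),
            " participant x condition cell(s) have no sequences; excluded")

  group <- cells[, .(pct = mean(pct)), by = .(condition_deg, k_bin)]
  group_mean <- cells[k_bin == bins[1],
                      .(mean_k = mean(mean_k), n_seq_total = sum(n_seq)),
                      by = condition_deg]
  group <- merge(group, group_mean, by = "condition_deg")
  setorderv(group, c("condition_deg", "k_bin"))
  list(cells = cells[], group = group[])
}

#' Sequence-level error rates
#'
#' Percentage of sequences flagged with an identity error (a distractor was
#' picked up), a location error (a model object was misplaced), or either.
#' Truncated sequences are excluded from the denominator.
#'
#' @param scored table from [score_sequences()].
#' @param by optional character vector of grouping columns.
#' @return data.table with `identity_pct`, `location_pct`, `any_pct` and the
#'   denominator `n_seq`.
#' @export
error_rates <- function(scored, by = NULL) {
  scored <- as.data.table(scored)[truncated == FALSE]
  out <- scored[, .(
    identity_pct = mean(has_identity_error) * 100,
    location_pct = mean(has_location_error) * 100,
    any_pct = mean(has_identity_error | has_location_error) * 100,
    n_seq = .N
  ), by = by]
  out[]
}
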