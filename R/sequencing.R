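# Segmentation of each display's gaze stream into model-to-model sequences.
#
# A sequence opens at a gaze sample on the model and closes at the next
# model view that satisfies the qualification rule; the closing view
# simultaneously opens the next sequence, so adjacent sequences share their
# boundary view.  Closure can be decided per model view: a model view
# closes the open sequence exactly when at least one qualifying-area visit
# occurred since the *previous* model view (if none had occurred since the
# sequence's opening view, none occurred since the previous merged view
# either).

#' Segment AOI visits into sequences
#'
#' @param visits visit table from [compress_visits()].
#' @param rule which interludes let a model re-view close the sequence:
#'   `"resource_or_workspace"` (default) requires at least one resource *or*
#'   workspace visit between the two model views; `"resource"` requires a
#'   resource visit (workspace-only interludes then merge into the open
#'   sequence).  `OTHER` samples never qualify under either rule.
#' @param frame_rate_hz frame rate, used for durations.
#' @return data.table with one row per sequence: display keys, `seq_id`,
#'   `start_s`/`end_s` (the boundary model views' start times, so spans tile
#'   the display), `start_frame`/`end_frame`, `duration_s`,
#'   `initial_model_dwell_ms` (summed model gaze from the opening view up to
#'   the first resource visit), `qualifying` and `truncated` flags.
#'   Displays without any model view contribute no rows (with a warning).
#' @export
segment_sequences <- function(visits,
                              rule = c("resource_or_workspace", "resource"),
                              frame_rate_hz = 90) {
  rule <- match.arg(rule)
  qualify_set <- if (rule == "resource") "RESOURCE"
                 else c("RESOURCE", "WORKSPACE")
  visits <- as.data.table(visits)
  empty <- data.table(participant = integer(), session = integer(),
                      run = integer(), condition_deg = integer(),
                      display = integer(), seq_id = integer(),
                      start_s = numeric(), end_s = numeric(),
                      start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(),
                      initial_model_dwell_ms = numeric(),
                      qualifying = logical(), truncated = logical())
  if (nrow(visits) == 0) return(empty)
  visits <- visits[order(participant, run, display, visit_id)]

  no_model <- visits[, .(has_model = any(aoi == "MODEL")),
                     by = .(participant, run, display)][has_model == FALSE]
  if (nrow(no_model) > 0)
    warning(nrow(no_model), " display(s) contain no model view; ",
            "they yield zero sequences")

  seqs <- visits[, {
    m_pos <- which(aoi == "MODEL")
    if (length(m_pos) == 0) {
      NULL
    } else {
      # which model views close a sequence: a qualifying visit occurred
      # since the previous model view
      m_count <- cumsum(aoi == "MODEL")
      qual_after <- unique(m_count[aoi %in% qualify_set])
      closes <- logical(length(m_pos))
      if (length(m_pos) > 1)
        closes[-1] <- (m_count[m_pos[-1]] - 1L) %in% qual_after
      bounds <- m_pos[c(TRUE, closes[-1])]
      n_closed <- sum(closes)
      # trailing activity after the last boundary view?
      last_b <- bounds[length(bounds)]
      trailing <- last_b < length(aoi)    # any visit after the boundary view
      n_seq <- n_closed + as.integer(trailing)
      if (n_seq == 0) {
        NULL
      } else {
        open_pos <- bounds[seq_len(n_seq)]
        close_pos <- if (trailing) c(bounds[-1], NA_integer_) else bounds[-1]
        s_frame <- start_frame[open_pos]
        s_time <- start_s[open_pos]
        e_frame <- ifelse(is.na(close_pos), end_frame[length(end_frame)],
                          start_frame[close_pos])
        e_time <- ifelse(is.na(close_pos), end_s[length(end_s)],
                         start_s[close_pos])
        # initial model dwell: model visits from the opening view up to the
        # first resource visit (workspace/other interludes neither end nor
        # extend it), bounded by the closing view
        dwell <- vapply(seq_len(n_seq), function(i) {
          lo <- open_pos[i]
          hi <- if (is.na(close_pos[i])) length(aoi) else close_pos[i] - 1L
          span <- lo:hi
          r <- which(aoi[span] == "RESOURCE")
          if (length(r) > 0) span <- span[seq_len(r[1] - 1L)]
          sum(n_frames[span][aoi[span] == "MODEL"]) / frame_rate_hz * 1000
        }, numeric(1))
        list(seq_id = seq_len(n_seq),
             start_s = s_time, end_s = e_time,
             start_frame = s_frame, end_frame = e_frame,
             duration_s = e_time - s_time,
             initial_model_dwell_ms = dwell,
             qualifying = c(rep(TRUE, n_closed), rep(FALSE, as.integer(trailing))),
             truncated = c(rep(FALSE, n_closed), rep(TRUE, as.integer(trailing))))
      }
    }
  }, by = .(participant, session, run, condition_deg, display)]
  if (nrow(seqs) == 0) return(empty)
  seqs[]
}

#' Attach action events to sequences
#'
#' Each event is assigned by its timestamp to the sequence whose half-open
#' span `(start, end]` contains it; events at a shared boundary therefore
#' belong to the closing (earlier) sequence.  Events before the first
#' sequence attach to the first sequence and events after the last boundary
#' attach to the trailing (truncated) sequence; both cases are flagged
#' `out_of_span`.
#'
#' @param sequences table from [segment_sequences()].
#' @param events table from [derive_events()].
#' @return the events table with `seq_id` and `out_of_span` columns added.
#' @export
assign_actions <- function(sequences, events) {
  sequences <- as.data.table(sequences)
  events <- copy(as.data.table(events))
  if (nrow(events) == 0) {
    events[, `:=`(seq_id = integer(), out_of_span = logical())]
    return(events)
  }
  events[, `:=`(seq_id = NA_integer_, out_of_span = FALSE)]
  key <- c("participant", "run", "display")
  seq_split <- split(sequences, by = key, keep.by = TRUE)
  ev_split <- split(seq_len(nrow(events)), events[, key, with = FALSE])
  for (nm in names(ev_split)) {
    idx <- ev_split[[nm]]
    sq <- seq_split[[nm]]
    if (is.null(sq) || nrow(sq) == 0) next
    t <- events$time_s[idx]
    # (start, end]: find the first sequence with end >= t and start < t
    pos <- findInterval(t, sq$start_s, left.open = TRUE)  # last start < t...
    pos <- pmax(pos, 1L)
    # events exactly at or before the first start, or beyond the last end
    oos <- t <= sq$start_s[1] | t > sq$end_s[nrow(sq)]
    pos <- pmin(pos, nrow(sq))
    events[idx, `:=`(seq_id = sq$seq_id[pos], out_of_span = oos)]
  }
  events[]
}
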