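# Frame-log IO, validation, run-length encoding of gaze, and derivation of
# controller action events.

#' Write a frame log to CSV
#'
#' Writes the fixed dialect: header
#' `participant,session,run,condition_deg,display,frame,time_s,aoi,gazed_object,controller_event,held_object,placement_cell,placement_correct`,
#' UTF-8, `.` decimal separator, `NA` for missing values.
#'
#' @param frames a frame-log data.frame/data.table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(frames, path) {
  frames <- as.data.table(frames)
  missing_cols <- setdiff(FRAME_LOG_COLUMNS, names(frames))
  if (length(missing_cols) > 0)
    stop("frame log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  fwrite(frames[, FRAME_LOG_COLUMNS, with = FALSE], path, na = "NA",
         quote = FALSE)
  invisible(path)
}

#' Write the ground-truth sequence ledger to CSV
#' @param ledger ledger table from [simulate_experiment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  fwrite(as.data.table(ledger), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Write the display manifest to CSV
#' @param displays manifest table (`displays` element of a `wm_sim`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(displays, path) {
  fwrite(as.data.table(displays), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a display manifest CSV
#' @param path manifest file written by [write_manifest()].
#' @return data.table with one row per object per display.
#' @export
read_manifest <- function(path) {
  fread(path, na.strings = "NA",
        colClasses = list(integer = c("participant", "session", "run",
                                      "condition_deg", "display",
                                      "object_id", "cell"),
                          character = "role"))
}

#' Read and validate a frame log
#'
#' Parses a CSV in the package dialect and validates the frame-log
#' invariants: required columns, strictly increasing time within each
#' display, pickups only with free hands, releases only while holding.
#' Violations raise errors citing the offending row.
#'
#' @param path CSV file.
#' @param validate run invariant checks (default TRUE).
#' @return a frame-log data.table.
#' @export
read_frame_log <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(fread(path, nrows = 0))
  missing_cols <- setdiff(FRAME_LOG_COLUMNS, hdr)
  if (length(missing_cols) > 0)
    stop("schema error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames <- fread(path, na.strings = "NA",
                  colClasses = list(
                    integer = c("participant", "session", "run",
                                "condition_deg", "display", "frame",
                                "gazed_object", "held_object",
                                "placement_cell"),
                    double = "time_s",
                    character = c("aoi", "controller_event"),
                    logical = "placement_correct"))
  missing_cols <- setdiff(FRAME_LOG_COLUMNS, names(frames))
  if (length(missing_cols) > 0)
    stop("schema error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(frames) == 0) {
    warning("frame log is empty (zero rows)")
    return(frames)
  }
  if (validate) validate_frame_log(frames)
  frames
}

#' Validate frame-log invariants
#'
#' @param frames frame-log table.
#' @return TRUE invisibly; errors on the first violation, naming the row.
#' @export
validate_frame_log <- function(frames) {
  frames <- as.data.table(frames)
  if (!all(frames$aoi %in% AOI_LEVELS))
    stop("integrity error: unknown aoi label at row ",
         which(!frames$aoi %in% AOI_LEVELS)[1], call. = FALSE)
  if (!all(frames$controller_event %in% c("NONE", "PICKUP", "RELEASE")))
    stop("integrity error: unknown controller_event at row ",
         which(!frames$controller_event %in%
                 c("NONE", "PICKUP", "RELEASE"))[1], call. = FALSE)
  frames[, {
    dt <- diff(time_s)
    if (length(dt) > 0 && any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop("integrity error: non-monotone time within display (participant ",
           participant[1], ", run ", run[1], ", display ", display[1],
           ", frame ", frame[bad], ")", call. = FALSE)
    }
    prev_held <- shift(held_object)
    bad_pick <- which(controller_event == "PICKUP" & !is.na(prev_held))
    if (length(bad_pick) > 0)
      stop("integrity error: PICKUP while already holding an object ",
           "(participant ", participant[1], ", run ", run[1], ", display ",
           display[1], ", frame ", frame[bad_pick[1]], ")", call. = FALSE)
    bad_rel <- which(controller_event == "RELEASE" & is.na(held_object))
    if (length(bad_rel) > 0)
      stop("integrity error: RELEASE while holding nothing ",
           "(participant ", participant[1], ", run ", run[1], ", display ",
           display[1], ", frame ", frame[bad_rel[1]], ")", call. = FALSE)
    NULL
  }, by = .(participant, run, display)]
  invisible(TRUE)
}

#' Run-length encode gaze into AOI visits
#'
#' Collapses consecutive frames with the same AOI label into visits, per
#' display.  Visit duration is the number of frames times the frame period,
#' so the visit durations of a display sum exactly to its recorded span.
#'
#' @param frames frame-log table.
#' @param frame_rate_hz sampling rate used to convert frame counts to time.
#' @return data.table of visits: display keys, `visit_id`, `aoi`,
#'   `start_s`, `end_s`, `n_frames`, `start_frame`, `end_frame`.
#' @export
compress_visits <- function(frames, frame_rate_hz = 90) {
  frames <- as.data.table(frames)
  if (nrow(frames) == 0)
    return(data.table(participant = integer(), session = integer(),
                      run = integer(), condition_deg = integer(),
                      display = integer(), visit_id = integer(),
                      aoi = character(), start_s = numeric(),
                      end_s = numeric(), n_frames = integer(),
                      start_frame = integer(), end_frame = integer()))
  frames <- frames[order(participant, run, display, frame)]
  frames[, visit_id := rleid(aoi), by = .(participant, run, display)]
  visits <- frames[, .(aoi = aoi[1], start_s = time_s[1],
                       n_frames = .N, start_frame = frame[1],
                       end_frame = frame[.N]),
                   by = .(participant, session, run, condition_deg, display,
                          visit_id)]
  visits[, end_s := start_s + n_frames / frame_rate_hz]
  visits[]
}

#' Derive controller action events from a frame log
#'
#' Emits one `PICKUP` per pickup frame and one `PLACE` per release frame
#' that carries a placement cell; releases without a cell are dropped
#' objects (they re-spawn) and produce no event.  Corrective actions are
#' identified from the placement history: re-pickups of a misplaced object
#' are emitted as kind `REMOVE`, and any placement of an object that is
#' currently misplaced is flagged `is_corrective`.
#'
#' @param frames validated frame-log table.
#' @param manifest display manifest giving each object's role (model /
#'   distractor); used to set `is_model_object`.  If NULL, model membership
#'   is inferred as "was ever placed correctly", which is only safe on
#'   error-free logs.
#' @return data.table of events: display keys, `time_s`, `frame`, `kind`
#'   (`PICKUP`/`PLACE`/`REMOVE`), `object_id`, `is_model_object`,
#'   `placement_cell`, `correct_location`, `is_corrective`.
#' @export
derive_events <- function(frames, manifest = NULL) {
  frames <- as.data.table(frames)
  ev <- frames[controller_event != "NONE",
               .(participant, session, run, condition_deg, display, frame,
                 time_s, controller_event, held_object, placement_cell,
                 placement_correct)]
  if (nrow(ev) == 0) {
    return(data.table(participant = integer(), session = integer(),
                      run = integer(), condition_deg = integer(),
                      display = integer(), frame = integer(),
                      time_s = numeric(), kind = character(),
                      object_id = integer(), is_model_object = logical(),
                      placement_cell = integer(),
                      correct_location = logical(),
                      is_corrective = logical()))
  }
  ev[, object_id := held_object]
  # RELEASE without a cell is a dropped object (it re-spawns) -> no event
  ev <- ev[controller_event == "PICKUP" |
             (controller_event == "RELEASE" & !is.na(placement_cell))]
  ev[, kind := fifelse(controller_event == "PICKUP", "PICKUP", "PLACE")]
  ev[, correct_location := fifelse(kind == "PLACE", placement_correct, NA)]

  # corrective flags: walk each object's event history within a display.
  # `wrong_down`: the object is sitting misplaced right now; `pending`: it
  # has an unresolved incorrect placement in its history.
  ev <- ev[order(participant, run, display, frame)]
  ev[, is_corrective := FALSE]
  ev[, c("kind", "is_corrective") := {
    k <- kind; corr <- rep(FALSE, .N)
    wrong_down <- FALSE; pending <- FALSE
    for (i in seq_len(.N)) {
      if (k[i] == "PLACE") {
        corr[i] <- pending
        ok <- !is.na(correct_location[i]) && correct_location[i]
        wrong_down <- !ok
        pending <- if (ok) FALSE else TRUE
      } else {                        # PICKUP
        if (wrong_down) { k[i] <- "REMOVE"; corr[i] <- TRUE; wrong_down <- FALSE }
      }
    }
    list(k, corr)
  }, by = .(participant, run, display, object_id)]

  if (!is.null(manifest)) {
    manifest <- as.data.table(manifest)
    ev[manifest, is_model_object := i.role == "model",
       on = c("participant", "run", "display", "object_id")]
    ev[is.na(is_model_object), is_model_object := FALSE]
  } else {
    placed_ok <- ev[kind == "PLACE" & correct_location %in% TRUE,
                    unique(.SD), .SDcols = c("participant", "run", "display",
                                             "object_id")]
    ev[, is_model_object := FALSE]
    ev[placed_ok, is_model_object := TRUE,
       on = c("participant", "run", "display", "object_id")]
  }
  ev[, .(participant, session, run, condition_deg, display, frame, time_s,
         kind, object_id, is_model_object, placement_cell, correct_location,
         is_corrective)]
}
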