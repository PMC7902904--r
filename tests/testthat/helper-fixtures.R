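# Fixtures are built in code: tiny hand-written frame logs, and an
# independent brute-force scorer used as the oracle for the segmentation +
# scoring pipeline.

library(data.table)

# Build a frame log from a compact visit description.
# visits: list of lists(aoi, n, [event, object, cell, correct, held]) --
# `held` is the object in hand during the block (NA default); events fire
# on the block's last frame.
make_frames <- function(visits, participant = 1L, session = 1L, run = 1L,
                        condition_deg = 0L, display = 1L, fr = 90) {
  rows <- list()
  frame0 <- 0L
  for (v in visits) {
    n <- v$n
    ev <- if (!is.null(v$event)) v$event else NA_character_
    held <- if (!is.null(v$held)) v$held else NA_integer_
    obj <- if (!is.null(v$object)) v$object else NA_integer_
    cell <- if (!is.null(v$cell)) v$cell else NA_integer_
    correct <- if (!is.null(v$correct)) v$correct else NA
    held_body <- held
    held_last <- held
    if (!is.na(ev) && ev == "PICKUP") { held_body <- NA_integer_; held_last <- obj }
    if (!is.na(ev) && ev == "RELEASE") { held_body <- obj; held_last <- obj }
    dt <- data.table(
      participant = participant, session = session, run = run,
      condition_deg = condition_deg, display = display,
      frame = frame0 + seq_len(n),
      aoi = v$aoi,
      gazed_object = NA_integer_,
      controller_event = c(rep("NONE", n - 1L), if (is.na(ev)) "NONE" else ev),
      held_object = c(rep(held_body, n - 1L), held_last),
      placement_cell = c(rep(NA_integer_, n - 1L),
                         if (!is.na(ev) && ev == "RELEASE") cell else NA_integer_),
      placement_correct = c(rep(NA, n - 1L),
                            if (!is.na(ev) && ev == "RELEASE") correct else NA))
    rows[[length(rows) + 1L]] <- dt
    frame0 <- frame0 + n
  }
  out <- rbindlist(rows)
  out[, time_s := (frame - 1) / fr]
  setcolorder(out, c("participant", "session", "run", "condition_deg",
                     "display", "frame", "time_s", "aoi", "gazed_object",
                     "controller_event", "held_object", "placement_cell",
                     "placement_correct"))
  out[]
}

# Independent brute-force scorer: walks one display's raw frames, splits at
# qualifying model views, and recounts credited features with its own
# placement-state bookkeeping.  Deliberately a second implementation.
oracle_score_display <- function(frames_disp, model_ids,
                                 rule = c("resource_or_workspace",
                                          "resource")) {
  rule <- match.arg(rule)
  qual <- if (rule == "resource") "RESOURCE" else c("RESOURCE", "WORKSPACE")
  aoi <- frames_disp$aoi
  r <- rle(aoi)
  v_aoi <- r$values
  v_end <- cumsum(r$lengths)
  v_start <- v_end - r$lengths + 1L

  m <- which(v_aoi == "MODEL")
  if (length(m) == 0L) return(NULL)
  bounds <- m[1]
  seen_q <- FALSE
  for (i in seq_along(v_aoi)) {
    if (i <= m[1]) next
    if (v_aoi[i] %in% qual) seen_q <- TRUE
    if (v_aoi[i] == "MODEL" && seen_q) { bounds <- c(bounds, i); seen_q <- FALSE }
  }
  trailing <- tail(bounds, 1) < length(v_aoi)
  n_seq <- length(bounds) - 1L + as.integer(trailing)
  if (n_seq == 0L) return(NULL)

  # event frames with their own corrective tracking
  evf <- which(frames_disp$controller_event != "NONE")
  misplaced <- integer(0)        # object ids sitting misplaced
  pending <- integer(0)          # objects with unresolved wrong placement
  out <- data.frame(seq_id = seq_len(n_seq), k = 0L,
                    id_err = FALSE, loc_err = FALSE,
                    truncated = c(rep(FALSE, length(bounds) - 1L),
                                  rep(TRUE, as.integer(trailing))))
  seq_of_frame <- function(f) {
    # sequence spans: (start frame of bound i, start frame of bound i+1]
    starts <- v_start[bounds]
    idx <- findInterval(f, starts + 0.5)   # f > starts[idx]
    min(max(idx, 1L), n_seq)
  }
  for (f in evf) {
    s <- seq_of_frame(f)
    ev <- frames_disp$controller_event[f]
    obj <- frames_disp$held_object[f]
    if (ev == "PICKUP") {
      if (obj %in% misplaced) {            # corrective removal
        misplaced <- setdiff(misplaced, obj)
      } else if (obj %in% model_ids) {
        out$k[s] <- out$k[s] + 1L
      } else {
        out$id_err[s] <- TRUE
      }
    } else {                               # RELEASE
      cell <- frames_disp$placement_cell[f]
      if (is.na(cell)) next                # dropped object
      ok <- isTRUE(frames_disp$placement_correct[f])
      if (obj %in% pending) {              # corrective placement
        if (ok) pending <- setdiff(pending, obj)
        if (!ok) misplaced <- union(misplaced, obj)
      } else if (ok) {
        out$k[s] <- out$k[s] + 1L
      } else {
        if (obj %in% model_ids) out$loc_err[s] <- TRUE
        misplaced <- union(misplaced, obj)
        pending <- union(pending, obj)
      }
    }
  }
  out
}

# convenience: small full simulation shared across tests
small_sim <- function(n_participants = 1L, seed = 11L, policy = agent_policy(),
                      runs = 4L, displays = 2L) {
  simulate_experiment(
    sim_config(n_participants = n_participants, runs_per_participant = runs,
               displays_per_run = displays),
    policy, seed = seed)
}
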