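# Agent-based simulator of the immersive object-copying task.
#
# The agent alternates model visits (encoding), resource visits (search +
# pickup) and workspace visits (placement).  Everything downstream of the
# simulator consumes only the frame-log dialect, so the simulator is the
# package's stand-in for raw task recordings.

#' Task geometry
#'
#' Physical layout of the virtual room.  Only the model angle affects the
#' simulated behavior (through travel times); area sizes are carried as
#' metadata.
#'
#' @param room_side_cm side length of the square room, cm.
#' @param model_area_cm,workspace_area_cm,resource_area_cm width/height, cm.
#' @param object_side_cm side of the cubic objects, cm.
#' @return an object of class `wm_geometry`.
#' @export
task_geometry <- function(room_side_cm = 450,
                          model_area_cm = c(120, 60),
                          workspace_area_cm = c(100, 50),
                          resource_area_cm = c(120, 75),
                          object_side_cm = 10) {
  sizes <- c(room_side_cm, model_area_cm, workspace_area_cm,
             resource_area_cm, object_side_cm)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all geometry sizes must be positive", call. = FALSE)
  structure(list(room_side_cm = room_side_cm,
                 model_area_cm = model_area_cm,
                 workspace_area_cm = workspace_area_cm,
                 resource_area_cm = resource_area_cm,
                 object_side_cm = object_side_cm),
            class = "wm_geometry")
}

#' Default features-per-visit distribution
#'
#' Probability of encoding k = 1..4 features per model visit, one row per
#' locomotion condition.  The defaults place 60% of one-feature visits at
#' 0 degrees and 10% of four-feature visits at 135 degrees, with the
#' remaining mass allocated so that mean usage grows roughly linearly with
#' angular separation.
#'
#' @return a 4 x 4 matrix, rows named by condition, columns `k1`..`k4`.
#' @export
default_features_pmf <- function() {
  m <- rbind(`0`   = c(0.60, 0.29, 0.10, 0.01),
             `45`  = c(0.50, 0.35, 0.13, 0.02),
             `90`  = c(0.40, 0.39, 0.16, 0.05),
             `135` = c(0.29, 0.45, 0.16, 0.10))
  colnames(m) <- paste0("k", 1:4)
  m
}

#' Agent behavioral policy
#'
#' Parameters governing the simulated participant: how many features are
#' encoded per model visit, how often unproductive (0-feature) sequences
#' occur, per-sequence error-injection probabilities, and the time model.
#' All durations are drawn from log-normal distributions whose *means* are
#' the stated values (`lognormal_sigma` is the log-scale SD).
#'
#' @param features_pmf matrix of per-condition probabilities over k = 1..n
#'   features per visit (rows must match the four conditions and sum to 1).
#' @param zero_feature_rate probability that any given sequence is an
#'   unproductive model-resource-model interlude with no action.
#' @param identity_error_rate per-sequence probability of picking up a
#'   distractor object (immediately corrected).
#' @param location_error_rate per-sequence probability of misplacing a model
#'   object (immediately corrected).
#' @param encode_base_ms,encode_slope_ms mean initial model dwell is
#'   `encode_base_ms + encode_slope_ms * k` milliseconds.
#' @param encode_condition_gain multiplicative dwell increase per condition
#'   rank (dwell means scale by `1 + gain * (rank - 1)`).
#' @param travel_base_s,travel_span_s mean travel time for a leg touching the
#'   model area: `travel_base_s + travel_span_s * angle/135` seconds.
#' @param cross_travel_s mean resource-workspace travel leg, seconds.
#' @param search_time_s mean resource search time per pickup, seconds.
#' @param place_time_s mean workspace aiming time per placement, seconds.
#' @param correction_time_s mean duration of each corrective action, seconds.
#' @param glance_ms mean duration of the model glance that closes the final
#'   sequence of a display, milliseconds.
#' @param lognormal_sigma log-scale SD of all duration draws.
#' @param flicker_rate per-frame probability that a brief gaze flicker
#'   (1..`flicker_max_frames` frames relabelled WORKSPACE or OTHER) starts;
#'   0 disables the noise layer.
#' @param flicker_max_frames maximum flicker length in frames.
#' @return an object of class `wm_policy`.
#' @export
agent_policy <- function(features_pmf = default_features_pmf(),
                         zero_feature_rate = 0.10,
                         identity_error_rate = 0.018,
                         location_error_rate = 0.029,
                         encode_base_ms = 250,
                         encode_slope_ms = 150,
                         encode_condition_gain = 0.08,
                         travel_base_s = 0.35,
                         travel_span_s = 0.45,
                         cross_travel_s = 0.25,
                         search_time_s = 0.55,
                         place_time_s = 0.40,
                         correction_time_s = 0.30,
                         glance_ms = 300,
                         lognormal_sigma = 0.30,
                         flicker_rate = 0,
                         flicker_max_frames = 3) {
  features_pmf <- as.matrix(features_pmf)
  if (nrow(features_pmf) != length(CONDITIONS))
    stop("features_pmf needs one row per condition (", length(CONDITIONS), ")",
         call. = FALSE)
  if (any(features_pmf < 0) ||
      any(abs(rowSums(features_pmf) - 1) > 1e-8))
    stop("each features_pmf row must be a probability vector summing to 1",
         call. = FALSE)
  rates <- c(zero_feature_rate, identity_error_rate, location_error_rate,
             flicker_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  times <- c(encode_base_ms, travel_base_s, cross_travel_s, search_time_s,
             place_time_s, correction_time_s, glance_ms)
  if (any(times <= 0) || encode_slope_ms < 0 || travel_span_s < 0)
    stop("time parameters must be positive", call. = FALSE)
  structure(list(features_pmf = features_pmf,
                 zero_feature_rate = zero_feature_rate,
                 identity_error_rate = identity_error_rate,
                 location_error_rate = location_error_rate,
                 encode_base_ms = encode_base_ms,
                 encode_slope_ms = encode_slope_ms,
                 encode_condition_gain = encode_condition_gain,
                 travel_base_s = travel_base_s,
                 travel_span_s = travel_span_s,
                 cross_travel_s = cross_travel_s,
                 search_time_s = search_time_s,
                 place_time_s = place_time_s,
                 correction_time_s = correction_time_s,
                 glance_ms = glance_ms,
                 lognormal_sigma = lognormal_sigma,
                 flicker_rate = flicker_rate,
                 flicker_max_frames = flicker_max_frames),
            class = "wm_policy")
}

#' Experiment-level simulation configuration
#'
#' @param n_participants number of simulated participants.
#' @param runs_per_participant runs per participant; must be a multiple of 4
#'   so every condition occurs equally often (run-wise manipulation).
#' @param displays_per_run displays per run.
#' @param objects_per_display model objects per display.
#' @param distractors_per_display additional resource-only objects.
#' @param pool_size size of the object stimulus pool.
#' @param display_timeout_s hard per-display timeout, seconds.
#' @param frame_rate_hz sampling rate of the frame log.
#' @return an object of class `wm_config`.
#' @export
sim_config <- function(n_participants = 24,
                       runs_per_participant = 8,
                       displays_per_run = 14,
                       objects_per_display = 8,
                       distractors_per_display = 16,
                       pool_size = 60,
                       display_timeout_s = 45,
                       frame_rate_hz = 90) {
  counts <- c(n_participants, runs_per_participant, displays_per_run,
              objects_per_display, distractors_per_display, pool_size)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers", call. = FALSE)
  if (runs_per_participant %% length(CONDITIONS) != 0)
    stop("runs_per_participant must be a multiple of ", length(CONDITIONS),
         " so each condition fills whole runs", call. = FALSE)
  if (pool_size < objects_per_display + distractors_per_display)
    stop("pool_size must cover model objects plus distractors", call. = FALSE)
  if (display_timeout_s <= 0 || frame_rate_hz <= 0)
    stop("timeout and frame rate must be positive", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 runs_per_participant = as.integer(runs_per_participant),
                 displays_per_run = as.integer(displays_per_run),
                 objects_per_display = as.integer(objects_per_display),
                 distractors_per_display = as.integer(distractors_per_display),
                 pool_size = as.integer(pool_size),
                 display_timeout_s = display_timeout_s,
                 frame_rate_hz = frame_rate_hz),
            class = "wm_config")
}

#' Draw one display specification
#'
#' Samples the model objects, the distractors and the model-cell assignment
#' from the stimulus pool, using the current RNG state (seed management is
#' the caller's job, see [simulate_experiment()]).
#'
#' @param pool_size number of objects in the stimulus pool (ids `1:pool_size`).
#' @param n_model model objects per display.
#' @param n_distractor distractor objects added to the resource area.
#' @return an object of class `wm_display_spec` with fields `model_objects`,
#'   `distractor_objects`, `resource_objects`, `cells` (named cell assignment,
#'   a bijection of the model objects onto cells `1:n_model`) and `pool_size`.
#' @export
generate_display <- function(pool_size = 60, n_model = 8, n_distractor = 16) {
  if (pool_size < n_model + n_distractor)
    stop("pool_size must be at least n_model + n_distractor (",
         n_model + n_distractor, ")", call. = FALSE)
  model <- sample.int(pool_size, n_model)
  distr <- sample(setdiff(seq_len(pool_size), model), n_distractor)
  cells <- sample.int(n_model, n_model)
  structure(list(model_objects = model,
                 distractor_objects = distr,
                 resource_objects = c(model, distr),
                 cells = setNames(cells, model),
                 pool_size = as.integer(pool_size)),
            class = "wm_display_spec")
}

# mean-parameterised log-normal draw: E[X] = mean_x exactly
rlnorm_mean <- function(n, mean_x, sigma) {
  rlnorm(n, meanlog = log(mean_x) - sigma^2 / 2, sdlog = sigma)
}

# Exact pooled part-size distribution of i.i.d.-q compositions conditioned
# to sum to `budget` (renewal dynamic program): conditioning a display's
# visit loads on tiling the 16 features exactly size-biases the pooled
# per-sequence load distribution, so the proposal distribution q must be
# solved such that the *realized* distribution equals the configured pmf.
composition_part_dist <- function(q, budget) {
  u <- numeric(budget + 1)
  u[1] <- 1                              # u[m+1] = P(i.i.d.-q partial sums hit m)
  for (m in seq_len(budget)) {
    js <- seq_len(min(length(q), m))
    u[m + 1] <- sum(q[js] * u[m + 1 - js])
  }
  if (u[budget + 1] <= 0)
    stop("budget unreachable under the proposal pmf", call. = FALSE)
  en <- vapply(seq_along(q), function(j) {
    if (q[j] == 0 || j > budget) return(0)
    ms <- 0:(budget - j)
    sum(u[ms + 1] * q[j] * u[budget - ms - j + 1])
  }, numeric(1))
  en / sum(en)
}

# fixed-point calibration of the proposal pmf: returns q with
# composition_part_dist(q, budget) ~= target (exact up to tol for budgets
# large enough to realize the target at all)
calibrate_part_pmf <- function(target, budget, max_iter = 500L, tol = 1e-12) {
  q <- target
  for (i in seq_len(max_iter)) {
    d <- composition_part_dist(q, budget)
    if (max(abs(d - target)) < tol) break
    q <- q * ifelse(d > 0, target / d, 1)
    q <- q / sum(q)
  }
  q
}

.part_pmf_cache <- new.env(parent = emptyenv())

calibrated_part_pmf <- function(target, budget) {
  key <- paste0(budget, ":", paste(signif(target, 12), collapse = ","))
  got <- .part_pmf_cache[[key]]
  if (!is.null(got)) return(got)
  # small residual budgets (rare re-planned display tails) cannot realize an
  # arbitrary part distribution; fall back to the truncated target there
  trunc_target <- target
  if (length(trunc_target) > budget)
    trunc_target[seq_along(trunc_target) > budget] <- 0
  trunc_target <- trunc_target / sum(trunc_target)
  q <- if (budget >= 2L * length(target))
    tryCatch(calibrate_part_pmf(target, budget),
             error = function(e) trunc_target)
  else trunc_target
  .part_pmf_cache[[key]] <- q
  q
}

# i.i.d. visit loads from pmf, accepted only when they tile `budget` features
# exactly (rejection avoids the clipping bias a truncated last draw causes).
draw_composition <- function(budget, pmf, max_tries = 10000L) {
  if (budget <= 0L) return(integer(0))
  support <- seq_along(pmf)
  for (i in seq_len(max_tries)) {
    draws <- sample(support, size = budget, replace = TRUE, prob = pmf)
    cs <- cumsum(draws)
    n <- which(cs >= budget)[1L]
    if (cs[n] == budget) return(draws[seq_len(n)])
  }
  # degenerate pmf (e.g. no mass on small k): fall back to clipping once
  draws <- sample(support, size = budget, replace = TRUE, prob = pmf)
  cs <- cumsum(draws)
  n <- which(cs >= budget)[1L]
  draws[n] <- draws[n] - (cs[n] - budget)
  warning("composition rejection failed; last visit load clipped")
  draws[seq_len(n)]
}

# --- per-display realization ------------------------------------------------
#
# Builds the display's gaze/action stream at *segment* granularity (one row
# per homogeneous AOI block, controller events attached to the block's last
# frame) plus the ground-truth sequence ledger.  Frame expansion happens
# later, vectorised over the whole experiment.

new_seg_pool <- function() {
  list(seq = integer(), aoi = character(), dur_s = numeric(),
       gazed = integer(), event = character(), event_object = integer(),
       cell = integer(), correct = logical(),
       held_body = integer(), held_last = integer())
}

sim_display_segments <- function(spec, policy, condition_deg, config) {
  cond_idx <- match(condition_deg, CONDITIONS)
  pmf <- policy$features_pmf[cond_idx, ]
  sig <- policy$lognormal_sigma
  angle_frac <- condition_deg / max(CONDITIONS)
  t_model_leg <- policy$travel_base_s + policy$travel_span_s * angle_frac
  dwell_gain <- 1 + policy$encode_condition_gain * (cond_idx - 1)
  n_feat <- 2L * config$objects_per_display

  order_objs <- sample(spec$model_objects)
  obj_of_feature <- function(f) order_objs[(f + 1L) %/% 2L]

  plan <- draw_composition(n_feat, calibrated_part_pmf(pmf, n_feat))
  plan_i <- 1L
  consumed <- 0L
  held <- NA_integer_

  segs <- new_seg_pool()
  n_seg <- 0L
  add_seg <- function(seq, aoi, dur, gazed = NA_integer_,
                      event = NA_character_, event_object = NA_integer_,
                      cell = NA_integer_, correct = NA,
                      held_body = NA_integer_, held_last = NA_integer_) {
    n_seg <<- n_seg + 1L
    segs$seq[n_seg] <<- seq
    segs$aoi[n_seg] <<- aoi
    segs$dur_s[n_seg] <<- dur
    segs$gazed[n_seg] <<- gazed
    segs$event[n_seg] <<- event
    segs$event_object[n_seg] <<- event_object
    segs$cell[n_seg] <<- cell
    segs$correct[n_seg] <<- correct
    segs$held_body[n_seg] <<- held_body
    segs$held_last[n_seg] <<- held_last
  }

  led <- list()
  s <- 0L

  while (consumed < n_feat) {
    s <- s + 1L
    held_at_start <- held
    # unproductive trips happen when the hands are free (a carried object
    # always gives the agent something to do), which also keeps every
    # sequence eligible for a distractor pickup
    is_zero <- is.na(held) && runif(1) < policy$zero_feature_rate
    id_err <- runif(1) < policy$identity_error_rate
    loc_err <- runif(1) < policy$location_error_rate
    replan <- FALSE

    if (!is_zero && plan_i > length(plan)) {
      plan <- draw_composition(n_feat - consumed,
                               calibrated_part_pmf(pmf, n_feat - consumed))
      plan_i <- 1L
    }
    planned_k <- if (is_zero) 0L else plan[plan_i]
    if (!is_zero && planned_k > n_feat - consumed) {
      plan <- draw_composition(n_feat - consumed,
                               calibrated_part_pmf(pmf, n_feat - consumed))
      plan_i <- 1L
      planned_k <- plan[1L]
    }

    # --- action list for this sequence --------------------------------------
    # columns: kind pickup/place/drop, object, cell, correct, corrective, distractor
    act <- list(kind = character(), object = integer(), cell = integer(),
                correct = logical(), corrective = logical(),
                distractor = logical())
    push <- function(kind, object, cell = NA_integer_, correct = NA,
                     corrective = FALSE, distractor = FALSE, at = NULL) {
      i <- if (is.null(at)) length(act$kind) + 1L else at
      for (nm in names(act)) {
        v <- switch(nm, kind = kind, object = object, cell = cell,
                    correct = correct, corrective = corrective,
                    distractor = distractor)
        act[[nm]] <<- append(act[[nm]], v, after = i - 1L)
      }
    }

    if (!is_zero) {
      for (j in seq_len(planned_k)) {
        f <- consumed + 1L
        obj <- obj_of_feature(f)
        if (f %% 2L == 1L) {              # odd feature: pickup
          push("pickup", obj)
          held <- obj
        } else {                          # even feature: place correctly
          push("place", obj, cell = unname(spec$cells[as.character(obj)]),
               correct = TRUE)
          held <- NA_integer_
        }
        consumed <- consumed + 1L
      }
      plan_i <- plan_i + 1L
    }

    # --- location-error injection -------------------------------------------
    if (loc_err) {
      pl <- which(act$kind == "place" & !act$corrective)
      if (length(pl) > 0L) {
        # misplace the first planned placement, correct immediately
        i <- pl[1L]
        obj <- act$object[i]
        good <- unname(spec$cells[as.character(obj)])
        act$cell[i] <- if (good == 1L) 2L else 1L
        act$correct[i] <- FALSE
        push("pickup", obj, corrective = TRUE, at = i + 1L)
        push("place", obj, cell = good, correct = TRUE, corrective = TRUE,
             at = i + 2L)
      } else if (!is.na(held)) {
        # carrying an object with no planned placement: misplace it now
        obj <- held
        good <- unname(spec$cells[as.character(obj)])
        push("place", obj, cell = if (good == 1L) 2L else 1L, correct = FALSE)
        push("pickup", obj, corrective = TRUE)
        push("place", obj, cell = good, correct = TRUE, corrective = TRUE)
        held <- NA_integer_
        consumed <- consumed + 1L          # its location feature is spent
        replan <- TRUE
      } else if (consumed < n_feat) {
        # hands free: fetch the next object and misplace it
        obj <- obj_of_feature(consumed + 1L)
        good <- unname(spec$cells[as.character(obj)])
        push("pickup", obj)
        push("place", obj, cell = if (good == 1L) 2L else 1L, correct = FALSE)
        push("pickup", obj, corrective = TRUE)
        push("place", obj, cell = good, correct = TRUE, corrective = TRUE)
        consumed <- consumed + 2L
        replan <- TRUE
      } else loc_err <- FALSE              # nothing left to place
    }

    # --- identity-error injection (needs free hands) ------------------------
    if (id_err) {
      holding <- !is.na(held_at_start)
      free_at <- integer(0)
      h <- held_at_start
      if (!holding) free_at <- 0L
      for (i in seq_along(act$kind)) {
        h <- switch(act$kind[i], pickup = act$object[i],
                    place = NA_integer_, drop = NA_integer_)
        if (is.na(h)) free_at <- c(free_at, i)
      }
      if (length(free_at) == 0L) {
        id_err <- FALSE                    # held throughout; cannot occur
      } else {
        # err while searching: just before the first genuine pickup if the
        # hands are free there, else at the first free point
        first_pick <- which(act$kind == "pickup" & !act$corrective)
        at <- if (length(first_pick) > 0L && (first_pick[1L] - 1L) %in% free_at)
          first_pick[1L] - 1L else free_at[1L]
        d_obj <- sample(spec$distractor_objects, 1L)
        push("pickup", d_obj, distractor = TRUE, at = at + 1L)
        push("place", d_obj, cell = sample.int(config$objects_per_display, 1L),
             correct = FALSE, distractor = TRUE, at = at + 2L)
        push("pickup", d_obj, corrective = TRUE, distractor = TRUE, at = at + 3L)
        push("drop", d_obj, corrective = TRUE, distractor = TRUE, at = at + 4L)
      }
    }

    if (replan) plan_i <- length(plan) + 1L   # force a fresh tail next time

    # --- realize gaze segments ----------------------------------------------
    k_dwell <- planned_k
    dwell_mean <- (policy$encode_base_ms + policy$encode_slope_ms * k_dwell) *
      dwell_gain / 1000
    dwell_s <- rlnorm_mean(1L, dwell_mean, sig)
    add_seg(s, "MODEL", dwell_s,
            held_body = held_at_start, held_last = held_at_start)

    area <- "MODEL"
    cur_held <- held_at_start
    travel_to <- function(dest) {
      mean_t <- if (area == "MODEL" || dest == "MODEL") t_model_leg
                else policy$cross_travel_s
      add_seg(s, "OTHER", rlnorm_mean(1L, mean_t, sig),
              held_body = cur_held, held_last = cur_held)
      area <<- dest
    }
    na <- length(act$kind)
    if (na == 0L && is_zero) {
      # unproductive trip: walk to the resources, find nothing, walk back
      travel_to("RESOURCE")
      add_seg(s, "RESOURCE", rlnorm_mean(1L, policy$search_time_s, sig),
              held_body = cur_held, held_last = cur_held)
      area <- "RESOURCE"
    }
    for (i in seq_len(na)) {
      kind <- act$kind[i]; obj <- act$object[i]
      if (kind == "pickup" && !act$corrective[i]) {
        if (area != "RESOURCE") travel_to("RESOURCE")
        add_seg(s, "RESOURCE", rlnorm_mean(1L, policy$search_time_s, sig),
                gazed = obj, event = "PICKUP", event_object = obj,
                held_body = cur_held, held_last = obj)
        cur_held <- obj
      } else if (kind == "pickup") {       # corrective re-pickup in workspace
        add_seg(s, "WORKSPACE", rlnorm_mean(1L, policy$correction_time_s, sig),
                event = "PICKUP", event_object = obj,
                held_body = cur_held, held_last = obj)
        cur_held <- obj
      } else if (kind == "place") {
        if (area != "WORKSPACE") travel_to("WORKSPACE")
        mean_t <- if (act$corrective[i]) policy$correction_time_s
                  else policy$place_time_s
        add_seg(s, "WORKSPACE", rlnorm_mean(1L, mean_t, sig),
                event = "RELEASE", event_object = obj,
                cell = act$cell[i], correct = act$correct[i],
                held_body = cur_held, held_last = cur_held)
        cur_held <- NA_integer_
      } else {                             # drop: release with no cell
        add_seg(s, "WORKSPACE", rlnorm_mean(1L, policy$correction_time_s, sig),
                event = "RELEASE", event_object = obj,
                held_body = cur_held, held_last = cur_held)
        cur_held <- NA_integer_
      }
    }
    travel_to("MODEL")                     # walk back; next dwell closes seq
    held <- cur_held

    n_id <- sum(act$kind == "pickup" & !act$corrective & !act$distractor)
    n_loc <- sum(act$kind == "place" & !act$corrective &
                   !is.na(act$correct) & act$correct)
    led[[s]] <- list(
      seq_id = s, planned_k = planned_k, k = n_id + n_loc,
      n_identity = n_id, n_location = n_loc, is_zero = is_zero,
      has_identity_error = id_err, has_location_error = loc_err,
      dwell_s = dwell_s)
  }

  # closing glance: gives the final sequence its terminating model view
  add_seg(s + 1L, "MODEL", rlnorm_mean(1L, policy$glance_ms / 1000, sig))

  seg_dt <- data.table(seq = segs$seq[1:n_seg],
                       aoi = segs$aoi[1:n_seg],
                       dur_s = segs$dur_s[1:n_seg],
                       gazed = segs$gazed[1:n_seg],
                       event = segs$event[1:n_seg],
                       event_object = segs$event_object[1:n_seg],
                       cell = segs$cell[1:n_seg],
                       correct = segs$correct[1:n_seg],
                       held_body = segs$held_body[1:n_seg],
                       held_last = segs$held_last[1:n_seg])
  led_dt <- rbindlist(lapply(led, as.data.table))
  list(segments = seg_dt, ledger = led_dt)
}

# expand a segment table (with id columns) to 90 Hz frames
segments_to_frames <- function(segs, frame_rate) {
  segs <- copy(segs)
  segs[, n_frames := pmax(1L, as.integer(round(dur_s * frame_rate)))]
  segs[, seg_id := .I]
  idx <- rep(segs$seg_id, segs$n_frames)
  fr <- segs[idx, .(participant, session, run, condition_deg, display,
                    seq, seg_id, aoi, gazed, event, event_object, cell,
                    correct, held_body, held_last, n_frames)]
  fr[, pos := seq_len(.N), by = seg_id]
  last <- fr$pos == fr$n_frames
  fr[, `:=`(
    controller_event = fifelse(last & !is.na(event), event, "NONE"),
    held_object = fifelse(last, held_last, held_body),
    placement_cell = fifelse(last & !is.na(event) & event == "RELEASE",
                             cell, NA_integer_),
    placement_correct = fifelse(last & !is.na(event) & event == "RELEASE",
                                correct, NA)
  )]
  fr[, frame := seq_len(.N), by = .(participant, run, display)]
  fr[, time_s := (frame - 1) / frame_rate]
  out <- fr[, .(participant, session, run, condition_deg, display, frame,
                time_s, aoi, gazed_object = gazed, controller_event,
                held_object, placement_cell, placement_correct,
                seq, seg_id)]
  out
}

apply_flicker <- function(frames, policy) {
  if (policy$flicker_rate <= 0) return(frames)
  n <- nrow(frames)
  starts <- which(runif(n) < policy$flicker_rate)
  if (length(starts) == 0L) return(frames)
  lens <- sample.int(policy$flicker_max_frames, length(starts), replace = TRUE)
  labs <- sample(c("OTHER", "WORKSPACE"), length(starts), replace = TRUE)
  for (i in seq_along(starts)) {
    span <- starts[i]:min(n, starts[i] + lens[i] - 1L)
    # stay within the display the flicker started in
    span <- span[frames$participant[span] == frames$participant[starts[i]] &
                   frames$run[span] == frames$run[starts[i]] &
                   frames$display[span] == frames$display[starts[i]]]
    frames$aoi[span] <- labs[i]
  }
  frames
}

#' Simulate one display
#'
#' Runs the agent on a single display specification and returns the
#' frame-level log fragment together with the ground-truth sequence ledger.
#' Uses the ambient RNG state.
#'
#' @param spec a [generate_display()] specification.
#' @param policy an [agent_policy()].
#' @param geometry a [task_geometry()] (metadata only).
#' @param config a [sim_config()].
#' @param condition_deg condition angle, one of 0, 45, 90, 135.
#' @param ids named list/vector giving `participant`, `session`, `run`,
#'   `display` identifiers stamped on each row.
#' @return list with elements `frames` (frame-log data.table in the package
#'   dialect) and `ledger` (one row per simulated sequence, including the
#'   intended feature count `planned_k`, the credited count `k`, injected
#'   error flags, realized dwell and the `truncated` flag).
#' @export
simulate_display <- function(spec, policy, geometry = task_geometry(),
                             config = sim_config(),
                             condition_deg = 0,
                             ids = list(participant = 1L, session = 1L,
                                        run = 1L, display = 1L)) {
  if (!condition_deg %in% CONDITIONS)
    stop("condition_deg must be one of ", paste(CONDITIONS, collapse = ", "),
         call. = FALSE)
  out <- sim_display_segments(spec, policy, condition_deg, config)
  segs <- out$segments
  segs[, `:=`(participant = as.integer(ids$participant),
              session = as.integer(ids$session),
              run = as.integer(ids$run),
              condition_deg = as.integer(condition_deg),
              display = as.integer(ids$display))]
  frames <- segments_to_frames(segs, config$frame_rate_hz)
  res <- finalize_display(frames, out$ledger, config)
  res$frames <- apply_flicker(res$frames, policy)
  res
}

# timeout truncation + ledger frame spans + realized dwell in ms
finalize_display <- function(frames, ledger, config) {
  fr_rate <- config$frame_rate_hz
  cutoff <- as.integer(round(config$display_timeout_s * fr_rate))
  ledger <- copy(ledger)
  spans <- frames[, .(start_frame = min(frame), end_frame = max(frame)),
                  by = .(participant, session, run, condition_deg, display, seq)]
  n_led <- nrow(ledger)
  # closing glance rows (seq > n_led) are part of the stream, not the ledger
  seq_spans <- spans[seq <= n_led]
  ledger[, `:=`(participant = seq_spans$participant[1],
                session = seq_spans$session[1],
                run = seq_spans$run[1],
                condition_deg = seq_spans$condition_deg[1],
                display = seq_spans$display[1])]
  ledger[seq_spans, `:=`(start_frame = i.start_frame, end_frame = i.end_frame),
         on = c(seq_id = "seq")]
  # realized dwell = frame count of the opening MODEL segment
  first_seg <- frames[, .(seg_id = min(seg_id)), by = seq]
  dwn <- frames[first_seg, on = c("seq", "seg_id")][, .(N = .N), by = seq]
  ledger[dwn, dwell_ms := i.N / fr_rate * 1000, on = c(seq_id = "seq")]

  truncated_display <- max(frames$frame) > cutoff
  if (truncated_display) {
    frames <- frames[frame <= cutoff]
    kept <- frames[, unique(seq)]
    ledger <- ledger[seq_id %in% kept]
    ledger[, truncated := end_frame > cutoff]
    # credited counts must reflect surviving events only
    if (any(ledger$truncated)) {
      ev <- frames[controller_event != "NONE"]
      for (sid in ledger[truncated == TRUE, seq_id]) {
        evs <- ev[seq == sid]
        ledger[seq_id == sid,
               `:=`(k = NA_integer_, n_identity = NA_integer_,
                    n_location = NA_integer_)]
        if (nrow(evs) > 0) {
          # conservative: truncated sequences are excluded downstream anyway
        }
      }
    }
  } else {
    ledger[, truncated := FALSE]
  }
  ledger[, display_truncated := truncated_display]
  frames[, c("seq", "seg_id") := NULL]
  list(frames = frames[], ledger = ledger[])
}

#' Simulate a full experiment
#'
#' Generates the frame log, ground-truth ledger and display manifest for a
#' complete study: `n_participants` x `runs_per_participant` runs x
#' `displays_per_run` displays, the condition varied run-wise so that each
#' participant meets every condition in the same number of runs.  Each
#' participant draws from an independent substream split from `seed`, so
#' enlarging the sample never perturbs earlier participants.
#'
#' @param config a [sim_config()].
#' @param policy an [agent_policy()].
#' @param geometry a [task_geometry()].
#' @param seed integer master seed.
#' @return an object of class `wm_sim`: a list with `frames` (the frame log),
#'   `ledger` (ground truth, one row per sequence), `displays` (manifest:
#'   one row per object per display with its role and model cell) and the
#'   echoed `config`/`policy`/`seed`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                policy = agent_policy(),
                                geometry = task_geometry(),
                                seed = 1L) {
  set.seed(seed)
  p_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  runs_per_cond <- config$runs_per_participant / length(CONDITIONS)

  all_frames <- vector("list", config$n_participants)
  all_ledger <- vector("list", config$n_participants)
  all_manifest <- vector("list", config$n_participants)

  for (p in seq_len(config$n_participants)) {
    set.seed(p_seeds[p])
    cond_order <- sample(rep(CONDITIONS, runs_per_cond))
    fr_l <- list(); led_l <- list(); man_l <- list()
    seen <- character(0)
    i <- 0L
    for (r in seq_len(config$runs_per_participant)) {
      sess <- if (r <= config$runs_per_participant / 2) 1L else 2L
      for (d in seq_len(config$displays_per_run)) {
        # arrangements never repeat within a participant
        repeat {
          spec <- generate_display(config$pool_size,
                                   config$objects_per_display,
                                   config$distractors_per_display)
          sig <- paste(sort(spec$model_objects), spec$cells[order(names(spec$cells))],
                       collapse = ";")
          if (!sig %in% seen) { seen <- c(seen, sig); break }
        }
        res <- simulate_display(spec, policy, geometry, config,
                                condition_deg = cond_order[r],
                                ids = list(participant = p, session = sess,
                                           run = r, display = d))
        i <- i + 1L
        fr_l[[i]] <- res$frames
        led_l[[i]] <- res$ledger
        man_l[[i]] <- data.table(
          participant = p, session = sess, run = r,
          condition_deg = cond_order[r], display = d,
          object_id = c(spec$model_objects, spec$distractor_objects),
          role = rep(c("model", "distractor"),
                     c(length(spec$model_objects),
                       length(spec$distractor_objects))),
          cell = c(unname(spec$cells[as.character(spec$model_objects)]),
                   rep(NA_integer_, length(spec$distractor_objects))))
      }
    }
    all_frames[[p]] <- rbindlist(fr_l)
    all_ledger[[p]] <- rbindlist(led_l)
    all_manifest[[p]] <- rbindlist(man_l)
  }

  structure(list(frames = rbindlist(all_frames),
                 ledger = rbindlist(all_ledger),
                 displays = rbindlist(all_manifest),
                 config = config, policy = policy, seed = seed),
            class = "wm_sim")
}

#' @export
print.wm_sim <- function(x, ...) {
  cat("<wm_sim> ", x$config$n_participants, " participants, ",
      nrow(x$ledger), " sequences, ", nrow(x$frames), " frames (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}
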