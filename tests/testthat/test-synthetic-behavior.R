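test_that("display specs have 8 distinct model objects, 16 distractors, a cell bijection", {
  set.seed(1)
  spec <- generate_display(pool_size = 60)
  expect_length(spec$model_objects, 8)
  expect_length(spec$distractor_objects, 16)
  expect_length(unique(spec$resource_objects), 24)
  expect_setequal(unname(spec$cells), 1:8)
  expect_setequal(names(spec$cells), as.character(spec$model_objects))

  # boundary: pool of 24 puts the whole pool in the resources
  spec24 <- generate_display(pool_size = 24)
  expect_setequal(spec24$resource_objects, 1:24)
  expect_error(generate_display(pool_size = 23), "pool_size")

  # determinism under a fixed seed
  set.seed(7); a <- generate_display()
  set.seed(7); b <- generate_display()
  expect_identical(a, b)
})

test_that("policy and config constructors enforce their invariants", {
  expect_error(agent_policy(zero_feature_rate = 1.2), "rates")
  expect_error(agent_policy(features_pmf = matrix(1, 4, 4)), "summing to 1")
  expect_error(sim_config(runs_per_participant = 6), "multiple of 4")
  expect_error(sim_config(pool_size = 10), "pool_size")
  expect_error(task_geometry(room_side_cm = -1), "positive")
})

test_that("calibrated composition proposals realize the configured load distribution", {
  pmfs <- list(c(0.60, 0.29, 0.10, 0.01), c(0.29, 0.45, 0.16, 0.10))
  for (pmf in pmfs) {
    q <- gazewm:::calibrated_part_pmf(pmf, 16L)
    expect_equal(gazewm:::composition_part_dist(q, 16L), pmf,
                 tolerance = 1e-8)
    set.seed(5)
    ks <- unlist(replicate(4000, gazewm:::draw_composition(16L, q),
                           simplify = FALSE))
    est <- as.numeric(prop.table(table(factor(ks, levels = 1:4))))
    # every composition sums exactly to 16
    expect_true(all(vapply(replicate(50, gazewm:::draw_composition(16L, q),
                                     simplify = FALSE), sum, numeric(1)) == 16))
    # 3-sigma binomial band: parts within a composition are dependent
    # (they are conditioned to tile 16), so the binomial SE understates
    ci <- 3 * sqrt(pmf * (1 - pmf) / length(ks))
    expect_true(all(abs(est - pmf) <= ci + 1e-12))
  }
})

test_that("degenerate policies force the expected sequence counts", {
  cfg <- sim_config(n_participants = 1, runs_per_participant = 4,
                    displays_per_run = 1)
  # always 2 features per visit (pick + place): 8 sequences per display
  pol2 <- agent_policy(features_pmf = matrix(rep(c(0, 1, 0, 0), 4), 4, 4,
                                             byrow = TRUE),
                       zero_feature_rate = 0, identity_error_rate = 0,
                       location_error_rate = 0)
  set.seed(3)
  spec <- generate_display()
  res2 <- simulate_display(spec, pol2, condition_deg = 0)
  expect_equal(nrow(res2$ledger), 8)
  expect_true(all(res2$ledger$k == 2))

  # always 1 feature per visit: 16 sequences per display
  pol1 <- agent_policy(features_pmf = matrix(rep(c(1, 0, 0, 0), 4), 4, 4,
                                             byrow = TRUE),
                       zero_feature_rate = 0, identity_error_rate = 0,
                       location_error_rate = 0)
  res1 <- simulate_display(spec, pol1, condition_deg = 0)
  expect_equal(nrow(res1$ledger), 16)
  expect_true(all(res1$ledger$k == 1))

  # identity_error_rate = 1: every sequence is flagged and contains a
  # corrective re-pickup of the distractor
  pole <- agent_policy(features_pmf = matrix(rep(c(0, 1, 0, 0), 4), 4, 4,
                                             byrow = TRUE),
                       zero_feature_rate = 0, identity_error_rate = 1,
                       location_error_rate = 0)
  rese <- simulate_display(spec, pole, condition_deg = 0)
  expect_true(all(rese$ledger$has_identity_error))
  ev <- derive_events(rese$frames)
  expect_true(any(ev$kind == "REMOVE" & ev$is_corrective))
})

test_that("pickup/release conservation holds on error-free completed displays", {
  sim <- small_sim(seed = 21)
  led <- sim$ledger
  clean <- led[, .(ok = !any(has_identity_error) && !any(has_location_error) &&
                     !any(truncated)),
               by = .(participant, run, display)][ok == TRUE]
  fr <- sim$frames
  for (i in seq_len(nrow(clean))) {
    d <- fr[participant == clean$participant[i] & run == clean$run[i] &
              display == clean$display[i]]
    expect_equal(sum(d$controller_event == "PICKUP"), 8)
    expect_equal(sum(d$controller_event == "RELEASE"), 8)
  }
})

test_that("experiment scale: per participant 8x14 displays, 28 per condition, same seed reproduces bytes", {
  sim <- simulate_experiment(sim_config(n_participants = 1), seed = 5)
  led <- sim$ledger
  expect_equal(led[, uniqueN(paste(run, display))], 8 * 14)
  per_cond <- led[, uniqueN(paste(run, display)), by = condition_deg]
  expect_true(all(per_cond$V1 == 28))
  expect_setequal(per_cond$condition_deg, c(0, 45, 90, 135))

  sim2 <- simulate_experiment(sim_config(n_participants = 1), seed = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_frame_log(sim$frames, f1); write_frame_log(sim2$frames, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # adding a participant never perturbs participant 1
  sim3 <- simulate_experiment(sim_config(n_participants = 2), seed = 5)
  expect_equal(sim3$frames[participant == 1], sim$frames)
})

test_that("mean completion time increases with the model angle under a fixed policy", {
  sim <- simulate_experiment(
    sim_config(n_participants = 3, runs_per_participant = 8,
               displays_per_run = 10), seed = 13)
  span <- sim$frames[, .(total_s = (max(frame) - min(frame)) / 90),
                     by = .(participant, run, display, condition_deg)]
  m <- span[, .(mean_s = mean(total_s)), keyby = condition_deg]
  expect_true(all(diff(m$mean_s) > 0))
})

test_that("gaze flicker noise degrades ledger agreement monotonically", {
  rates <- c(0, 0.002, 0.02)
  agree <- vapply(rates, function(r) {
    sim <- small_sim(n_participants = 1, seed = 31,
                     policy = agent_policy(flicker_rate = r))
    res <- run_pipeline(sim$frames, sim$displays)
    ledger_agreement(res$scored, sim$ledger)$count_agreement
  }, numeric(1))
  expect_equal(agree[1], 1)
  expect_true(agree[2] >= agree[3])
  expect_lt(agree[3], 1)
})
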