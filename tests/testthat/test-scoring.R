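mk_ev <- function(kinds, model = TRUE, correct = TRUE, corrective = FALSE) {
  data.frame(kind = kinds,
             is_model_object = rep_len(model, length(kinds)),
             correct_location = ifelse(kinds == "PLACE",
                                       rep_len(correct, length(kinds)), NA),
             is_corrective = rep_len(corrective, length(kinds)))
}

test_that("feature counting follows the pickup/placement ladder", {
  expect_equal(count_features(mk_ev(character(0)))$k, 0)
  expect_equal(count_features(mk_ev("PICKUP"))$k, 1)
  expect_equal(count_features(mk_ev(c("PICKUP", "PLACE")))$k, 2)
  expect_equal(count_features(mk_ev(c("PICKUP", "PLACE", "PICKUP")))$k, 3)
  expect_equal(count_features(mk_ev(c("PICKUP", "PLACE", "PICKUP", "PLACE")))$k, 4)
  # corrective actions and distractor pickups earn nothing
  expect_equal(count_features(mk_ev(c("PICKUP", "PLACE"), corrective = TRUE))$k, 0)
  expect_equal(count_features(mk_ev("PICKUP", model = FALSE))$k, 0)
  # components split identity vs location
  fc <- count_features(mk_ev(c("PICKUP", "PLACE", "PICKUP")))
  expect_equal(fc$n_identity, 2)
  expect_equal(fc$n_location, 1)
})

test_that("display tallies conserve 16 features on clean completed displays", {
  pol <- agent_policy(identity_error_rate = 0, location_error_rate = 0)
  sim <- small_sim(seed = 61, policy = pol)
  res <- run_pipeline(sim$frames, sim$displays)
  tal <- res$tallies
  expect_true(all(tal[complete & error_free & !truncated,
                      total_features] == 16))
  expect_equal(nrow(tal), sim$ledger[, uniqueN(paste(participant, run, display))])
})

test_that("probability table matches hand-computed percentages", {
  scored <- data.table::data.table(
    participant = 1L, condition_deg = 0L, run = 1L, display = 1L,
    seq_id = 1:10, k = rep(c(1L, 2L, 3L), c(6, 3, 1)),
    truncated = FALSE, has_identity_error = FALSE,
    has_location_error = FALSE)
  fp <- feature_probabilities(scored)
  cells <- fp$cells
  expect_equal(cells[cells$k_bin == "1", pct], 60)
  expect_equal(cells[cells$k_bin == "2", pct], 30)
  expect_equal(cells[cells$k_bin == "3", pct], 10)
  expect_equal(cells[cells$k_bin == "4", pct], 0)
  expect_equal(unique(cells$mean_k), 1.5)
  expect_equal(sum(cells$pct), 100)

  # degenerate: everything k = 2
  scored2 <- data.table::copy(scored)[, k := 2L]
  fp2 <- feature_probabilities(scored2)
  expect_equal(fp2$cells[k_bin == "2", pct], 100)
  expect_equal(unique(fp2$cells$mean_k), 2)

  # counts above 4 are binned but kept in the mean
  scored3 <- data.table::copy(scored)[seq_id == 1, k := 6L]
  fp3 <- feature_probabilities(scored3)
  expect_equal(fp3$cells[k_bin == ">4", pct], 10)
  expect_equal(unique(fp3$cells$mean_k), mean(c(6, rep(1, 5), 2, 2, 2, 3)))
})

test_that("error rates are plain flagged-sequence percentages", {
  scored <- data.table::data.table(
    participant = 1L, condition_deg = 0L, seq_id = 1:100,
    k = 1L, truncated = FALSE,
    has_identity_error = rep(c(TRUE, FALSE), c(2, 98)),
    has_location_error = FALSE)
  er <- error_rates(scored)
  expect_equal(er$identity_pct, 2)
  expect_equal(er$location_pct, 0)
  expect_equal(er$n_seq, 100)
})

test_that("scorer agrees with a brute-force frame replay on random displays", {
  sim <- simulate_experiment(
    sim_config(n_participants = 2, runs_per_participant = 4,
               displays_per_run = 3), seed = 71)
  res <- run_pipeline(sim$frames, sim$displays)
  fr <- sim$frames
  man <- sim$displays
  keys <- unique(res$scored[, .(participant, run, display)])
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i]
    d <- fr[participant == kk$participant & run == kk$run &
              display == kk$display]
    model_ids <- man[participant == kk$participant & run == kk$run &
                       display == kk$display & role == "model", object_id]
    orc <- oracle_score_display(as.data.frame(d), model_ids)
    got <- res$scored[participant == kk$participant & run == kk$run &
                        display == kk$display][order(seq_id)]
    expect_equal(got$k, orc$k)
    expect_equal(got$has_identity_error, orc$id_err)
    expect_equal(got$has_location_error, orc$loc_err)
  }
})

test_that("mean feature use rises with condition angle when policies are ordered", {
  sim <- simulate_experiment(
    sim_config(n_participants = 3, runs_per_participant = 4,
               displays_per_run = 6), seed = 81)
  res <- run_pipeline(sim$frames, sim$displays)
  mk <- unique(res$probabilities$group[, .(condition_deg, mean_k)])
  data.table::setorder(mk, condition_deg)
  expect_true(all(diff(mk$mean_k) > 0))
})
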