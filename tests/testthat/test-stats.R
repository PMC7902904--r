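test_that("Box-Cox selection recovers the generating transform", {
  set.seed(1)
  # log-normal data: lambda CI contains 0, log recommended
  y <- exp(rnorm(5000))
  bc <- boxcox_select(y)
  expect_true(bc$ci[1] <= 0 && 0 <= bc$ci[2])
  expect_equal(bc$recommended, "log")
  # already-normal data shifted positive: lambda near 1
  y2 <- rnorm(5000, mean = 20, sd = 1)
  bc2 <- boxcox_select(y2)
  expect_lt(abs(bc2$lambda - 1), 0.35)
  # non-positive input errors with row locations
  expect_error(boxcox_select(c(1, -1, 2)), "offending rows: 2")
  # the lambda = 0 limit is the natural log (sanity on the definition used)
  lam <- 1e-8
  expect_equal((y[1:10]^lam - 1) / lam, log(y[1:10]), tolerance = 1e-6)
})

test_that("locomotion predictors are orthogonal, z-scaled and monotone", {
  cond <- rep(c(0, 45, 90, 135), each = 25)
  pr <- make_predictors(cond)
  for (cl in names(pr)) {
    expect_equal(mean(pr[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(pr[[cl]]), 1, tolerance = 1e-12)
  }
  # polynomial columns pairwise orthogonal over the design
  polys <- as.matrix(pr[, c("loco_lin", "loco_quad", "loco_cube")])
  gram <- crossprod(polys)
  expect_equal(gram[upper.tri(gram)], rep(0, 3), tolerance = 1e-9)
  # the linear column is constant within and monotone across conditions
  sp <- split(pr$loco_lin, cond)
  expect_true(all(vapply(sp, function(x) diff(range(x)), numeric(1)) < 1e-9))
  lv <- vapply(sp, mean, numeric(1))
  expect_true(all(diff(lv[order(as.numeric(names(lv)))]) > 0))
  expect_error(make_predictors(c(0, 30)), "unknown condition")
})

glmm_data <- function(n_per = 60, beta0 = 0.3, beta1 = 0.4, re_sd = 0,
                      n_part = 24, seed = 5) {
  set.seed(seed)
  cond <- rep(c(0, 45, 90, 135), length.out = n_per)
  d <- data.frame(participant = rep(seq_len(n_part), each = n_per),
                  condition_deg = rep(cond, n_part))
  d <- cbind(d, make_predictors(d$condition_deg))
  u <- rnorm(n_part, 0, re_sd)
  eta <- beta0 + beta1 * d$loco_lin + u[d$participant]
  d$k <- rpois(nrow(d), exp(eta))
  d
}

test_that("Poisson GLMM: intercept identity and equivalence to the GLM oracle", {
  # constant response: intercept = log(mean), zero random variance
  d <- glmm_data()
  d$k <- 2L
  f <- fit_poisson_glmm(d, fixed_terms = character(0), random_slope = NULL,
                        label = "intercept-only")
  expect_equal(f$fixed$estimate[1], log(2), tolerance = 1e-6)

  # zero true random-effect variance: fixed effects match an independently
  # fitted Poisson regression to 1e-4
  d2 <- glmm_data(re_sd = 0)
  fg <- fit_poisson_glmm(d2, fixed_terms = "loco_lin")
  oracle <- glm(k ~ loco_lin, data = d2, family = poisson)
  expect_lt(max(abs(fg$fixed$estimate - coef(oracle))), 1e-4)

  # AIC/BIC identities hold exactly
  expect_equal(fg$AIC, 2 * fg$df - 2 * fg$logLik)
  expect_equal(fg$BIC, fg$df * log(fg$n_obs) - 2 * fg$logLik)
})

test_that("slope recovery: true coefficient inside 2 SE in most replicates", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- glmm_data(n_per = 40, beta1 = 0.3, re_sd = 0.15, seed = 100 + r)
    f <- fit_poisson_glmm(d, fixed_terms = "loco_lin")
    b <- f$fixed[f$fixed$term == "loco_lin", ]
    if (abs(b$estimate - 0.3) <= 2 * b$se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the likelihood-ratio ladder reports identities and flags non-nested rows", {
  d <- glmm_data(re_sd = 0.1)
  f_log <- fit_poisson_glmm(d, fixed_terms = "loco_log",
                            random_slope = "loco_log", label = "logarithmic")
  f_lin <- fit_poisson_glmm(d, fixed_terms = "loco_lin", label = "linear")
  f_quad <- fit_poisson_glmm(d, fixed_terms = c("loco_lin", "loco_quad"),
                             label = "quadratic")
  lad <- lr_ladder(list(f_log, f_lin, f_quad))
  # chi-square is 2 * delta logLik by definition
  expect_equal(lad$chisq[3], 2 * (f_quad$logLik - f_lin$logLik))
  expect_equal(lad$delta_df[3], 1L)
  # equal-parameter adjacent pair flagged non-nested
  expect_false(lad$nested[2])
  # a model compared with itself: chi-square 0, p = 1
  lad2 <- lr_ladder(list(f_lin, f_lin))
  expect_equal(lad2$chisq[2], 0)
  expect_equal(lad2$p[2], 1)
  # differing observation counts refuse to compare
  f_small <- fit_poisson_glmm(d[1:200, ], fixed_terms = "loco_lin")
  expect_error(lr_ladder(list(f_lin, f_small)), "differing")
})

test_that("LMM: exact-fit limit and per-condition slices", {
  set.seed(9)
  d <- data.frame(participant = rep(1:12, each = 40),
                  k = rep(1:4, 120))
  d$y <- 2 + 0.5 * d$k                    # exactly linear, no noise
  f <- fit_lmm(d, response = "y", loco = NULL, maximal = FALSE)
  quad <- f$fixed[f$fixed$term == "feat_quad", "estimate"]
  expect_lt(abs(quad), 1e-8)
  lin <- f$fixed[f$fixed$term == "feat_lin", "estimate"]
  expect_gt(lin, 0)

  # simulated quadratic effect: recovered curvature has the right sign
  signs <- vapply(1:10, function(r) {
    set.seed(200 + r)
    dd <- data.frame(participant = rep(1:12, each = 40), k = rep(1:4, 120))
    u <- rnorm(12, 0, 0.2)
    dd$y <- 2 + 0.3 * dd$k + 0.25 * dd$k^2 + u[dd$participant] +
      rnorm(nrow(dd), 0, 0.3)
    ff <- fit_lmm(dd, response = "y", loco = NULL, maximal = FALSE)
    sign(ff$fixed[ff$fixed$term == "feat_quad", "estimate"])
  }, numeric(1))
  expect_gte(mean(signs == 1), 0.95)
})

test_that("random-structure simplification drops unsupported slopes only", {
  set.seed(31)
  n_part <- 16; n_obs <- 30
  d <- data.frame(participant = rep(seq_len(n_part), each = n_obs),
                  k = rep(1:4, length.out = n_part * n_obs))
  # zero slope variance: by-participant intercepts only
  u <- rnorm(n_part, 0, 0.5)
  d$y <- 1 + 0.4 * d$k + u[d$participant] + rnorm(nrow(d), 0, 0.4)
  f <- fit_lmm(d, response = "y", loco = NULL, maximal = TRUE)
  simp <- simplify_random_structure(f)
  expect_gt(nrow(simp$audit), 0)
  expect_true(any(simp$audit$dropped))
  # the intercept survives
  expect_true(grepl("\\| participant", deparse1(simp$fit$formula)))

  # strong slope variance: the slope is retained
  set.seed(32)
  b <- rnorm(n_part, 0, 1.5)
  d2 <- d
  d2$y <- 1 + (0.4 + b[d2$participant]) * d2$k + u[d2$participant] +
    rnorm(nrow(d2), 0, 0.3)
  f2 <- fit_lmm(d2, response = "y", loco = NULL, maximal = TRUE)
  simp2 <- simplify_random_structure(f2)
  kept <- simp2$fit$re_spec
  expect_true(grepl("feat_lin", kept))
})

test_that("paired tests reproduce hand-computed values and emit 12 comparisons", {
  # differences {1, 2, 3}: mean 2, sd 1, t = 2 / (1/sqrt(3)) = 3.464, df 2
  cells <- data.table::data.table(
    participant = rep(1:3, 2),
    condition_deg = rep(c(0L, 45L), each = 3),
    k_bin = "1",
    pct = c(11, 12, 13, 10, 10, 10))
  out <- suppressWarnings(paired_feature_tests(cells, k_levels = 1))
  row <- out[cond_a == 0 & cond_b == 45]
  expect_equal(row$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(row$df, 2)
  expect_equal(row$mean_diff, 2)
  expect_equal(row$cohens_d, 2)
  expect_true(row$ci_lo <= 2 && 2 <= row$ci_hi)

  # identical vectors: t = 0, d = 0, CI spans 0
  cells0 <- data.table::data.table(
    participant = rep(1:4, 2),
    condition_deg = rep(c(45L, 90L), each = 4),
    k_bin = "2", pct = c(1, 2, 3, 4, 1, 2, 3, 4))
  out0 <- suppressWarnings(paired_feature_tests(cells0, k_levels = 2))
  expect_equal(out0$t, 0)
  expect_equal(out0$cohens_d, 0)

  # full grid: 4 feature levels x 3 neighboring pairs = 12 rows
  grid <- data.table::CJ(participant = 1:6, condition_deg = c(0L, 45L, 90L, 135L),
                         k_bin = as.character(1:4))
  set.seed(3)
  grid[, pct := 25 + rnorm(.N)]
  out12 <- paired_feature_tests(grid)
  expect_equal(nrow(out12), 12)
  expect_true(all(out12$df == 5))
})
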