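# Statistical battery: Box-Cox transform selection, locomotion predictor
# construction, Poisson GLMMs for feature counts, LMMs for viewing and
# completion times, likelihood-ratio ladders, random-structure
# simplification and planned paired t tests.
#
# Model fitting goes through lme4 (glmer/lmer, maximum likelihood, Laplace
# approximation for the GLMMs); this package adds the model-building
# conventions, the comparison ladder and the audit trail around them.

#' Box-Cox transformation selection
#'
#' Profile-likelihood estimate of the Box-Cox power parameter over a grid
#' on \[-2, 2\] (via [MASS::boxcox()]).  If 0 lies in the 95% profile CI
#' the natural log transform is recommended; if instead 1 lies in the CI no
#' transform is recommended; otherwise the point estimate's power.
#'
#' @param y strictly positive numeric vector.
#' @param grid lambda grid.
#' @return list with `lambda`, `ci` (95% profile interval), `recommended`
#'   (`"log"`, `"identity"` or `"power"`).
#' @export
boxcox_select <- function(y, grid = seq(-2, 2, by = 0.01)) {
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad) > 0)
    stop("y must be strictly positive; offending rows: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  prof <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  cutoff <- max(prof$y) - qchisq(0.95, 1) / 2
  ci <- range(prof$x[prof$y >= cutoff])
  recommended <- if (ci[1] <= 0 && 0 <= ci[2]) "log"
                 else if (ci[1] <= 1 && 1 <= ci[2]) "identity"
                 else "power"
  list(lambda = lambda, ci = ci, recommended = recommended)
}

#' Locomotion predictor columns
#'
#' Codes the condition angles as equally spaced ranks 1..4 (so the
#' logarithmic transform is defined at 0 degrees), then builds the five
#' candidate locomotion predictors: exponential and logarithmic transforms
#' of the rank, and orthogonal linear/quadratic/cubic polynomials over the
#' design.  Every column is z-scaled (mean 0, SD 1 over the rows).
#'
#' @param condition_deg vector of condition angles.
#' @return data.frame with columns `loco_exp`, `loco_log`, `loco_lin`,
#'   `loco_quad`, `loco_cube` (polynomial columns pairwise orthogonal).
#' @export
make_predictors <- function(condition_deg) {
  rank <- match(condition_deg, CONDITIONS)
  if (anyNA(rank))
    stop("unknown condition level: ",
         paste(unique(condition_deg[is.na(rank)]), collapse = ", "),
         call. = FALSE)
  zs <- function(x) as.numeric(scale(x))
  nlev <- length(unique(rank))
  deg <- min(3L, nlev - 1L)
  if (deg < 1L) stop("need at least two condition levels", call. = FALSE)
  pol <- poly(rank, degree = deg)
  out <- data.frame(loco_exp = zs(exp(rank)),
                    loco_log = zs(log(rank)),
                    loco_lin = zs(pol[, 1]))
  out$loco_quad <- if (deg >= 2) zs(pol[, 2]) else NA_real_
  out$loco_cube <- if (deg >= 3) zs(pol[, 3]) else NA_real_
  out
}

# wrap an lme4 fit into the package's fit container
as_wm_fit <- function(fit, label, data, response, fixed_terms, re_spec,
                      group) {
  sm <- summary(fit)
  co <- sm$coefficients
  stat_col <- if ("z value" %in% colnames(co)) "z value" else "t value"
  fixed <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      statistic = co[, stat_col],
                      row.names = NULL)
  fixed$p <- if ("Pr(>|z|)" %in% colnames(co)) co[, "Pr(>|z|)"]
             else NA_real_
  ll <- logLik(fit)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(label = label,
                 formula = formula(fit),
                 fixed = fixed,
                 varcor = lme4::VarCorr(fit),
                 logLik = as.numeric(ll),
                 df = attr(ll, "df"),
                 AIC = AIC(fit),
                 BIC = BIC(fit),
                 n_obs = stats::nobs(fit),
                 converged = is.null(msgs),
                 messages = msgs,
                 singular = lme4::isSingular(fit),
                 statistic_type = if (stat_col == "z value") "wald-z"
                                  else "wald-t",
                 fit = fit,
                 data = data, response = response,
                 fixed_terms = fixed_terms, re_spec = re_spec,
                 group = group),
            class = "wm_fit")
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("<wm_fit> ", x$label, "\n  ", deparse1(x$formula), "\n",
      "  logLik ", round(x$logLik, 2), "  AIC ", round(x$AIC, 1),
      "  BIC ", round(x$BIC, 1), "  n ", x$n_obs,
      if (!x$converged) "  [convergence warnings]" else "",
      if (x$singular) "  [singular]" else "", "\n", sep = "")
  print(x$fixed, digits = 4)
  invisible(x)
}

#' Poisson GLMM for feature counts
#'
#' Fits `k ~ <fixed terms> + (1 + <random slope> | group)` with a Poisson
#' family by maximum likelihood (Laplace approximation), matching the
#' random-effects structure used for the locomotion analysis: by-participant
#' intercepts plus a by-participant slope for the locomotion predictor.
#'
#' @param data data.frame containing the response, predictors and group.
#' @param fixed_terms character vector of fixed-effect column names.
#' @param random_slope column name for the by-group random slope, or NULL
#'   for a random intercept only.
#' @param response response column (non-negative integer counts).
#' @param group grouping column.
#' @param label label carried into ladders and reports.
#' @return a `wm_fit` (see [print.wm_fit()]); never errors on convergence
#'   problems, which are recorded in `converged`/`messages`.
#' @export
fit_poisson_glmm <- function(data, fixed_terms, random_slope = "loco_lin",
                             response = "k", group = "participant",
                             label = paste(fixed_terms, collapse = "+")) {
  data <- as.data.frame(data)
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts", call. = FALSE)
  if (length(unique(data[[group]])) < 2)
    stop("need at least 2 groups", call. = FALSE)
  re <- if (is.null(random_slope)) paste0("(1 | ", group, ")")
        else paste0("(1 + ", random_slope, " | ", group, ")")
  if (stats::var(y) == 0) {
    # degenerate boundary case: a constant response pins the random-effect
    # variance at zero, where the GLMM coincides with plain Poisson
    # regression; fit that directly (the PIRLS loop cannot iterate here)
    fml0 <- as.formula(paste(response, "~",
                             if (length(fixed_terms) == 0) "1"
                             else paste(fixed_terms, collapse = " + ")))
    fit0 <- glm(fml0, data = data, family = poisson)
    return(as_wm_fit_glm(fit0, label, data, response, fixed_terms, group))
  }
  fml <- as.formula(paste(response, "~",
                          paste(c(fixed_terms, re), collapse = " + ")))
  fit <- suppressMessages(lme4::glmer(
    fml, data = data, family = poisson,
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE)))
  as_wm_fit(fit, label, data, response, fixed_terms,
            re_spec = re, group = group)
}

# wm_fit container for the degenerate plain-GLM boundary case
as_wm_fit_glm <- function(fit, label, data, response, fixed_terms, group) {
  co <- summary(fit)$coefficients
  ll <- logLik(fit)
  structure(list(label = label, formula = formula(fit),
                 fixed = data.frame(term = rownames(co),
                                    estimate = co[, "Estimate"],
                                    se = co[, "Std. Error"],
                                    statistic = co[, "z value"],
                                    p = co[, "Pr(>|z|)"],
                                    row.names = NULL),
                 varcor = NULL, logLik = as.numeric(ll),
                 df = attr(ll, "df"), AIC = AIC(fit), BIC = BIC(fit),
                 n_obs = stats::nobs(fit), converged = fit$converged,
                 messages = paste("constant response: random-effect variance",
                                  "pinned at zero; plain Poisson fit"),
                 singular = TRUE, statistic_type = "wald-z", fit = fit,
                 data = data, response = response,
                 fixed_terms = fixed_terms, re_spec = "1", group = group),
            class = "wm_fit")
}

#' Likelihood-ratio ladder over an ordered set of fits
#'
#' Compares each fit with the preceding one: for nested pairs (parameter
#' count strictly increases) a likelihood-ratio chi-square test; adjacent
#' pairs with equal parameter counts (e.g. exponential vs logarithmic
#' locomotion codings) are not nested, are compared by AIC, and their
#' chi-square is referred to 1 df by convention so a "last significant
#' step" remains defined (`nested` flags these rows).
#'
#' @param fits list of `wm_fit` objects, ordered simplest to richest, all
#'   fitted to the same observations.
#' @param alpha significance level used by the `selected` attribute.
#' @return data.table with one row per fit: `label`, `df`, `AIC`, `BIC`,
#'   `logLik`, `chisq`, `delta_df`, `p`, `nested`, `aic_preferred`.  The
#'   attribute `"selected"` names the last fit whose step was significant.
#' @export
lr_ladder <- function(fits, alpha = 0.05) {
  if (length(fits) < 2) stop("need at least two fits", call. = FALSE)
  ns <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits were made on differing numbers of observations: ",
         paste(ns, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (i == 1)
      return(data.table(label = f$label, df = f$df, AIC = f$AIC, BIC = f$BIC,
                        logLik = f$logLik, chisq = NA_real_,
                        delta_df = NA_integer_, p = NA_real_, nested = NA,
                        aic_preferred = NA))
    g <- fits[[i - 1]]
    chisq <- 2 * (f$logLik - g$logLik)
    ddf <- f$df - g$df
    nested <- ddf > 0
    p <- if (nested) pchisq(chisq, ddf, lower.tail = FALSE)
         else pchisq(max(chisq, 0), 1, lower.tail = FALSE)
    data.table(label = f$label, df = f$df, AIC = f$AIC, BIC = f$BIC,
               logLik = f$logLik, chisq = chisq, delta_df = as.integer(ddf),
               p = p, nested = nested, aic_preferred = f$AIC < g$AIC)
  })
  out <- rbindlist(rows)
  sig <- which(!is.na(out$p) & out$p <= alpha)
  attr(out, "selected") <- if (length(sig) > 0) out$label[max(sig)]
                           else out$label[1]
  out[]
}

#' Linear mixed model for (log) viewing or completion time
#'
#' Builds orthogonal linear + quadratic predictors of the feature count,
#' crosses them with a locomotion predictor when given, and fits by maximum
#' likelihood with a by-participant random structure that is maximal by
#' default (intercept + slopes for the feature terms, locomotion and their
#' interactions).  t statistics are Wald; per-term p values are not
#' computed here (see [simplify_random_structure()] for LRT machinery).
#'
#' @param data data.frame with the response, feature count and optionally a
#'   locomotion column.
#' @param response response column name (transform before calling; see
#'   [boxcox_select()]).
#' @param features column holding the per-observation feature count.
#' @param loco optional z-scaled locomotion column name; NULL fits a
#'   features-only model (the per-condition sub-model).
#' @param group grouping column.
#' @param maximal use the full random-slope structure; FALSE fits a random
#'   intercept only.
#' @param label fit label.
#' @return a `wm_fit`; the model data (with the derived `feat_lin`,
#'   `feat_quad` columns) is carried in `$data`.
#' @export
fit_lmm <- function(data, response, features = "k", loco = "loco_lin",
                    group = "participant", maximal = TRUE,
                    label = response) {
  data <- as.data.frame(data)
  kv <- data[[features]]
  if (length(unique(kv)) < 3)
    stop("need at least 3 distinct feature counts for a quadratic fit",
         call. = FALSE)
  pol <- poly(kv, 2)
  zs <- function(x) as.numeric(scale(x))
  data$feat_lin <- zs(pol[, 1])
  data$feat_quad <- zs(pol[, 2])
  fx <- if (is.null(loco)) "feat_lin + feat_quad"
        else paste0("(feat_lin + feat_quad) * ", loco)
  re_inner <- if (maximal) fx else "1"
  fml <- as.formula(paste0(response, " ~ ", fx,
                           " + (", re_inner, " | ", group, ")"))
  fit <- suppressMessages(lme4::lmer(
    fml, data = data, REML = FALSE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                calc.derivs = FALSE)))
  as_wm_fit(fit, label, data, response,
            fixed_terms = fx, re_spec = re_inner, group = group)
}

#' PCA-guided simplification of a random-effects structure
#'
#' Runs a principal component analysis of the fitted random-effects
#' covariance ([lme4::rePCA()]).  While some component carries less than
#' `tol` of the total random-effect variance, candidate slopes are removed
#' one at a time (interactions first, then quadratic, then remaining
#' slopes) -- but only when a likelihood-ratio test against the model
#' without that slope is non-significant.  The intercept is never removed.
#'
#' @param fit a `wm_fit` from [fit_lmm()].
#' @param tol variance-proportion threshold below which a component counts
#'   as unsupported.
#' @param alpha LRT significance level protecting a slope from removal.
#' @return list with `fit` (possibly reduced) and `audit` (a data.table
#'   recording, per examined slope, the PCA support, the LRT and the
#'   decision).
#' @export
simplify_random_structure <- function(fit, tol = 1e-6, alpha = 0.05) {
  stopifnot(inherits(fit, "wm_fit"))
  audit <- list()
  current <- fit
  repeat {
    pca <- summary(lme4::rePCA(current$fit))[[1]]
    prop <- pca$importance["Proportion of Variance", ]
    n_unsupported <- sum(prop < tol)
    if (n_unsupported == 0) break
    terms <- attr(stats::terms(as.formula(paste("~", current$re_spec))),
                  "term.labels")
    if (length(terms) == 0) break
    ord <- order(-vapply(strsplit(terms, ":", fixed = TRUE), length,
                         numeric(1)), rev(seq_along(terms)))
    dropped_any <- FALSE
    for (tm in terms[ord]) {
      reduced_terms <- setdiff(terms, tm)
      re_new <- if (length(reduced_terms) == 0) "1"
                else paste(reduced_terms, collapse = " + ")
      fml <- as.formula(paste0(current$response, " ~ ", current$fixed_terms,
                               " + (", re_new, " | ", current$group, ")"))
      cand <- suppressMessages(lme4::lmer(
        fml, data = current$data, REML = FALSE,
        control = lme4::lmerControl(optimizer = "bobyqa",
                                    calc.derivs = FALSE)))
      chisq <- 2 * (current$logLik - as.numeric(logLik(cand)))
      ddf <- current$df - attr(logLik(cand), "df")
      p <- pchisq(max(chisq, 0), max(ddf, 1), lower.tail = FALSE)
      drop_it <- p > alpha
      audit[[length(audit) + 1]] <- data.table(
        slope = tm, pca_unsupported_components = n_unsupported,
        lrt_chisq = chisq, lrt_df = ddf, lrt_p = p, dropped = drop_it)
      if (drop_it) {
        current <- as_wm_fit(cand, current$label, current$data,
                             current$response, current$fixed_terms,
                             re_spec = re_new, group = current$group)
        dropped_any <- TRUE
        break
      }
    }
    if (!dropped_any) break
    if (current$re_spec == "1") break
  }
  list(fit = current,
       audit = if (length(audit) > 0) rbindlist(audit)
               else data.table(slope = character(),
                               pca_unsupported_components = integer(),
                               lrt_chisq = numeric(), lrt_df = numeric(),
                               lrt_p = numeric(), dropped = logical()))
}

#' Planned paired t tests between neighboring conditions
#'
#' For each feature count in `k_levels` and each neighboring pair of
#' conditions, a within-subject paired t test of the per-participant
#' percentages, with Cohen's d for paired data (mean difference over the SD
#' of the differences) and the 95% CI of the mean difference.
#'
#' @param cells per-cell percentage table (`cells` element of
#'   [feature_probabilities()], or any table with `participant`,
#'   `condition_deg`, `k_bin`, `pct`).
#' @param k_levels feature counts to test.
#' @return data.table with one row per comparison: `k_bin`, `cond_a`,
#'   `cond_b`, `t`, `df`, `p`, `cohens_d`, `mean_diff`, `ci_lo`, `ci_hi`,
#'   `n_pairs`.  Incomplete cells reduce to pairwise-complete participants
#'   with a warning.
#' @export
paired_feature_tests <- function(cells, k_levels = 1:4) {
  cells <- as.data.table(cells)
  pairs <- data.table(cond_a = CONDITIONS[-length(CONDITIONS)],
                      cond_b = CONDITIONS[-1])
  rows <- list()
  for (kl in as.character(k_levels)) {
    for (j in seq_len(nrow(pairs))) {
      a <- cells[k_bin == kl & condition_deg == pairs$cond_a[j],
                 .(participant, pct_a = pct)]
      b <- cells[k_bin == kl & condition_deg == pairs$cond_b[j],
                 .(participant, pct_b = pct)]
      ab <- merge(a, b, by = "participant")
      if (nrow(ab) < nrow(a) || nrow(ab) < nrow(b))
        warning("incomplete cells for k=", kl, ", ", pairs$cond_a[j], " vs ",
                pairs$cond_b[j], "; using pairwise-complete participants")
      if (nrow(ab) < 2) next
      d <- ab$pct_a - ab$pct_b
      sd_d <- sd(d)
      if (sd_d > 0) {
        tt <- t.test(ab$pct_a, ab$pct_b, paired = TRUE)
        row <- data.table(
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, cohens_d = mean(d) / sd_d, mean_diff = mean(d),
          ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2])
      } else {
        # identical paired vectors: degenerate test
        row <- data.table(t = 0, df = nrow(ab) - 1, p = 1, cohens_d = 0,
                          mean_diff = mean(d), ci_lo = mean(d),
                          ci_hi = mean(d))
      }
      rows[[length(rows) + 1]] <- data.table(
        k_bin = kl, cond_a = pairs$cond_a[j], cond_b = pairs$cond_b[j],
        row, n_pairs = nrow(ab))
    }
  }
  rbindlist(rows)
}
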