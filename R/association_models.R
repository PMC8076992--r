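# Bivariate random-intercept models per sleep feature, Wald z inference,
# Benjamini-Hochberg correction, Box-Cox fallback, Spearman checks.

#' Fit one feature-outcome random-intercept linear mixed model
#'
#' Fits, by restricted maximum likelihood with \pkg{lme4}, the bivariate
#' model with the sleep feature as the response and the depression score
#' as the predictor:
#' \deqn{Sleep_{ijk} = \delta_{000} + V_{00k} + U_{0jk} +
#'   \beta_1 PHQ8_{ijk} + \beta_2 age + \beta_3 gender +
#'   \beta_4 education + \beta_5 income + \epsilon_{ijk}}
#' with a participant random intercept \eqn{U_{0jk}} and, for the
#' three-level model, a site random intercept \eqn{V_{00k}}. Confounders
#' (baseline age, gender, education, income) enter as fixed effects with
#' treatment coding (references: female, below_degree, lt15k); a
#' confounder that is constant in the supplied records is dropped from
#' the design rather than producing a rank-deficient fit. Inference on
#' the slope is Wald: `z = beta1 / se`, two-sided p from the standard
#' normal, 95% CI `beta1 +/- 1.96 se`.
#'
#' With `boxcox = "auto"`, residual skewness is checked after the first
#' fit; when its absolute value exceeds 1 the response is Box-Cox
#' transformed ([boxcox_transform()]) and the model refit, with the
#' selected lambda reported.
#'
#' @param records Analysis records ([join_records()] /
#'   [filter_records()]).
#' @param feature One of [sleep_feature_names()]. Rows where the feature
#'   is missing are excluded from this model only.
#' @param outcome `"phq8_total"` or `"sleep_subscore"`.
#' @param levels `"three_level"` (participant + site random intercepts;
#'   requires >= 2 sites) or `"two_level"` (participant only).
#' @param boxcox `"never"` or `"auto"`.
#' @return One-row tibble (a model result): `feature`, `outcome`,
#'   `levels`, `beta1`, `se`, `ci_low`, `ci_high`, `z`, `p`,
#'   `boxcox_lambda`, `n_obs`, `n_participants`, `n_sites`.
#' @export
fit_lmm <- function(records,
                    feature,
                    outcome = c("phq8_total", "sleep_subscore"),
                    levels = c("three_level", "two_level"),
                    boxcox = c("never", "auto")) {
  outcome <- match.arg(outcome)
  levels <- match.arg(levels)
  boxcox <- match.arg(boxcox)
  if (!feature %in% names(records))
    stop("unknown feature '", feature, "'", call. = FALSE)

  d <- records[!is.na(records[[feature]]) & !is.na(records[[outcome]]), ,
               drop = FALSE]
  d <- droplevels(d)
  if (nrow(d) < 3L)
    stop("too few observations for feature '", feature, "'",
         call. = FALSE)
  y <- d[[feature]]
  if (isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0)
    stop("feature '", feature, "' is constant; model is singular",
         call. = FALSE)
  n_sites <- length(unique(d$site_id))
  if (levels == "three_level" && n_sites < 2L)
    stop("three_level model requires >= 2 sites", call. = FALSE)

  # fixed-effect terms: outcome + confounders that vary in this subset
  conf <- character()
  if (stats::var(d$age) > 0) conf <- c(conf, "age")
  for (v in c("gender", "education", "income"))
    if (length(unique(d[[v]])) > 1L) conf <- c(conf, v)
  re <- if (levels == "three_level")
    "(1 | participant_id) + (1 | site_id)" else "(1 | participant_id)"
  rhs <- paste(c(outcome, conf, re), collapse = " + ")

  fit_once <- function(dd, resp_col) {
    form <- stats::as.formula(paste(resp_col, "~", rhs))
    withCallingHandlers(
      lme4::lmer(form, data = dd, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore",
                   check.conv.hess = "ignore",
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.nRE = "ignore")),
      message = function(m) invokeRestart("muffleMessage"))
  }

  d$.response <- y
  fit <- fit_once(d, ".response")
  lambda <- NA_real_
  if (boxcox == "auto" &&
      abs(sample_skewness(stats::residuals(fit))) > 1) {
    bc <- boxcox_transform(y)
    d$.response <- bc$transformed
    fit <- fit_once(d, ".response")
    lambda <- bc$lambda
  }

  fe <- lme4::fixef(fit)
  if (!outcome %in% names(fe))
    stop("model did not estimate a slope for ", outcome,
         " (singular design)", call. = FALSE)
  beta1 <- unname(fe[[outcome]])
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[[outcome]])
  z <- beta1 / se
  tibble::tibble(
    feature = feature, outcome = outcome, levels = levels,
    beta1 = beta1, se = se,
    ci_low = beta1 - 1.96 * se, ci_high = beta1 + 1.96 * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    boxcox_lambda = lambda,
    n_obs = nrow(d),
    n_participants = length(unique(d$participant_id)),
    n_sites = n_sites)
}

#' Fit all feature models for one outcome and adjust p values
#'
#' Fits [fit_lmm()] for each feature and applies Benjamini-Hochberg
#' correction across the fitted family (the 18 features of one outcome
#' on one dataset, mirroring a per-table analysis). Features whose model
#' cannot be fit (e.g. constant in the data) are skipped with a warning
#' and do not enter the BH family.
#'
#' @inheritParams fit_lmm
#' @param features Feature names to fit (default all 18).
#' @return Tibble of model results with a `p_bh` column.
#' @export
fit_all_models <- function(records,
                           outcome = c("phq8_total", "sleep_subscore"),
                           levels = c("three_level", "two_level"),
                           features = sleep_feature_names(),
                           boxcox = c("never", "auto")) {
  outcome <- match.arg(outcome)
  levels <- match.arg(levels)
  boxcox <- match.arg(boxcox)
  rows <- lapply(features, function(f) {
    tryCatch(fit_lmm(records, f, outcome, levels, boxcox),
             error = function(e) {
               warning("feature '", f, "' skipped: ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_bh <- benjamini_hochberg(out$p)
  out
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' Sort the m raw p values ascending; the adjusted value of the k-th is
#' `min over k' >= k of p_(k') * m / k'`, clipped at 1, mapped back to
#' the input order. Controls the false discovery rate across the family.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.005, 0.03, 0.5))
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p values must be finite and in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Box-Cox transformation with profile-likelihood lambda
#'
#' Selects lambda on the grid \[-2, 2\] in steps of 0.01 by maximizing
#' the profile log-likelihood of the normal model for the transformed
#' response, and returns `(y^lambda - 1) / lambda` (or `log(y)` at
#' lambda = 0). Non-positive responses are first shifted by
#' `1 - min(y)`; the shift is reported.
#'
#' @param y Numeric response vector (constant input is an error).
#' @return List with `transformed`, `lambda`, `shift`.
#' @export
boxcox_transform <- function(y) {
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (stats::var(y) == 0)
    stop("constant response: Box-Cox transform undefined", call. = FALSE)
  shift <- 0
  if (min(y) <= 0) {
    shift <- 1 - min(y)
    y <- y + shift
  }
  n <- length(y)
  slog <- sum(log(y))
  grid <- seq(-2, 2, by = 0.01)
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    -n / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * slog
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(transformed = z, lambda = lambda, shift = shift)
}

#' Spearman rank correlation with Fisher-transform inference
#'
#' Computes the Spearman coefficient as the product-moment correlation
#' of mid-ranks (average ranks for ties), with the large-sample normal
#' approximation `z = atanh(r) * sqrt(n - 3)` for the test and a
#' Fisher-transform 95% confidence interval.
#'
#' @param x,y Equal-length numeric vectors, n >= 3. Pairs with a missing
#'   value are dropped.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `z`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("need >= 3 complete pairs of equal length", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero variance in ranks: correlation undefined", call. = FALSE)
  r <- stats::cor(rx, ry)
  fz <- atanh(min(max(r, -1), 1))
  z <- fz * sqrt(n - 3)
  tibble::tibble(
    r = r,
    ci_low = tanh(fz - 1.96 / sqrt(n - 3)),
    ci_high = tanh(fz + 1.96 / sqrt(n - 3)),
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    n = n)
}
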