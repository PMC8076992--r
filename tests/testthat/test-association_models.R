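test_that("noise-free linear data recovers the exact slope", {
  d <- make_analysis_records(5, 4, beta = 0.035, noise_sd = 0)
  m <- fit_lmm(d, "Awake_pct", "phq8_total", "two_level")
  expect_equal(m$beta1, 0.035, tolerance = 1e-8)
  expect_lt(m$se, 1e-6)
  expect_equal(sign(m$z), sign(m$beta1))
  expect_true(m$ci_low <= m$beta1 && m$beta1 <= m$ci_high)
})

test_that("one record per participant reduces to the pooled OLS slope", {
  d <- make_analysis_records(30, 1, beta = 0.02, noise_sd = 1.5, seed = 3)
  m <- fit_lmm(d, "Awake_pct", "phq8_total", "two_level")
  ols <- unname(stats::coef(stats::lm(Awake_pct ~ phq8_total, data = d))[2])
  expect_equal(m$beta1, ols, tolerance = 1e-4)
})

test_that("single-site three-level request errors; constant feature errors", {
  d <- make_analysis_records(6, 3, noise_sd = 1)
  expect_error(fit_lmm(d, "Awake_pct", "phq8_total", "three_level"),
               "sites")
  d$Awake_pct <- 5
  expect_error(fit_lmm(d, "Awake_pct", "phq8_total", "two_level"),
               "constant")
  expect_error(fit_lmm(d, "not_a_feature", "phq8_total", "two_level"),
               "unknown feature")
})

test_that("site intercept with a single site collapses to the 2-level fit", {
  # multi-site data fit with both models after restricting to one site
  cfg <- sim_config(participants_per_site = 8, followup_weeks = 12,
                    seed = 19)
  co <- simulate_cohort(cfg, realize = "nights")
  fv <- extract_all_features(co$nights, co$phq8)
  rec <- filter_records(
    join_records(fv, co$phq8, co$demographics),
    inclusion_config(date_cutoff = as.Date("2100-01-01")))
  one_site <- rec[rec$site_id == rec$site_id[1], ]
  m2 <- fit_lmm(one_site, "Av_tst", "phq8_total", "two_level")
  # a site random intercept over one site has variance driven to 0
  one_site2 <- one_site
  m3 <- tryCatch(
    fit_lmm(dplyr::mutate(one_site2, site_id = "only"), "Av_tst",
            "phq8_total", "two_level"),
    error = function(e) NULL)
  expect_equal(m3$beta1, m2$beta1, tolerance = 1e-6)
  expect_equal(m3$se, m2$se, tolerance = 1e-6)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.03, 0.5)),
               c(0.015, 0.045, 0.5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(8, {
    for (i in 1:50) {
      p <- stats::runif(sample(1:50, 1))
      adj <- benjamini_hochberg(p)
      expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
})

test_that("Box-Cox grid search finds sensible lambdas", {
  withr::with_seed(21, {
    y_norm <- stats::rnorm(800, 20, 2)
    bc <- boxcox_transform(y_norm)
    expect_lt(abs(bc$lambda - 1), 0.5)
    y_log <- exp(stats::rnorm(800))
    bc2 <- boxcox_transform(y_log)
    expect_lt(abs(bc2$lambda), 0.15)
    expect_equal(bc2$transformed, log(y_log), tolerance = 0.2)
  })
  # shift reported for non-positive input
  bc3 <- boxcox_transform(c(-1, 0, 2, 5, 9, 3))
  expect_equal(bc3$shift, 2)
  expect_error(boxcox_transform(rep(3, 10)), "constant")
})

test_that("auto Box-Cox triggers on skewed residuals and reports lambda", {
  withr::with_seed(14, {
    d <- make_analysis_records(40, 4, beta = 0, noise_sd = 0)
    d$Awake_pct <- exp(stats::rnorm(nrow(d), 1, 0.9))  # heavily skewed
  })
  m <- fit_lmm(d, "Awake_pct", "phq8_total", "two_level", boxcox = "auto")
  expect_false(is.na(m$boxcox_lambda))
  m0 <- fit_lmm(d, "Awake_pct", "phq8_total", "two_level", boxcox = "never")
  expect_true(is.na(m0$boxcox_lambda))
})

test_that("Spearman agrees with the direct rank formula and handles ties", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$r, 1)
  withr::with_seed(9, {
    for (i in 1:20) {
      x <- stats::runif(5)
      y <- sample(5)
      out <- spearman_corr(x, y)
      expect_equal(out$r, stats::cor(x, y, method = "spearman"),
                   tolerance = 1e-12)
      expect_true(out$ci_low <= out$r && out$r <= out$ci_high)
    }
    # mid-ranks for ties match base R
    x <- c(1, 2, 2, 3, 5, 5, 7)
    y <- c(2, 1, 4, 4, 6, 8, 9)
    expect_equal(spearman_corr(x, y)$r,
                 stats::cor(x, y, method = "spearman"))
  })
  expect_error(spearman_corr(1:5, rep(2, 5)), "variance")
  expect_error(spearman_corr(1:2, 1:2), ">= 3")
})

test_that("fit_all_models returns one row per feature with BH column", {
  cfg <- sim_config(participants_per_site = 8, followup_weeks = 12,
                    seed = 31)
  co <- simulate_cohort(cfg, realize = "nights")
  fv <- extract_all_features(co$nights, co$phq8)
  rec <- filter_records(
    join_records(fv, co$phq8, co$demographics),
    inclusion_config(date_cutoff = as.Date("2100-01-01")))
  res <- suppressWarnings(fit_all_models(rec, "phq8_total", "three_level"))
  expect_lte(nrow(res), 18L)
  expect_gte(nrow(res), 16L)
  expect_true(all(res$p_bh >= res$p - 1e-15))
  expect_true(all(res$ci_low <= res$beta1 & res$beta1 <= res$ci_high))
  expect_true(all(sign(res$z) == sign(res$beta1)))
})
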