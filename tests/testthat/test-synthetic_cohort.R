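test_that("synthesized nights realize their targets exactly", {
  t <- night_targets(as.Date("2019-05-06"), tst_min = 420,
                     frac_light = 0.714, frac_deep = 0.143,
                     frac_rem = 0.143, latency_min = 15,
                     awakenings = 40, onset_clock = 23.5)
  sess <- synthesize_night(t)
  n <- compute_nights(as_sleep_sessions(sess))
  expect_equal(n$tst_h, 7)                      # TST exact
  expect_equal(n$onset_h, 23.5, tolerance = 1e-9)
  expect_equal(n$n_awakenings_gt5, 1L)
  expect_true(n$has_awakening_ge30)
  expect_equal(n$min_awake, 55)
  # stage minutes equal the largest-remainder allocation
  expect_equal(c(n$min_light, n$min_deep, n$min_rem), c(300, 60, 60))

  # no awakenings, no latency -> perfect efficiency
  t2 <- night_targets(as.Date("2019-05-06"), 400, 0.6, 0.2, 0.2)
  n2 <- compute_nights(as_sleep_sessions(synthesize_night(t2)))
  expect_equal(n2$efficiency_pct, 100)

  # long target night is a hypersomnia day downstream
  t3 <- night_targets(as.Date("2019-05-06"), 620, 0.6, 0.2, 0.2)
  n3 <- compute_nights(as_sleep_sessions(synthesize_night(t3)))
  expect_true(n3$is_hypersomnia_day)
})

test_that("infeasible targets are rejected", {
  expect_error(night_targets(Sys.Date(), 400, 0.6, 0.3, 0.3), "sum to 1")
  expect_error(night_targets(Sys.Date(), 0, 0.6, 0.2, 0.2), "positive")
  # more awakenings than interior cycle boundaries
  t <- night_targets(Sys.Date(), 100, 0.6, 0.2, 0.2,
                     awakenings = c(10, 10, 10))
  expect_error(synthesize_night(t), "boundaries")
})

test_that("night-level realization equals session realization metric for metric", {
  cfg <- sim_config(participants_per_site = 4, followup_weeks = 8,
                    seed = 99)
  fast <- simulate_cohort(cfg, realize = "nights")$nights
  slow <- suppressMessages(
    compute_nights(simulate_cohort(cfg, realize = "sessions")$sessions))
  fast <- fast[order(fast$participant_id, fast$anchor_date), ]
  slow <- slow[order(slow$participant_id, slow$anchor_date), ]
  expect_equal(nrow(fast), nrow(slow))
  for (cn in names(fast)) {
    if (is.numeric(fast[[cn]])) {
      expect_equal(fast[[cn]], slow[[cn]], tolerance = 1e-9, label = cn)
    } else {
      expect_equal(as.vector(fast[[cn]]), as.vector(slow[[cn]]),
                   label = cn)
    }
  }
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  cfg <- sim_config(participants_per_site = 3, followup_weeks = 8,
                    seed = 7)
  a <- simulate_cohort(cfg, realize = "nights")
  b <- simulate_cohort(cfg, realize = "nights")
  expect_identical(a$nights, b$nights)
  expect_identical(a$phq8, b$phq8)
  expect_identical(a$demographics, b$demographics)
  cfg2 <- cfg; cfg2$seed <- 8L
  c <- simulate_cohort(cfg2, realize = "nights")
  expect_false(identical(a$nights, c$nights))
})

test_that("generated PHQ-8 items are in range and sum to the total", {
  co <- simulate_cohort(sim_config(participants_per_site = 6,
                                   followup_weeks = 10, seed = 13),
                        realize = "nights")
  items <- as.matrix(co$phq8[paste0("item", 1:8)])
  expect_true(all(items >= 0 & items <= 3))
  expect_equal(unname(rowSums(items)), as.numeric(co$phq8$total))
  expect_equal(co$phq8$sleep_subscore, co$phq8$item3)
  expect_true(all(co$phq8$total >= 0 & co$phq8$total <= 24))
})

test_that("null couplings yield mostly non-significant slopes", {
  # modest replicate count as a unit-level sanity check; the full null
  # calibration runs in the acceptance suite
  hits <- 0L
  for (r in 1:10) {
    cfg <- sim_config(participants_per_site = 20, followup_weeks = 12,
                      couplings = list(), night_missing_prob = 0,
                      phq8_missing_prob = 0, seed = 400 + r)
    co <- simulate_cohort(cfg, realize = "nights")
    fv <- extract_all_features(co$nights, co$phq8)
    rec <- filter_records(
      join_records(fv, co$phq8, co$demographics),
      inclusion_config(date_cutoff = as.Date("2100-01-01")))
    m <- fit_lmm(rec, "Av_tst", "phq8_total", "three_level")
    if (abs(m$z) > 1.96) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("an injected awake-percentage coupling is recovered in sign", {
  pos <- 0L
  for (r in 1:5) {
    cfg <- sim_config(participants_per_site = 30, followup_weeks = 12,
                      couplings = list(awake_pct = 0.035),
                      night_missing_prob = 0, phq8_missing_prob = 0,
                      seed = 600 + r)
    co <- simulate_cohort(cfg, realize = "nights")
    fv <- extract_all_features(co$nights, co$phq8)
    rec <- filter_records(
      join_records(fv, co$phq8, co$demographics),
      inclusion_config(date_cutoff = as.Date("2100-01-01")))
    m <- fit_lmm(rec, "Awake_pct", "phq8_total", "three_level")
    if (m$beta1 > 0) pos <- pos + 1L
  }
  expect_gte(pos, 4L)
})

test_that("cohort export writes the canonical formats and re-reads", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(participants_per_site = 2,
                                   followup_weeks = 8, seed = 3),
                        realize = "sessions")
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  ss <- read_sessions(paths[["sessions"]])
  expect_equal(nrow(ss), nrow(co$sessions))
  ph <- read_phq8(paths[["phq8"]])
  expect_equal(ph$total, co$phq8$total)
  demo <- read_demographics(paths[["demographics"]])
  expect_equal(demo$participant_id, co$demographics$participant_id)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$couplings$awake_pct, 0)
})
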