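test_that("anchor date follows the noon rule", {
  expect_equal(assign_anchor_date(
    as.POSIXct("2019-03-04 23:00:00", tz = "UTC")),
    as.Date("2019-03-04"))
  expect_equal(assign_anchor_date(
    as.POSIXct("2019-03-09 00:30:00", tz = "UTC")),
    as.Date("2019-03-08"))
  # boundary: exactly noon belongs to its own date
  expect_equal(assign_anchor_date(
    as.POSIXct("2019-03-04 12:00:00", tz = "UTC")),
    as.Date("2019-03-04"))
})

test_that("main-sleep selection keeps the longest session, earliest on tie", {
  long <- make_session(c("light"), c(480), "2019-03-04 23:00:00",
                       session = "long")
  nap <- make_session(c("light"), c(45), "2019-03-04 14:00:00",
                      session = "nap")
  picked <- select_main_sleep(dplyr::bind_rows(nap, long))
  expect_equal(unique(picked$session_id), "long")

  a <- make_session(c("light"), c(300), "2019-03-04 22:00:00",
                    session = "a")
  b <- make_session(c("light"), c(300), "2019-03-04 23:00:00",
                    session = "b")
  expect_equal(unique(select_main_sleep(dplyr::bind_rows(b, a))$session_id),
               "a")
  expect_equal(unique(select_main_sleep(a)$session_id), "a")
  expect_error(select_main_sleep(a[0, ]), "no sessions")
})

test_that("night metrics match hand-derived values for the worked nights", {
  nights <- worked_fixture_nights()
  A <- nights[nights$anchor_date == as.Date("2019-03-06"), ]
  expect_equal(A$tib_h, 8)
  expect_equal(A$tst_h, 7)
  expect_equal(A$onset_h, 23.25)
  expect_equal(A$offset_h, 30 + 55 / 60)
  expect_equal(A$rem_latency_h, 4)
  expect_equal(A$n_awakenings_gt5, 1L)
  expect_true(A$has_awakening_ge30)
  expect_equal(A$efficiency_pct, 87.5)
  expect_equal(100 * A$min_awake / (A$tib_h * 60), 12.5)
  expect_equal(100 * A$min_light / (A$tib_h * 60), 62.5)
  expect_false(A$is_weekend_night)

  B <- nights[nights$anchor_date == as.Date("2019-03-08"), ]
  expect_equal(B$tib_h, 5.5)
  expect_equal(B$tst_h, 5.5)
  expect_equal(B$onset_h, 24.5)
  expect_equal(B$offset_h, 30)
  expect_equal(B$rem_latency_h, 5)
  expect_equal(B$n_awakenings_gt5, 0L)
  expect_false(B$has_awakening_ge30)
  expect_equal(B$efficiency_pct, 100)
  expect_true(B$is_weekend_night)
})

test_that("a night of pure light sleep has full efficiency, no REM latency", {
  ss <- as_sleep_sessions(make_session("light", 300, "2019-03-04 23:00:00"))
  n <- compute_nights(ss)
  expect_equal(n$tst_h, n$tib_h)
  expect_equal(n$efficiency_pct, 100)
  expect_true(is.na(n$rem_latency_h))
})

test_that("entirely awake sessions are rejected during night scoring", {
  ss <- as_sleep_sessions(make_session("awake", 120, "2019-03-04 23:00:00"))
  n <- suppressMessages(compute_nights(ss))
  expect_equal(nrow(n), 0L)
  expect_match(rejected_sessions(n)$reason, "awake")
})

test_that("insomnia and hypersomnia flags apply the literal thresholds", {
  base <- worked_fixture_nights()[1, ]
  # insomnia: BOTH short sleep and a prolonged awakening
  n1 <- base; n1$tst_h <- 5.8; n1$has_awakening_ge30 <- TRUE
  expect_true(classify_night_flags(n1)$is_insomnia_day)
  n2 <- base; n2$tst_h <- 5.5; n2$has_awakening_ge30 <- FALSE
  expect_false(classify_night_flags(n2)$is_insomnia_day)
  n3 <- base; n3$tst_h <- 6.0; n3$has_awakening_ge30 <- TRUE
  expect_false(classify_night_flags(n3)$is_insomnia_day)
  # hypersomnia strictly above 10 h
  n4 <- base; n4$tst_h <- 10.0
  expect_false(classify_night_flags(n4)$is_hypersomnia_day)
  n5 <- base; n5$tst_h <- 10.01
  expect_true(classify_night_flags(n5)$is_hypersomnia_day)
})

test_that("stage percentages are complementary and order-invariant", {
  withr::with_seed(11, {
    for (i in 1:25) {
      stages <- sample(c("awake", "light", "deep", "rem"), 8,
                       replace = TRUE, prob = c(0.2, 0.45, 0.15, 0.2))
      if (all(stages == "awake")) stages[1] <- "light"
      dur <- sample(5:90, 8, replace = TRUE)
      seg <- make_session(stages, dur, "2019-03-04 22:00:00")
      n <- compute_nights(as_sleep_sessions(seg))
      pct <- 100 * c(n$min_awake, n$min_light, n$min_deep, n$min_rem) /
        (n$tib_h * 60)
      expect_equal(sum(pct), 100, tolerance = 1e-9)
      expect_equal(n$efficiency_pct, 100 - pct[1], tolerance = 1e-9)
      if (!is.na(n$rem_latency_h)) expect_gte(n$rem_latency_h, 0)
      expect_lte(n$offset_h - n$onset_h, n$tib_h + 1e-9)

      # permuting input row order leaves the record unchanged
      n2 <- compute_nights(as_sleep_sessions(seg[sample(8), ]))
      expect_equal(as.data.frame(n2), as.data.frame(n))
    }
  })
})
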