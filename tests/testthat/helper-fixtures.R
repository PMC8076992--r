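# Fixtures shared across test files, built in code.

# Segment tibble from a compact spec: stages and durations laid end to
# end from `start`.
make_session <- function(stages, durations, start, participant = "p1",
                         site = "s1", session = "sess1") {
  start <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(
    participant_id = participant, site_id = site, session_id = session,
    stage = stages,
    start = start + c(0, cumsum(utils::head(durations, -1L))) * 60,
    duration_min = as.numeric(durations))
}

# The two-night worked fixture: Night A is a weekday night (Wed
# 2019-03-06), Night B a weekend night (starts Sat 00:30, anchored to
# Fri 2019-03-08).
night_A_segments <- function(participant = "p1") {
  make_session(c("awake", "light", "deep", "rem", "awake", "light",
                 "awake"),
               c(15, 180, 60, 60, 40, 120, 5),
               "2019-03-06 23:00:00", participant, session = "A")
}

night_B_segments <- function(participant = "p1") {
  make_session(c("light", "deep", "rem"), c(270, 30, 30),
               "2019-03-09 00:30:00", participant, session = "B")
}

worked_fixture_nights <- function() {
  ss <- as_sleep_sessions(dplyr::bind_rows(night_A_segments(),
                                           night_B_segments()))
  compute_nights(ss)
}

# Hand-derived expectations for the worked fixture's feature vector.
worked_fixture_expected <- function() {
  c(Av_tst = 6.25, Av_time_bed = 6.75,
    Deep_pct = (12.5 + 100 * 30 / 330) / 2,
    Light_pct = (62.5 + 100 * 270 / 330) / 2,
    REM_pct = (12.5 + 100 * 30 / 330) / 2,
    NREM_pct = (75 + 100 * 300 / 330) / 2,
    Awake_pct = 6.25,
    Av_onset = (23.25 + 24.5) / 2, Av_offset = (30 + 55 / 60 + 30) / 2,
    REM_L = 4.5,
    Std_tst = stats::sd(c(7, 5.5)),
    Std_onset = stats::sd(c(23.25, 24.5)),
    Std_offset = stats::sd(c(30 + 55 / 60, 30)),
    Efficiency = 93.75, Awake_5 = 0.5, WKD_diff = -1.5,
    M_insomnia = 0, Dur_10 = 0)
}

# Minimal analysis-record frame with constant confounders for model
# tests; one row per (participant, record).
make_analysis_records <- function(n_participants, records_each,
                                  beta = 0.035, noise_sd = 0,
                                  intercept_sd = 0, seed = 1,
                                  site = "s1") {
  withr::with_seed(seed, {
    n <- n_participants * records_each
    pid <- rep(sprintf("p%03d", seq_len(n_participants)),
               each = records_each)
    phq <- sample(0:24, n, replace = TRUE)
    u <- rep(stats::rnorm(n_participants, 0, intercept_sd),
             each = records_each)
    tibble::tibble(
      participant_id = pid, site_id = site,
      phq8_ts = as.POSIXct("2019-06-01", tz = "UTC") + seq_len(n) * 86400,
      n_nights = 14L,
      phq8_total = phq, sleep_subscore = pmin(3L, phq %/% 8L),
      complete = TRUE,
      Awake_pct = 8 + u + beta * phq + stats::rnorm(n, 0, noise_sd),
      age = 40,
      gender = factor("female", c("female", "male", "other")),
      education = factor("below_degree",
                         c("below_degree", "degree_or_above")),
      income = factor("lt15k",
                      c("lt15k", "15k_40k", "gt40k", "not_mentioned")))
  })
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# sort ascending, q_(k) = min over k' >= k of p_(k') * m / k', clip at
# 1, map back. Independent oracle for the packaged implementation.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(k)
    min(1, min(ps[k:m] * m / (k:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random but valid night targets for round-trip testing.
random_night_targets <- function() {
  tst <- sample(180:700, 1L)
  deep <- stats::runif(1, 0.08, 0.28)
  rem <- stats::runif(1, 0.08, 0.3)
  n_c <- max(1, ceiling(tst / 90))
  k <- sample(0:min(3, n_c - 1L), 1L)
  night_targets(
    date = as.Date("2019-05-01") + sample(0:300, 1L),
    tst_min = tst,
    frac_light = 1 - deep - rem, frac_deep = deep, frac_rem = rem,
    latency_min = sample(0:45, 1L),
    awakenings = if (k) sample(6:45, k, replace = TRUE) else integer(),
    onset_clock = stats::runif(1, 20.5, 26.5),
    rem_first_cycle = sample(1:2, 1L))
}
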