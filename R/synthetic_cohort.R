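# Multi-site synthetic longitudinal cohort generator: latent depressive
# severity drives PHQ-8 trajectories and nightly hypnogram targets with
# known, configurable couplings, so pipeline tests and recovery studies
# run without any real cohort.

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic cohort: three
#' heterogeneous sites by default (one emulating a clinical population
#' with higher baseline severity), biweekly PHQ-8 assessments, a latent
#' AR(1) severity process per participant, and nightly sleep targets
#' that are linear (or, for binary night events, logistic) functions of
#' concurrent severity.
#'
#' Couplings are per PHQ-8 point on the feature's own scale:
#' `tst_h` (hours/point), `awake_pct` (percentage points/point, default
#' 0.035 - the scale of published wearable-cohort estimates), `onset_h`
#' (hours/point), `prolonged_awakening` and `hypersomnia` (log-odds per
#' point for the corresponding night events). Sleep offset is onset plus
#' time in bed, so its (positive) coupling is emergent rather than
#' directly injected.
#'
#' @param n_sites Number of sites (default 3).
#' @param participants_per_site Scalar or length-`n_sites` vector.
#' @param followup_weeks Follow-up length (>= 6 so that >= 3 PHQ-8
#'   records are possible).
#' @param phq8_period_days Days between PHQ-8 records (default 14).
#' @param start_date Enrollment date (first PHQ-8 falls one period
#'   later).
#' @param site_severity_means Baseline PHQ-8 location per site; the
#'   default `c(6, 10, 5)` makes the second site the clinical one.
#' @param between_participant_sd SD of participant severity intercepts.
#' @param ar1_rho,ar1_sd Stationary AR(1) correlation and marginal SD of
#'   the within-participant severity dynamics.
#' @param couplings Named list of injected depression-sleep slopes (see
#'   above); omitted names default to 0.
#' @param subscore_noise_sd SD of the noise on the sleep item (item 3)
#'   around its severity-proportional target; smaller values couple the
#'   sleep subscore more tightly to the total.
#' @param night_missing_prob,phq8_missing_prob Record-level missingness.
#' @param rem_cycle2_prob Probability that a night's first REM block
#'   falls in sleep cycle 2 rather than cycle 1 (controls REM latency).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`, including a `base` sub-list of
#'   night-level baselines and noise SDs.
#' @export
sim_config <- function(n_sites = 3L,
                       participants_per_site = 20L,
                       followup_weeks = 26L,
                       phq8_period_days = 14L,
                       start_date = as.Date("2019-01-07"),
                       site_severity_means = NULL,
                       between_participant_sd = 4,
                       ar1_rho = 0.8,
                       ar1_sd = 2,
                       couplings = list(),
                       subscore_noise_sd = 0.55,
                       night_missing_prob = 0.08,
                       phq8_missing_prob = 0.10,
                       rem_cycle2_prob = 0.35,
                       seed = 1L) {
  n_sites <- as.integer(n_sites)
  site_severity_means <- site_severity_means %||%
    rep_len(c(6, 10, 5), n_sites)
  stopifnot(length(site_severity_means) == n_sites)
  if (followup_weeks < 6)
    stop("followup_weeks must be >= 6 (>= 3 PHQ-8 records)", call. = FALSE)
  for (p in c(night_missing_prob, phq8_missing_prob, rem_cycle2_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)", call. = FALSE)
  default_coup <- list(tst_h = 0, awake_pct = 0, onset_h = 0,
                       prolonged_awakening = 0, hypersomnia = 0)
  extra <- setdiff(names(couplings), names(default_coup))
  if (length(extra))
    stop("unknown coupling(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  default_coup[names(couplings)] <- couplings

  structure(list(
    n_sites = n_sites,
    participants_per_site = rep_len(as.integer(participants_per_site),
                                    n_sites),
    followup_weeks = as.integer(followup_weeks),
    phq8_period_days = as.integer(phq8_period_days),
    start_date = as.Date(start_date),
    site_severity_means = site_severity_means,
    severity_center = mean(site_severity_means),
    between_participant_sd = between_participant_sd,
    ar1_rho = ar1_rho, ar1_sd = ar1_sd,
    couplings = default_coup,
    subscore_noise_sd = subscore_noise_sd,
    night_missing_prob = night_missing_prob,
    phq8_missing_prob = phq8_missing_prob,
    rem_cycle2_prob = rem_cycle2_prob,
    base = list(tst_min = 430, awake_pct = 7, onset_clock = 23.25,
                sd_tst_min = 40, sd_awake_pct = 2.5, sd_onset = 0.7,
                part_sd_tst_min = 25, part_sd_awake_pct = 1.5,
                part_sd_onset = 0.5,
                p_prolonged = 0.12, p_hypersomnia = 0.015,
                site_age_means = rep_len(c(45, 55, 40), n_sites),
                deep_frac_mean = 0.16, deep_frac_sd = 0.025,
                rem_frac_mean = 0.21, rem_frac_sd = 0.03),
    seed = as.integer(seed)),
    class = "sim_config")
}

#' Per-night sleep targets
#'
#' The quantities a synthesized night must realize: total sleep minutes,
#' stage fractions of TST (summing to 1), sleep-onset latency (initial
#' awake time), a list of awakening durations to insert strictly inside
#' the sleep period, the onset clock time (hours since 00:00 of the
#' anchor date, so 23.5 is 23:30 and 25 is 01:00 next morning), and the
#' sleep cycle (1 or 2) carrying the first REM block.
#'
#' @param date Anchor date of the night.
#' @param tst_min Total sleep minutes (positive integer).
#' @param frac_light,frac_deep,frac_rem Stage fractions of TST; must sum
#'   to 1.
#' @param latency_min Initial awake minutes before sleep onset.
#' @param awakenings Integer vector of awake-episode minutes to insert
#'   at successive sleep-cycle boundaries.
#' @param onset_clock Sleep onset in hours on the anchor-date clock axis.
#' @param rem_first_cycle 1 or 2.
#' @return A list of class `night_targets`.
#' @export
night_targets <- function(date, tst_min, frac_light, frac_deep, frac_rem,
                          latency_min = 0L, awakenings = integer(),
                          onset_clock = 23, rem_first_cycle = 1L) {
  tst_min <- as.integer(round(tst_min))
  if (tst_min <= 0) stop("tst_min must be positive", call. = FALSE)
  fr <- c(frac_light, frac_deep, frac_rem)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("stage fractions must be nonnegative and sum to 1",
         call. = FALSE)
  awakenings <- as.integer(round(awakenings))
  if (any(awakenings <= 0))
    stop("awakening durations must be positive", call. = FALSE)
  if (latency_min < 0) stop("latency_min must be >= 0", call. = FALSE)
  if (!rem_first_cycle %in% 1:2)
    stop("rem_first_cycle must be 1 or 2", call. = FALSE)
  structure(list(date = as.Date(date), tst_min = tst_min,
                 frac_light = frac_light, frac_deep = frac_deep,
                 frac_rem = frac_rem,
                 latency_min = as.integer(round(latency_min)),
                 awakenings = awakenings,
                 onset_clock = onset_clock,
                 rem_first_cycle = as.integer(rem_first_cycle)),
            class = "night_targets")
}

# Deterministic segment plan for one night: stage minutes are allocated
# to light/deep/REM by largest remainder, each stage is split evenly
# across ~90-min sleep cycles (REM only from its first cycle on, so REM
# latency is controlled), segments run light -> deep -> REM within each
# cycle, and awakening j is inserted at the boundary after cycle j.
plan_night <- function(t) {
  n <- max(1L, ceiling(t$tst_min / 90))
  rfc <- min(t$rem_first_cycle, n)
  sm <- largest_remainder(t$tst_min,
                          c(t$frac_light, t$frac_deep, t$frac_rem))
  k <- length(t$awakenings)
  if (k > n - 1L)
    stop("awakening durations exceed available cycle boundaries",
         call. = FALSE)
  light_c <- largest_remainder(sm[1L], rep(1, n))
  deep_c <- largest_remainder(sm[2L], rep(1, n))
  rem_c <- largest_remainder(sm[3L], c(rep(0, rfc - 1L),
                                       rep(1, n - rfc + 1L)))
  stage <- character(0)
  dur <- numeric(0)
  if (t$latency_min > 0) {
    stage <- "awake"; dur <- t$latency_min
  }
  for (cy in seq_len(n)) {
    cs <- c("light", "deep", "rem")
    cd <- c(light_c[cy], deep_c[cy], rem_c[cy])
    stage <- c(stage, cs[cd > 0])
    dur <- c(dur, cd[cd > 0])
    if (cy <= k) {
      stage <- c(stage, "awake")
      dur <- c(dur, t$awakenings[cy])
    }
  }
  if (stage[length(stage)] == "awake")
    stop("awakening falls after the last sleep segment; ",
         "not enough sleep in trailing cycles", call. = FALSE)
  list(stage = stage, duration_min = dur)
}

#' Realize one night's targets as a sleep-stage session
#'
#' Emits the segment sequence of [plan_night()]: the initial awake
#' latency, then the night's sleep minutes partitioned into ~90-minute
#' cycles of light/deep/REM blocks whose whole-night stage minutes equal
#' the largest-remainder allocation of `frac * tst_min`, with the
#' requested awakening episodes at cycle boundaries strictly inside the
#' sleep period. The session starts at `onset_clock - latency` on the
#' anchor-date clock axis, so derived sleep onset equals `onset_clock`
#' and derived TST equals `tst_min` exactly.
#'
#' @param t A [night_targets()] object.
#' @param participant_id,site_id,session_id Identifiers for the emitted
#'   segments (`session_id` defaults to `<participant>_<date>`).
#' @return Segment tibble in the [read_sessions()] layout.
#' @export
synthesize_night <- function(t, participant_id = "p1", site_id = "site1",
                             session_id = NULL) {
  pl <- plan_night(t)
  start0 <- as.POSIXct(paste(t$date, "00:00:00"), tz = "UTC") +
    (t$onset_clock - t$latency_min / 60) * 3600
  starts <- start0 + c(0, cumsum(utils::head(pl$duration_min, -1L))) * 60
  tibble::tibble(
    participant_id = participant_id,
    site_id = site_id,
    session_id = session_id %||% paste0(participant_id, "_", t$date),
    stage = pl$stage,
    start = starts,
    duration_min = pl$duration_min)
}

#' Night record implied by a set of night targets
#'
#' Computes, through the same segment plan used by [synthesize_night()],
#' the night metrics that [compute_nights()] would return for the
#' synthesized session - without building timestamps. Used for fast
#' night-level cohort realization.
#'
#' @inheritParams synthesize_night
#' @return One-row night-record tibble (see [compute_nights()]).
#' @export
night_record_from_targets <- function(t, participant_id = "p1",
                                      site_id = "site1") {
  pl <- plan_night(t)
  rel_start <- t$onset_clock - t$latency_min / 60 +
    c(0, cumsum(utils::head(pl$duration_min, -1L))) / 60
  m <- night_metrics_core(pl$stage, rel_start, pl$duration_min)
  out <- tibble::tibble(
    participant_id = participant_id, site_id = site_id,
    anchor_date = t$date,
    tst_h = m$tst_h, tib_h = m$tib_h,
    min_awake = m$min_awake, min_light = m$min_light,
    min_deep = m$min_deep, min_rem = m$min_rem,
    onset_h = m$onset_h, offset_h = m$offset_h,
    rem_latency_h = m$rem_latency_h,
    n_awakenings_gt5 = m$n_awakenings_gt5,
    has_awakening_ge30 = m$has_awakening_ge30,
    efficiency_pct = m$efficiency_pct,
    is_weekend_night = is_weekend_anchor(t$date))
  classify_night_flags(out)
}

# --- vectorized internals -------------------------------------------------

# Largest-remainder allocation of `total` (vector) over three weights,
# identical tie-breaking (earliest index) to largest_remainder().
lr3_vec <- function(total, w1, w2, w3) {
  s <- w1 + w2 + w3
  r1 <- total * w1 / s; r2 <- total * w2 / s; r3 <- total * w3 / s
  b1 <- floor(r1); b2 <- floor(r2); b3 <- floor(r3)
  short <- total - (b1 + b2 + b3)
  f1 <- r1 - b1; f2 <- r2 - b2; f3 <- r3 - b3
  h1 <- (f2 > f1) + (f3 > f1)
  h2 <- (f1 >= f2) + (f3 > f2)
  h3 <- (f1 >= f3) + (f2 >= f3)
  cbind(b1 + (h1 < short), b2 + (h2 < short), b3 + (h3 < short))
}

# Sum of the first `upto` shares of `total` split evenly over n slots
# (earliest slots receive the remainder), vectorized.
even_split_first <- function(total, n, upto) {
  upto * (total %/% n) + pmin(upto, total %% n)
}

# Closed-form night records for a frame of per-night targets (columns:
# participant_id, site_id, date, tst_min, frac_light/deep/rem,
# latency_min, awk1..awk4 in insertion order, rfc, onset_clock).
# Mirrors plan_night() + night_metrics_core() exactly.
nights_from_target_frame <- function(tg) {
  sm <- lr3_vec(tg$tst_min, tg$frac_light, tg$frac_deep, tg$frac_rem)
  n_c <- pmax(1, ceiling(tg$tst_min / 90))
  rfc <- pmin(tg$rfc, n_c)
  awk <- cbind(tg$awk1, tg$awk2, tg$awk3, tg$awk4)
  sum_awk <- rowSums(awk)
  min_awake <- tg$latency_min + sum_awk
  tst_h <- tg$tst_min / 60
  tib_h <- (tg$tst_min + min_awake) / 60
  awake_before_rem <- (rfc == 2) * awk[, 1L]
  rem_lat <- (even_split_first(sm[, 1L], n_c, rfc) +
                even_split_first(sm[, 2L], n_c, rfc) +
                awake_before_rem) / 60
  out <- tibble::tibble(
    participant_id = tg$participant_id, site_id = tg$site_id,
    anchor_date = tg$date,
    tst_h = tst_h, tib_h = tib_h,
    min_awake = min_awake, min_light = sm[, 1L],
    min_deep = sm[, 2L], min_rem = sm[, 3L],
    onset_h = tg$onset_clock,
    offset_h = tg$onset_clock + (tg$tst_min + sum_awk) / 60,
    rem_latency_h = ifelse(sm[, 3L] > 0, rem_lat, NA_real_),
    n_awakenings_gt5 = as.integer(rowSums(awk > 5)),
    has_awakening_ge30 = rowSums(awk >= 30) > 0,
    efficiency_pct = 100 * tst_h / tib_h,
    is_weekend_night = is_weekend_anchor(tg$date))
  classify_night_flags(out)
}

# Allocate a PHQ-8 total minus its item 3 across the other 7 items
# (each 0-3): multinomial draw with deterministic overflow repair.
allocate_phq8_items <- function(rest) {
  x <- as.vector(stats::rmultinom(1L, rest, rep(1, 7L)))
  while (any(x > 3L)) {
    excess <- sum(x[x > 3L] - 3L)
    x[x > 3L] <- 3L
    room <- 3L - x
    x <- x + largest_remainder(excess, room)
  }
  x
}

#' Simulate a multi-site longitudinal cohort
#'
#' Per participant: demographics from site-specific distributions; a
#' latent severity trajectory (site mean + participant intercept +
#' stationary AR(1) noise, clipped to the PHQ-8 range); biweekly PHQ-8
#' items whose total is the rounded severity and whose item 3 tracks a
#' sleep-disturbance index; and nightly sleep targets that are linear
#' (continuous) or logistic (night events) in the severity governing
#' the night's feature window. Targets are realized either as full
#' stage-segment sessions (`realize = "sessions"`) or directly as night
#' records (`realize = "nights"`, equivalent by construction and much
#' faster; used by the simulation studies). Records are then dropped at
#' the configured missingness rates.
#'
#' @param cfg A [sim_config()].
#' @param realize `"sessions"` or `"nights"`.
#' @return List with elements `sessions` (a `sleep_sessions` tibble, or
#'   NULL), `nights` (night records, or NULL), `phq8`, `demographics`,
#'   and `truth` (the injected couplings and generator constants).
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            realize = c("sessions", "nights")) {
  realize <- match.arg(realize)
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg, realize))
}

simulate_cohort_impl <- function(cfg, realize) {
  b <- cfg$base
  cp <- cfg$couplings
  n_rec <- (cfg$followup_weeks * 7L) %/% cfg$phq8_period_days
  period <- cfg$phq8_period_days
  n_part <- sum(cfg$participants_per_site)
  site_ids <- paste0("site", seq_len(cfg$n_sites))
  site_of <- rep(seq_len(cfg$n_sites), cfg$participants_per_site)
  pid <- sprintf("P%04d", seq_len(n_part))

  demographics <- as_demographics(data.frame(
    participant_id = pid,
    site_id = site_ids[site_of],
    age = pmin(80, pmax(18, round(stats::rnorm(
      n_part, b$site_age_means[site_of], 12)))),
    gender = sample(c("female", "male", "other"), n_part, TRUE,
                    prob = c(0.74, 0.24, 0.02)),
    education = sample(c("degree_or_above", "below_degree"), n_part, TRUE),
    income = sample(c("lt15k", "15k_40k", "gt40k", "not_mentioned"),
                    n_part, TRUE, prob = c(0.3, 0.3, 0.2, 0.2))))

  # latent severity per participant x record: site mean + intercept + AR(1)
  u <- stats::rnorm(n_part, 0, cfg$between_participant_sd)
  innov_sd <- cfg$ar1_sd * sqrt(1 - cfg$ar1_rho^2)
  e <- matrix(0, n_part, n_rec)
  e[, 1L] <- stats::rnorm(n_part, 0, cfg$ar1_sd)
  if (n_rec > 1L) for (i in 2:n_rec)
    e[, i] <- cfg$ar1_rho * e[, i - 1L] + stats::rnorm(n_part, 0, innov_sd)
  sev <- matrix(pmin(24, pmax(0, cfg$site_severity_means[site_of] + u + e)),
                n_part, n_rec)

  # PHQ-8 records at start_date + period * i, completed in the evening
  rec_part <- rep(seq_len(n_part), each = n_rec)
  rec_i <- rep(seq_len(n_rec), n_part)
  rec_date <- cfg$start_date + period * rec_i
  rec_sev <- sev[cbind(rec_part, rec_i)]
  total <- as.integer(round(rec_sev))
  item3_raw <- round(3 * total / 24 +
                       stats::rnorm(length(total), 0, cfg$subscore_noise_sd))
  item3 <- pmin(pmin(3L, total),
                pmax(pmax(0L, total - 21L), as.integer(item3_raw)))
  others <- t(vapply(total - item3, allocate_phq8_items, integer(7L)))
  items <- cbind(others[, 1:2, drop = FALSE], item3,
                 others[, 3:7, drop = FALSE])
  colnames(items) <- paste0("item", 1:8)
  phq8 <- tibble::tibble(
    participant_id = pid[rec_part],
    completion_ts = as.POSIXct(paste(rec_date, "00:00:00"), tz = "UTC") +
      round(stats::runif(length(total), 17.5, 21.5) * 3600))
  for (j in 1:8) phq8[[colnames(items)[j]]] <- as.integer(items[, j])
  phq8$complete <- TRUE
  phq8$total <- as.integer(rowSums(items))
  phq8$sleep_subscore <- as.integer(items[, 3L])

  # nightly targets; each night is governed by the severity of the PHQ-8
  # record whose feature window contains it
  n_nights <- n_rec * period
  ni_part <- rep(seq_len(n_part), each = n_nights)
  ni_day <- rep(seq_len(n_nights), n_part)
  ni_date <- cfg$start_date + (ni_day - 1L)
  ni_rec <- (ni_day - 1L) %/% period + 1L
  s <- sev[cbind(ni_part, ni_rec)] - cfg$severity_center
  nn <- length(s)

  part_tst <- stats::rnorm(n_part, 0, b$part_sd_tst_min)
  part_awk <- stats::rnorm(n_part, 0, b$part_sd_awake_pct)
  part_ons <- stats::rnorm(n_part, 0, b$part_sd_onset)

  tst <- round(b$tst_min + part_tst[ni_part] + 60 * cp$tst_h * s +
                 stats::rnorm(nn, 0, b$sd_tst_min))
  hyper <- stats::rbinom(nn, 1L, stats::plogis(
    stats::qlogis(b$p_hypersomnia) + cp$hypersomnia * s))
  tst <- tst + hyper * round(stats::runif(nn, 160, 260))
  tst <- pmin(1300, pmax(120, tst))

  a_pct <- pmin(55, pmax(0.5, b$awake_pct + part_awk[ni_part] +
                           cp$awake_pct * s +
                           stats::rnorm(nn, 0, b$sd_awake_pct)))
  awake_tot <- pmin(1440 - tst, round(a_pct / (100 - a_pct) * tst))
  latency <- round(stats::runif(nn, 0.2, 0.5) * awake_tot)
  w_int <- awake_tot - latency

  n_c <- pmax(1, ceiling(tst / 90))
  # fold interior awake into latency when no cycle boundary can host it
  no_slot <- n_c < 2
  latency[no_slot] <- latency[no_slot] + w_int[no_slot]
  w_int[no_slot] <- 0

  prolonged <- stats::rbinom(nn, 1L, stats::plogis(
    stats::qlogis(b$p_prolonged) + cp$prolonged_awakening * s)) == 1L
  d1 <- ifelse(prolonged & w_int >= 30,
               pmin(w_int, 30 + round(stats::runif(nn, 0, 15))), 0)
  rem_w <- w_int - d1
  slots <- pmin(3, n_c - 1 - (d1 > 0))
  k2 <- ifelse(rem_w > 0, pmin(slots, pmax(1, round(rem_w / 13))), 0)
  overflow <- rem_w > 0 & k2 == 0       # no slot left: grow the long one
  d1[overflow] <- d1[overflow] + rem_w[overflow]
  rem_w[overflow] <- 0
  chunk <- function(j) ifelse(k2 >= j, rem_w %/% k2 + (j <= rem_w %% k2), 0)
  c1 <- chunk(1); c2 <- chunk(2); c3 <- chunk(3)
  # slots in insertion order (after cycles 1, 2, 3, 4)
  awk1 <- ifelse(d1 > 0, d1, c1)
  awk2 <- ifelse(d1 > 0, c1, c2)
  awk3 <- ifelse(d1 > 0, c2, c3)
  awk4 <- ifelse(d1 > 0, c3, 0)

  deep_f <- pmin(0.30, pmax(0.05, stats::rnorm(nn, b$deep_frac_mean,
                                               b$deep_frac_sd)))
  rem_f <- pmin(0.35, pmax(0.05, stats::rnorm(nn, b$rem_frac_mean,
                                              b$rem_frac_sd)))
  onset <- pmin(27, pmax(20.5, b$onset_clock + part_ons[ni_part] +
                           cp$onset_h * s +
                           stats::rnorm(nn, 0, b$sd_onset)))
  rfc <- 1L + stats::rbinom(nn, 1L, cfg$rem_cycle2_prob)

  tg <- tibble::tibble(
    participant_id = pid[ni_part], site_id = site_ids[site_of[ni_part]],
    date = ni_date, tst_min = tst,
    frac_light = 1 - deep_f - rem_f, frac_deep = deep_f, frac_rem = rem_f,
    latency_min = latency, awk1 = awk1, awk2 = awk2, awk3 = awk3,
    awk4 = awk4, rfc = rfc, onset_clock = onset)

  # missingness
  tg <- tg[stats::runif(nn) >= cfg$night_missing_prob, , drop = FALSE]
  phq8 <- phq8[stats::runif(nrow(phq8)) >= cfg$phq8_missing_prob, ,
               drop = FALSE]

  truth <- list(couplings = cp, severity_center = cfg$severity_center,
                site_severity_means = cfg$site_severity_means,
                base = b, seed = cfg$seed)

  if (realize == "nights") {
    nights <- nights_from_target_frame(tg)
    nights <- nights[order(nights$participant_id, nights$anchor_date), ]
    return(list(sessions = NULL, nights = nights, phq8 = phq8,
                demographics = demographics, truth = truth))
  }
  sess <- realize_sessions(tg)
  list(sessions = sess, nights = NULL, phq8 = phq8,
       demographics = demographics, truth = truth)
}

# Build the full segment table for a frame of targets (one session per
# night) via the shared plan; deterministic given the targets.
realize_sessions <- function(tg) {
  n <- nrow(tg)
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    awk <- c(tg$awk1[i], tg$awk2[i], tg$awk3[i], tg$awk4[i])
    t <- list(date = tg$date[i], tst_min = tg$tst_min[i],
              frac_light = tg$frac_light[i], frac_deep = tg$frac_deep[i],
              frac_rem = tg$frac_rem[i], latency_min = tg$latency_min[i],
              awakenings = awk[awk > 0], onset_clock = tg$onset_clock[i],
              rem_first_cycle = tg$rfc[i])
    plans[[i]] <- plan_night(t)
  }
  lens <- vapply(plans, function(p) length(p$stage), integer(1L))
  dur <- unlist(lapply(plans, `[[`, "duration_min"))
  day0 <- as.POSIXct(paste(tg$date, "00:00:00"), tz = "UTC")
  start0 <- rep(day0 + (tg$onset_clock - tg$latency_min / 60) * 3600, lens)
  within <- sequence(lens)
  offs <- unlist(lapply(plans, function(p)
    c(0, cumsum(utils::head(p$duration_min, -1L)))))
  seg <- tibble::tibble(
    participant_id = rep(tg$participant_id, lens),
    site_id = rep(tg$site_id, lens),
    session_id = rep(paste0(tg$participant_id, "_", tg$date), lens),
    stage = unlist(lapply(plans, `[[`, "stage")),
    start = start0 + offs * 60,
    duration_min = dur)
  as_sleep_sessions(seg)
}

#' Write a simulated cohort in the canonical input formats
#'
#' Emits `segments.csv` (or `sessions.jsonl`), `phq8.csv`,
#' `demographics.csv` and `truth.json` (the injected parameters) into a
#' directory, so a simulated cohort can be re-read with the standard
#' readers.
#'
#' @param cohort Output of [simulate_cohort()] with sessions realized.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$sessions))
    stop("cohort was realized at night level; re-run simulate_cohort ",
         "with realize = 'sessions' to export raw sessions",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sessions = file.path(dir, "segments.csv"),
             phq8 = file.path(dir, "phq8.csv"),
             demographics = file.path(dir, "demographics.csv"),
             truth = file.path(dir, "truth.json"))
  write_table(cohort$sessions, paths[["sessions"]])
  phq <- cohort$phq8[, c("participant_id", "completion_ts",
                         paste0("item", 1:8))]
  write_table(phq, paths[["phq8"]])
  demo <- cohort$demographics
  names(demo)[names(demo) == "age"] <- "age"
  write_table(demo, paths[["demographics"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
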