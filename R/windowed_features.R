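# Aggregation of night records over the 2-week window before each PHQ-8
# record into the 18-feature vector.

#' Select the nights in the feature window before a questionnaire
#'
#' The feature window is the half-open date interval
#' `[date(phq8_ts) - window_days, date(phq8_ts))`: the `window_days`
#' nights ending with the night whose sleep ends on the morning of the
#' questionnaire day. The questionnaire day's own night is excluded.
#'
#' @param nights Night-record tibble (see [compute_nights()]).
#' @param phq8_ts POSIXct completion time of the PHQ-8 record.
#' @param window_days Window length in days (default 14).
#' @return The rows of `nights` whose `anchor_date` falls in the window.
#' @export
collect_window <- function(nights, phq8_ts, window_days = 14L) {
  if (window_days <= 0) stop("window_days must be positive", call. = FALSE)
  qd <- as.Date(phq8_ts, tz = "UTC")
  nights[nights$anchor_date >= qd - window_days &
           nights$anchor_date < qd, , drop = FALSE]
}

# Feature computation on per-night vectors. Means over nights for level
# features; sample SD (n-1) for stability features (missing when < 2
# nights); REM latency averaged over nights where it is defined; weekend
# catch-up sleep needs both a weekend and a weekday night.
extract_features_core <- function(tst_h, tib_h, min_awake, min_light,
                                  min_deep, min_rem, onset_h, offset_h,
                                  rem_latency_h, n_awakenings_gt5,
                                  is_insomnia, is_hypersomnia, is_weekend) {
  n <- length(tst_h)
  tib_min <- tib_h * 60
  awake_pct <- 100 * min_awake / tib_min
  light_pct <- 100 * min_light / tib_min
  deep_pct <- 100 * min_deep / tib_min
  rem_pct <- 100 * min_rem / tib_min
  rem_def <- !is.na(rem_latency_h)
  list(
    n_nights = n,
    Av_tst = mean(tst_h),
    Av_time_bed = mean(tib_h),
    Deep_pct = mean(deep_pct),
    Light_pct = mean(light_pct),
    REM_pct = mean(rem_pct),
    NREM_pct = mean(deep_pct + light_pct),
    Awake_pct = mean(awake_pct),
    Av_onset = mean(onset_h),
    Av_offset = mean(offset_h),
    REM_L = if (any(rem_def)) mean(rem_latency_h[rem_def]) else NA_real_,
    Std_tst = if (n >= 2L) stats::sd(tst_h) else NA_real_,
    Std_onset = if (n >= 2L) stats::sd(onset_h) else NA_real_,
    Std_offset = if (n >= 2L) stats::sd(offset_h) else NA_real_,
    Efficiency = mean(100 - awake_pct),
    Awake_5 = mean(n_awakenings_gt5),
    WKD_diff = if (any(is_weekend) && any(!is_weekend))
      mean(tst_h[is_weekend]) - mean(tst_h[!is_weekend]) else NA_real_,
    M_insomnia = 100 * sum(is_insomnia) / n,
    Dur_10 = 100 * sum(is_hypersomnia) / n
  )
}

#' Extract the 18-feature vector from one window of nights
#'
#' Level features (mean TST, time in bed, the five stage percentages,
#' onset, offset, efficiency, awakenings per night) are means of the
#' per-night values; stage percentages are averaged as per-night
#' percentages (mean of ratios, one value per night), not pooled minutes.
#' Stability features are sample (n-1) standard deviations, missing with
#' fewer than 2 nights. REM latency is averaged over nights where it is
#' defined and missing when no night reached REM. Weekend catch-up sleep
#' (`WKD_diff`) is mean weekend-night TST minus mean weekday-night TST,
#' missing unless both groups are non-empty. `M_insomnia` and `Dur_10`
#' are the percentage of window nights flagged as potential middle
#' insomnia and as hypersomnia (TST > 10 h).
#'
#' @param window_nights Night records in the feature window (at least 1).
#' @param phq8_ts Completion time the window precedes (carried through).
#' @return One-row tibble: `participant_id`, `site_id`, `phq8_ts`,
#'   `n_nights` and the 18 features of [sleep_feature_names()].
#' @export
extract_features <- function(window_nights, phq8_ts) {
  if (!NROW(window_nights))
    stop("empty feature window: no nights to aggregate", call. = FALSE)
  w <- window_nights
  f <- extract_features_core(w$tst_h, w$tib_h, w$min_awake, w$min_light,
                             w$min_deep, w$min_rem, w$onset_h, w$offset_h,
                             w$rem_latency_h, w$n_awakenings_gt5,
                             w$is_insomnia_day, w$is_hypersomnia_day,
                             w$is_weekend_night)
  tibble::as_tibble(c(list(participant_id = w$participant_id[1L],
                           site_id = w$site_id[1L],
                           phq8_ts = phq8_ts), f))
}

#' Feature vectors for every PHQ-8 record
#'
#' Applies [collect_window()] + [extract_features()] to each PHQ-8
#' record of each participant. Records with an empty window are returned
#' with `n_nights = 0` and missing features, so the inclusion filter can
#' account for them.
#'
#' @param nights Night-record tibble.
#' @param phq8 PHQ-8 tibble (see [read_phq8()]).
#' @param window_days Feature window length in days (default 14).
#' @return Tibble with one row per PHQ-8 record.
#' @export
extract_all_features <- function(nights, phq8, window_days = 14L) {
  if (window_days <= 0) stop("window_days must be positive", call. = FALSE)
  by_pid <- split(seq_len(nrow(nights)), nights$participant_id)
  anchor <- nights$anchor_date
  qd_all <- as.Date(phq8$completion_ts, tz = "UTC")
  feat_mat <- matrix(NA_real_, nrow(phq8), 19L)
  colnames(feat_mat) <- c("n_nights", sleep_feature_names())
  site <- rep(NA_character_, nrow(phq8))
  for (i in seq_len(nrow(phq8))) {
    idx <- by_pid[[phq8$participant_id[i]]]
    if (is.null(idx)) next
    qd <- qd_all[i]
    idx <- idx[anchor[idx] >= qd - window_days & anchor[idx] < qd]
    if (!length(idx)) next
    w <- nights[idx, , drop = FALSE]
    f <- extract_features_core(w$tst_h, w$tib_h, w$min_awake, w$min_light,
                               w$min_deep, w$min_rem, w$onset_h,
                               w$offset_h, w$rem_latency_h,
                               w$n_awakenings_gt5, w$is_insomnia_day,
                               w$is_hypersomnia_day, w$is_weekend_night)
    feat_mat[i, ] <- unlist(f, use.names = FALSE)
    site[i] <- w$site_id[1L]
  }
  out <- tibble::tibble(participant_id = phq8$participant_id,
                        site_id = site,
                        phq8_ts = phq8$completion_ts)
  fm <- tibble::as_tibble(as.data.frame(feat_mat))
  fm$n_nights <- ifelse(is.na(fm$n_nights), 0L, as.integer(fm$n_nights))
  dplyr::bind_cols(out, fm)
}

#' Join features, PHQ-8 outcomes and demographics into analysis records
#'
#' Inner join of feature vectors and complete PHQ-8 records on
#' (`participant_id`, completion time), then of demographics on
#' `participant_id`. Incomplete PHQ-8 records are excluded here (their
#' total is undefined). Participants with features but no demographics
#' are dropped with a warning.
#'
#' @param features Output of [extract_all_features()].
#' @param phq8 PHQ-8 tibble.
#' @param demographics Demographics tibble (see [read_demographics()]).
#' @return Tibble of analysis records: features + `phq8_total`,
#'   `sleep_subscore`, `complete` + `age`, `gender`, `education`,
#'   `income` (site taken from demographics).
#' @export
join_records <- function(features, phq8, demographics) {
  ph <- phq8[, c("participant_id", "completion_ts", "complete", "total",
                 "sleep_subscore")]
  names(ph)[names(ph) == "completion_ts"] <- "phq8_ts"
  names(ph)[names(ph) == "total"] <- "phq8_total"
  out <- dplyr::inner_join(features, ph,
                           by = c("participant_id", "phq8_ts"))
  out <- out[out$complete, , drop = FALSE]
  no_demo <- setdiff(unique(out$participant_id),
                     demographics$participant_id)
  if (length(no_demo)) {
    warning(length(no_demo),
            " participant(s) dropped: no demographics record",
            call. = FALSE)
    out <- out[!out$participant_id %in% no_demo, , drop = FALSE]
  }
  out$site_id <- NULL  # authoritative site comes from demographics
  dplyr::inner_join(out, demographics, by = "participant_id")
}
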