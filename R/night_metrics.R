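# Per-night sleep metrics: anchor-date attribution, main-sleep selection,
# and the NightRecord quantities from which all windowed features derive.

#' Attribute a session start to a calendar night (noon rule)
#'
#' A night belongs to the evening on which it began: sessions starting at
#' or after 12:00 local time are anchored to their own calendar date,
#' sessions starting before noon (after-midnight sleep) to the preceding
#' date. This is the standard actigraphy convention for mapping sleep
#' episodes to days.
#'
#' @param start POSIXct vector of session start times.
#' @return Date vector of anchor dates.
#' @export
#' @examples
#' assign_anchor_date(as.POSIXct("2019-03-04 23:00:00", tz = "UTC"))
#' assign_anchor_date(as.POSIXct("2019-03-09 00:30:00", tz = "UTC"))
assign_anchor_date <- function(start) {
  lt <- as.POSIXlt(start, tz = "UTC")
  d <- as.Date(start, tz = "UTC")
  d - as.integer(lt$hour < 12)
}

#' Select the main sleep among sessions sharing an anchor date
#'
#' When several sessions (e.g. a nap and the night's sleep) map to the
#' same anchor date, the session with the largest total duration (time in
#' bed) is the night's main sleep; ties are broken by the earliest start.
#'
#' @param sessions A `sleep_sessions` segment tibble whose sessions all
#'   share one anchor date.
#' @return The segment rows of the selected session.
#' @export
select_main_sleep <- function(sessions) {
  if (!NROW(sessions)) stop("no sessions to select from", call. = FALSE)
  info <- dplyr::summarise(
    dplyr::group_by(sessions, .data$session_id),
    tib = sum(.data$duration_min), first = min(.data$start),
    .groups = "drop")
  info <- info[order(-info$tib, info$first), ]
  sessions[sessions$session_id == info$session_id[1L], , drop = FALSE]
}

# Core per-session metric computation on sorted segment vectors.
# Returns NULL for a session with no non-awake segment.
night_metrics_core <- function(stage, rel_start_h, duration_min) {
  nonawake <- stage != "awake"
  if (!any(nonawake)) return(NULL)
  end_h <- rel_start_h + duration_min / 60
  i_on <- which(nonawake)[1L]
  i_off <- max(which(nonawake))
  onset_h <- rel_start_h[i_on]
  offset_h <- end_h[i_off]

  min_awake <- sum(duration_min[stage == "awake"])
  min_light <- sum(duration_min[stage == "light"])
  min_deep <- sum(duration_min[stage == "deep"])
  min_rem <- sum(duration_min[stage == "rem"])
  tib_h <- sum(duration_min) / 60
  tst_h <- (min_light + min_deep + min_rem) / 60

  i_rem <- which(stage == "rem")[1L]
  rem_latency_h <- if (is.na(i_rem)) NA_real_ else
    rel_start_h[i_rem] - onset_h

  # awakenings: awake episodes strictly between onset and offset
  interior <- stage == "awake" & seq_along(stage) > i_on &
    seq_along(stage) < i_off
  list(
    tst_h = tst_h, tib_h = tib_h,
    min_awake = min_awake, min_light = min_light,
    min_deep = min_deep, min_rem = min_rem,
    onset_h = onset_h, offset_h = offset_h,
    rem_latency_h = rem_latency_h,
    n_awakenings_gt5 = sum(duration_min[interior] > 5),
    has_awakening_ge30 = any(duration_min[interior] >= 30),
    efficiency_pct = 100 * tst_h / tib_h
  )
}

#' Compute per-night metrics for validated sessions
#'
#' Runs the full session-to-night stage: anchor-date attribution (noon
#' rule), main-sleep selection per (participant, anchor date), and metric
#' computation per selected session. Per night: total sleep time (sum of
#' light + deep + REM), time in bed (all stages, awake included), stage
#' minutes, sleep onset (start of the first non-awake segment) and offset
#' (end of the last non-awake segment) on the anchor-date clock axis
#' (hours since 00:00 of the anchor date, so next-morning times exceed
#' 24), REM latency (onset to first REM segment, missing when the night
#' has no REM), awakening counts (awake episodes > 5 min strictly between
#' onset and offset; a prolonged awakening is >= 30 min), sleep
#' efficiency (100 * TST / TIB) and night flags: potential middle
#' insomnia (TST < 6 h AND a prolonged awakening) and hypersomnia
#' (TST > 10 h, strict).
#'
#' Sessions consisting entirely of awake time carry no sleep to score and
#' are rejected (logged in the `rejected` attribute).
#'
#' @param sessions A `sleep_sessions` segment tibble (see
#'   [read_sessions()]).
#' @return Tibble of night records, one row per (participant, anchor
#'   date), sorted by participant and date, with attribute `rejected`
#'   listing discarded sessions.
#' @export
compute_nights <- function(sessions) {
  rejected <- rejected_sessions(sessions) %||%
    tibble::tibble(session_id = character(), participant_id = character(),
                   reason = character())
  if (!NROW(sessions)) {
    return(structure(empty_nights(), rejected = rejected,
                     class = class(tibble::tibble())))
  }

  seg <- tibble::as_tibble(sessions)
  first_start <- stats::ave(as.numeric(seg$start), seg$session_id, FUN = min)
  seg$anchor_date <- assign_anchor_date(
    as.POSIXct(first_start, origin = "1970-01-01", tz = "UTC"))

  # main-sleep selection: largest TIB per (participant, anchor), tie ->
  # earliest start
  info <- dplyr::summarise(
    dplyr::group_by(seg, .data$participant_id, .data$anchor_date,
                    .data$session_id),
    tib = sum(.data$duration_min), first = min(.data$start),
    .groups = "drop")
  info <- info[order(info$participant_id, info$anchor_date, -info$tib,
                     info$first), ]
  chosen <- info[!duplicated(info[c("participant_id", "anchor_date")]), ]
  dropped <- setdiff(info$session_id, chosen$session_id)
  if (length(dropped))
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      session_id = dropped,
      participant_id = info$participant_id[match(dropped, info$session_id)],
      reason = "not main sleep for its night"))

  seg <- seg[seg$session_id %in% chosen$session_id, ]
  rows <- vector("list", nrow(chosen))
  for (i in seq_len(nrow(chosen))) {
    s <- seg[seg$session_id == chosen$session_id[i], , drop = FALSE]
    s <- s[order(s$start), ]
    anchor <- s$anchor_date[1L]
    m <- night_metrics_core(s$stage, hours_on_anchor_axis(s$start, anchor),
                            s$duration_min)
    if (is.null(m)) {
      rejected <- dplyr::bind_rows(rejected, tibble::tibble(
        session_id = s$session_id[1L], participant_id = s$participant_id[1L],
        reason = "entirely awake"))
      next
    }
    rows[[i]] <- tibble::tibble(
      participant_id = s$participant_id[1L], site_id = s$site_id[1L],
      anchor_date = anchor,
      tst_h = m$tst_h, tib_h = m$tib_h,
      min_awake = m$min_awake, min_light = m$min_light,
      min_deep = m$min_deep, min_rem = m$min_rem,
      onset_h = m$onset_h, offset_h = m$offset_h,
      rem_latency_h = m$rem_latency_h,
      n_awakenings_gt5 = m$n_awakenings_gt5,
      has_awakening_ge30 = m$has_awakening_ge30,
      efficiency_pct = m$efficiency_pct,
      is_weekend_night = is_weekend_anchor(anchor))
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- empty_nights()
  out <- classify_night_flags(out)
  out <- out[order(out$participant_id, out$anchor_date), ]
  n_prior <- NROW(rejected_sessions(sessions))
  if (nrow(rejected) > n_prior)
    message(nrow(rejected) - n_prior,
            " session(s) discarded during night scoring")
  structure(out, rejected = rejected, class = class(tibble::tibble()))
}

empty_nights <- function() {
  tibble::tibble(
    participant_id = character(), site_id = character(),
    anchor_date = as.Date(character()),
    tst_h = numeric(), tib_h = numeric(),
    min_awake = numeric(), min_light = numeric(), min_deep = numeric(),
    min_rem = numeric(), onset_h = numeric(), offset_h = numeric(),
    rem_latency_h = numeric(), n_awakenings_gt5 = integer(),
    has_awakening_ge30 = logical(), efficiency_pct = numeric(),
    is_weekend_night = logical())
}

#' Flag potential-insomnia and hypersomnia nights
#'
#' A night is a potential middle-insomnia day when total sleep time is
#' under 6 hours AND it contains at least one prolonged (>= 30 min)
#' awakening; a hypersomnia day when total sleep time strictly exceeds
#' 10 hours.
#'
#' @param nights Night-record tibble (see [compute_nights()]).
#' @return `nights` with logical columns `is_insomnia_day` and
#'   `is_hypersomnia_day` added (replaced if present).
#' @export
classify_night_flags <- function(nights) {
  nights$is_insomnia_day <- nights$tst_h < 6 & nights$has_awakening_ge30
  nights$is_hypersomnia_day <- nights$tst_h > 10
  nights
}
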