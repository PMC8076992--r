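# The four cohort inclusion criteria.

#' Inclusion criteria configuration
#'
#' The analysis dataset keeps a (participant, PHQ-8 record) row only when
#' (1) the PHQ-8 record is complete (all 8 items answered); (2) the
#' feature window holds at least `min_sleep_days` nights with sleep
#' records (default 12, about 85% of the 14-day window); (3) the
#' participant retains at least `min_phq8_per_participant` records
#' (default 3); and (4) the record was completed before `date_cutoff`
#' (default 2020-02-01, excluding pandemic-era sleep).
#'
#' @param min_sleep_days Minimum nights in the window (default 12).
#' @param min_phq8_per_participant Minimum surviving records per
#'   participant (default 3).
#' @param date_cutoff Records completed on or after this date are
#'   excluded (default `"2020-02-01"`).
#' @param require_complete_phq8 Drop incomplete questionnaires
#'   (default TRUE).
#' @param window_days Feature window the night count refers to
#'   (default 14); `min_sleep_days` may not exceed it.
#' @return A list of class `inclusion_config`.
#' @export
inclusion_config <- function(min_sleep_days = 12L,
                             min_phq8_per_participant = 3L,
                             date_cutoff = as.Date("2020-02-01"),
                             require_complete_phq8 = TRUE,
                             window_days = 14L) {
  date_cutoff <- as.Date(date_cutoff)
  if (min_sleep_days > window_days)
    stop("min_sleep_days (", min_sleep_days,
         ") exceeds window_days (", window_days, ")", call. = FALSE)
  if (min_phq8_per_participant < 1L)
    stop("min_phq8_per_participant must be >= 1", call. = FALSE)
  structure(list(min_sleep_days = as.integer(min_sleep_days),
                 min_phq8_per_participant =
                   as.integer(min_phq8_per_participant),
                 date_cutoff = date_cutoff,
                 require_complete_phq8 = isTRUE(require_complete_phq8),
                 window_days = as.integer(window_days)),
            class = "inclusion_config")
}

#' Apply the inclusion criteria to candidate analysis records
#'
#' Record-level rules run first, in fixed order - incomplete PHQ-8, too
#' few nights in the window, completion date on/after the cutoff - and a
#' record failing several rules is tallied under the first failing rule.
#' The participant-level rule (at least `min_phq8_per_participant`
#' otherwise-valid records) then runs on the survivors, so the record
#' count it tests refers to records that would otherwise be analysed.
#'
#' @param candidates Analysis-record tibble (see [join_records()]); must
#'   carry `n_nights`, `phq8_ts` and (if present) `complete`.
#' @param cfg An [inclusion_config()].
#' @return The surviving records, with attribute `exclusions`: a tibble
#'   of `rule` / `n_excluded` tallies (retrieve with
#'   [exclusion_report()]).
#' @export
filter_records <- function(candidates, cfg = inclusion_config()) {
  x <- candidates
  complete <- if ("complete" %in% names(x)) x$complete else
    !is.na(x$phq8_total)

  fail_incomplete <- cfg$require_complete_phq8 & !complete
  fail_nights <- x$n_nights < cfg$min_sleep_days
  fail_date <- as.Date(x$phq8_ts, tz = "UTC") >= cfg$date_cutoff

  first_fail <- rep(NA_character_, nrow(x))
  first_fail[fail_date] <- "completed_on_or_after_cutoff"
  first_fail[fail_nights] <- "fewer_than_min_sleep_days"
  first_fail[fail_incomplete] <- "incomplete_phq8"

  keep1 <- is.na(first_fail)
  survivors <- x[keep1, , drop = FALSE]

  counts <- table(survivors$participant_id)
  few <- names(counts)[counts < cfg$min_phq8_per_participant]
  fail_participant <- survivors$participant_id %in% few
  out <- survivors[!fail_participant, , drop = FALSE]

  tally <- tibble::tibble(
    rule = c("incomplete_phq8", "fewer_than_min_sleep_days",
             "completed_on_or_after_cutoff",
             "fewer_than_min_phq8_records", "retained"),
    n_excluded = c(sum(first_fail == "incomplete_phq8", na.rm = TRUE),
                   sum(first_fail == "fewer_than_min_sleep_days",
                       na.rm = TRUE),
                   sum(first_fail == "completed_on_or_after_cutoff",
                       na.rm = TRUE),
                   sum(fail_participant),
                   nrow(out)))
  structure(out, exclusions = tally)
}

#' Per-rule exclusion tally from a filtered record set
#'
#' @param filtered Output of [filter_records()].
#' @return Tibble with columns `rule` and `n_excluded` (the final row,
#'   `retained`, counts survivors).
#' @export
exclusion_report <- function(filtered) attr(filtered, "exclusions")
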