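# Ingest and validation of sleep sessions, PHQ-8 records and demographics,
# plus stable tabular output.

#' Read and validate sleep-stage sessions
#'
#' Reads hypnogram sessions in one of two dialects and validates each
#' session: known stage labels (`awake`, `light`, `deep`, `rem`), positive
#' segment durations, contiguous segments (each segment starts where the
#' previous one ends) and a total duration of at most 24 hours. Segments
#' are grouped by `session_id` and sorted by start time, so row order in
#' the input file does not matter.
#'
#' * `segments_csv`: one row per segment with columns `participant_id`,
#'   `site_id`, `session_id`, `stage`, `start` (ISO-8601), `duration_min`.
#' * `jsonl`: one JSON object per line with fields `participant_id`,
#'   `site_id`, `session_id`, `start` (ISO-8601 session start) and
#'   `segments`, an array of `{stage, duration_min}` objects laid end to
#'   end from `start`.
#'
#' An unknown stage label or a non-positive duration is a hard error
#' naming the offending row. A non-contiguous session is rejected (and
#' logged in the `rejected` attribute) when `on_noncontiguous = "reject"`,
#' or truncated to its longest contiguous prefix when `"repair"`.
#'
#' @param path Path to the input file.
#' @param dialect `"segments_csv"` (default) or `"jsonl"`.
#' @param on_noncontiguous `"reject"` (drop the session, log it) or
#'   `"repair"` (keep the longest contiguous prefix).
#' @return A tibble of segments (class `sleep_sessions`) with columns
#'   `participant_id`, `site_id`, `session_id`, `stage`, `start`
#'   (POSIXct, timezone-naive local clock stored as UTC), `duration_min`,
#'   sorted by participant and session start. Attribute `rejected` is a
#'   tibble logging each rejected session and the reason.
#' @export
read_sessions <- function(path,
                          dialect = c("segments_csv", "jsonl"),
                          on_noncontiguous = c("reject", "repair")) {
  dialect <- match.arg(dialect)
  on_noncontiguous <- match.arg(on_noncontiguous)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "segments_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("participant_id", "site_id", "session_id", "stage",
              "start", "duration_min")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop("segments_csv missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    seg <- tibble::tibble(
      participant_id = raw$participant_id,
      site_id = raw$site_id,
      session_id = raw$session_id,
      stage = raw$stage,
      start = parse_ts(raw$start, "segment start"),
      duration_min = as.numeric(raw$duration_min)
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    seg_list <- lapply(seq_along(lines), function(i) {
      obj <- jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE)
      segs <- obj$segments
      if (is.null(segs) || !NROW(segs))
        stop("jsonl line ", i, ": no segments array", call. = FALSE)
      start0 <- parse_ts(obj$start, "session start")
      dur <- as.numeric(segs$duration_min)
      starts <- start0 + c(0, cumsum(utils::head(dur, -1L))) * 60
      tibble::tibble(
        participant_id = as.character(obj$participant_id),
        site_id = as.character(obj$site_id),
        session_id = as.character(obj$session_id %||% paste0("jsonl_", i)),
        stage = as.character(segs$stage),
        start = starts,
        duration_min = dur
      )
    })
    seg <- dplyr::bind_rows(seg_list)
  }
  as_sleep_sessions(seg, on_noncontiguous = on_noncontiguous)
}

#' Construct a validated set of sleep sessions from a segment table
#'
#' Workhorse behind [read_sessions()]; also used by the synthetic cohort
#' generator. Validates stage labels and durations (hard errors naming the
#' row), sorts segments within session, checks contiguity and total
#' duration, and drops (or repairs) offending sessions.
#'
#' @param segments Data frame with columns `participant_id`, `site_id`,
#'   `session_id`, `stage`, `start` (POSIXct), `duration_min`.
#' @inheritParams read_sessions
#' @return A `sleep_sessions` tibble; see [read_sessions()].
#' @export
as_sleep_sessions <- function(segments,
                              on_noncontiguous = c("reject", "repair")) {
  on_noncontiguous <- match.arg(on_noncontiguous)
  seg <- tibble::as_tibble(segments)

  bad_stage <- which(!seg$stage %in% sleep_stages)
  if (length(bad_stage))
    stop("unknown stage label '", seg$stage[bad_stage[1L]],
         "' at row ", bad_stage[1L], call. = FALSE)
  bad_dur <- which(!is.finite(seg$duration_min) | seg$duration_min <= 0)
  if (length(bad_dur))
    stop("non-positive duration_min at row ", bad_dur[1L], call. = FALSE)

  seg <- dplyr::arrange(seg, .data$participant_id, .data$session_id,
                        .data$start)

  rejected <- list()
  keep <- vector("list", 0L)
  for (sid in unique(seg$session_id)) {
    s <- seg[seg$session_id == sid, , drop = FALSE]
    ends <- as.numeric(s$start) + s$duration_min * 60
    gaps <- abs(as.numeric(s$start[-1L]) - ends[-nrow(s)])
    first_break <- which(gaps > 1)[1L]  # tolerance: 1 second
    if (!is.na(first_break)) {
      if (on_noncontiguous == "reject") {
        rejected[[length(rejected) + 1L]] <- tibble::tibble(
          session_id = sid, participant_id = s$participant_id[1L],
          reason = "non-contiguous segments")
        next
      }
      s <- s[seq_len(first_break), , drop = FALSE]
    }
    if (sum(s$duration_min) > 24 * 60) {
      rejected[[length(rejected) + 1L]] <- tibble::tibble(
        session_id = sid, participant_id = s$participant_id[1L],
        reason = "total duration exceeds 24 h")
      next
    }
    keep[[length(keep) + 1L]] <- s
  }

  out <- if (length(keep)) dplyr::bind_rows(keep) else seg[0L, ]
  rej <- if (length(rejected)) dplyr::bind_rows(rejected) else
    tibble::tibble(session_id = character(), participant_id = character(),
                   reason = character())
  if (nrow(rej))
    message(nrow(rej), " session(s) rejected during validation")

  # order sessions by (participant, first segment start)
  if (nrow(out)) {
    first_start <- stats::ave(as.numeric(out$start), out$session_id,
                              FUN = min)
    out <- out[order(out$participant_id, first_start, out$start), ]
  }
  structure(tibble::as_tibble(out),
            rejected = rej,
            class = c("sleep_sessions", class(tibble::tibble())))
}

#' Sessions rejected during validation
#'
#' @param x A `sleep_sessions` object (or any object carrying a
#'   `rejected` attribute, e.g. night records from [compute_nights()]).
#' @return Tibble with columns `session_id`, `participant_id`, `reason`.
#' @export
rejected_sessions <- function(x) attr(x, "rejected")

#' Read PHQ-8 questionnaire records
#'
#' The PHQ-8 has 8 items scored 0-3; the total (0-24) measures depressive
#' symptom severity over the past two weeks, and item 3 ("trouble falling
#' or staying asleep, or sleeping too much") is the sleep subscore.
#' Expected columns: `participant_id`, `completion_ts` (ISO-8601),
#' `item1`..`item8` (blank = unanswered). `total` and `sleep_subscore`
#' are populated only for complete records; incomplete records are kept
#' but flagged (`complete = FALSE`). An item outside 0-3 is a hard error
#' naming the row.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `participant_id`, `completion_ts`, `item1`..`item8`,
#'   `complete`, `total`, `sleep_subscore`.
#' @export
read_phq8 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- paste0("item", 1:8)
  missing_cols <- setdiff(c("participant_id", "completion_ts", items),
                          names(raw))
  if (length(missing_cols))
    stop("phq8_csv missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  im <- as.matrix(raw[items])
  storage.mode(im) <- "numeric"
  bad <- which(!is.na(im) & (im < 0 | im > 3 | im != round(im)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("PHQ-8 item outside 0-3 at row ", bad[1L, 1L],
         " (", items[bad[1L, 2L]], ")", call. = FALSE)
  complete <- rowSums(is.na(im)) == 0L
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    completion_ts = parse_ts(raw$completion_ts, "completion_ts")
  )
  for (j in seq_along(items)) out[[items[j]]] <- as.integer(im[, j])
  out$complete <- complete
  out$total <- ifelse(complete, as.integer(rowSums(im)), NA_integer_)
  out$sleep_subscore <- as.integer(im[, 3L])  # item 3, 1-based numbering
  out
}

#' Read baseline demographics
#'
#' Expected columns: `participant_id`, `site_id`, `age` (> 0, years),
#' `gender` (`female`/`male`/`other`), `education` (`degree_or_above` /
#' `below_degree`), `income` (`lt15k`/`15k_40k`/`gt40k`/`not_mentioned`).
#' Categorical variables are returned as factors with reference levels
#' `female`, `below_degree` and `lt15k`, the coding used for confounder
#' adjustment in the association models.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per participant.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", "site_id", "age", "gender",
                            "education", "income"), names(raw))
  if (length(missing_cols))
    stop("demographics_csv missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as_demographics(raw)
}

#' @rdname read_demographics
#' @param df Data frame with the demographics columns (see above).
#' @export
as_demographics <- function(df) {
  check_enum <- function(x, levels, what) {
    bad <- which(!x %in% levels)
    if (length(bad))
      stop("invalid ", what, " '", x[bad[1L]], "' at row ", bad[1L],
           call. = FALSE)
    factor(x, levels = levels)
  }
  age <- as.numeric(df$age)
  if (any(!is.finite(age) | age <= 0))
    stop("age must be positive at row ",
         which(!is.finite(age) | age <= 0)[1L], call. = FALSE)
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    site_id = as.character(df$site_id),
    age = age,
    gender = check_enum(df$gender, c("female", "male", "other"), "gender"),
    education = check_enum(df$education,
                           c("below_degree", "degree_or_above"),
                           "education"),
    income = check_enum(df$income,
                        c("lt15k", "15k_40k", "gt40k", "not_mentioned"),
                        "income")
  )
}

#' Write a feature or model-result table as CSV
#'
#' Fixed column order (as supplied), floating-point values rounded to 9
#' significant digits, missing values as empty cells. The written file
#' round-trips through [read_table()] exactly for integers and within
#' relative 1e-6 for reals.
#'
#' @param records Data frame (feature vectors, night records, model
#'   results, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.double(x) && !inherits(x, c("POSIXct", "Date"))) {
      df[[j]] <- signif(x, 9)
    } else if (inherits(x, "POSIXct")) {
      df[[j]] <- format(x, "%Y-%m-%dT%H:%M:%S")
    } else if (inherits(x, "Date")) {
      df[[j]] <- format(x, "%Y-%m-%d")
    } else if (is.factor(x)) {
      df[[j]] <- as.character(x)
    }
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write table to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to the CSV file.
#' @return Tibble; numeric-looking columns are parsed as numeric,
#'   ISO-8601 timestamp columns as POSIXct, dates as Date.
#' @export
read_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  out <- lapply(raw, function(x) {
    x[x == ""] <- NA
    nz <- x[!is.na(x)]
    if (!length(nz)) return(as.numeric(x))
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", nz)))
      return(as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"))
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", nz)))
      return(as.Date(x))
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num[!is.na(x)])) return(num)
    if (all(nz %in% c("TRUE", "FALSE"))) return(as.logical(x))
    x
  })
  tibble::as_tibble(out)
}
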