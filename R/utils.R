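# Internal numeric helpers.

# Integer apportionment by the largest-remainder (Hamilton) method:
# allocate `total` integer units proportionally to `weights`, ties broken
# by earliest index so the allocation is deterministic.
largest_remainder <- function(total, weights) {
  stopifnot(length(weights) >= 1L, all(weights >= 0), total >= 0)
  total <- as.integer(round(total))
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    out[1L] <- total
    return(out)
  }
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  short <- total - sum(base)
  add <- integer(length(weights))
  if (short > 0L) {
    ord <- order(-(raw - base), seq_along(weights))
    add[ord[seq_len(short)]] <- 1L
  }
  as.integer(base + add)
}

# Moment-based skewness (g1); used as the numeric trigger for the Box-Cox
# fallback in place of a visual residual check.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Hours since 00:00 of `anchor` for POSIXct `ts` (may exceed 24 for
# next-morning times); keeps onset/offset on one linear clock axis.
hours_on_anchor_axis <- function(ts, anchor) {
  midnight <- as.POSIXct(paste(anchor, "00:00:00"), tz = "UTC")
  as.numeric(difftime(ts, midnight, units = "hours"))
}

parse_ts <- function(x, what = "timestamp") {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))[1L]
    stop("unparseable ", what, " at row ", bad, ": '", x[bad], "'",
         call. = FALSE)
  }
  out
}

is_weekend_anchor <- function(anchor_date) {
  # Friday/Saturday anchors: the sleep preceding a non-work day.
  format(anchor_date, "%u") %in% c("5", "6")
}
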