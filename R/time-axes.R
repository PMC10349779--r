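#' Clock-time helpers and circular time axes
#'
#' Chrononutrition variables live on a clock, and naive arithmetic on clock
#' times fails whenever an interval crosses midnight. Two linearized axes are
#' used throughout the package:
#'
#' * the *noon-anchored axis* for sleep: clock times in `[12, 36)` where
#'   01:13 becomes 25.217. Sleep onset, offset and midsleep points are
#'   averaged on this axis because they cluster around midnight.
#' * the *within-day axis* for eating events: times earlier than `day_start`
#'   (04:00 by default) are mapped to `hour + 24`, so a 00:30 snack belongs
#'   to the evening of the same recall day.
#'
#' `parse_clock_time()` accepts `"HH:MM"` / `"HH:MM:SS"` strings or numeric
#' decimal hours and returns decimal hours in `[0, 24)`.
#'
#' @param x Clock times: character `"HH:MM"` or numeric decimal hours.
#' @param hours Numeric decimal hours.
#' @param day_start Hour at which a calendar day is considered to begin for
#'   eating events (default 4, i.e. 04:00).
#' @return Numeric decimal hours (or `"HH:MM"` strings for
#'   [format_clock_time()]).
#' @examples
#' parse_clock_time("01:13")
#' to_noon_axis(1.217)
#' within_day_axis(c(21, 0.5))
#' @name time-axes
NULL

#' @rdname time-axes
#' @export
parse_clock_time <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 0 | x >= 24)
    if (any(bad)) {
      abort_rows("clock time out of [0, 24)", which(bad))
    }
    return(as.numeric(x))
  }
  x <- as.character(x)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))
  out <- vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(NA_real_)
    p <- m[[i]]
    if (length(p) == 0) return(NaN)
    h <- as.numeric(p[2])
    mi <- as.numeric(p[3])
    s <- if (is.na(p[4]) || p[4] == "") 0 else as.numeric(p[4])
    if (h >= 24 || mi >= 60 || s >= 60) return(NaN)
    h + mi / 60 + s / 3600
  }, numeric(1))
  bad <- is.nan(out)
  if (any(bad)) {
    abort_rows(
      sprintf("unparseable or out-of-range clock time (e.g. %s)",
              encodeString(x[which(bad)[1]], quote = '"')),
      which(bad)
    )
  }
  out
}

#' @rdname time-axes
#' @export
format_clock_time <- function(hours) {
  h <- ((hours %% 24) + 24) %% 24
  mins <- round(h * 60)
  mins <- mins %% (24 * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' @rdname time-axes
#' @export
to_noon_axis <- function(x) {
  x <- x %% 24
  ifelse(x < 12, x + 24, x)
}

#' @rdname time-axes
#' @export
from_noon_axis <- function(x) {
  x %% 24
}

#' @rdname time-axes
#' @export
within_day_axis <- function(x, day_start = 4) {
  x <- x %% 24
  ifelse(x < day_start, x + 24, x)
}

# Difference (b - a) mod 24, in (0, 24] mapped to [0, 24).
circ_diff <- function(a, b) {
  ((b - a) %% 24 + 24) %% 24
}

abort_rows <- function(msg, rows) {
  abort(sprintf("%s [row%s %s]", msg,
                if (length(rows) > 1) "s" else "",
                paste(head(rows, 5), collapse = ", ")),
        class = "chronomeal_row_error")
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg),
        class = "chronomeal_config_error")
}
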