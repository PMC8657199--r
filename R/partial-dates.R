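# Partial calendar dates.
#
# Spontaneous reports carry dates at whatever precision the reporter gave:
# a year ("2016"), a month ("2015-03") or a full day ("2015-03-25"). The
# package stores them as ISO-like character strings so that precision is
# never invented: day-level arithmetic (time to onset) is only performed on
# day-complete dates, while interval membership (analysis windows) coerces
# a partial date to the earliest calendar day consistent with it.

.pd_pattern <- "^[0-9]{4}(-(0[1-9]|1[0-2])(-([0-3][0-9]))?)?$"

#' Validate partial-date strings
#'
#' A valid partial date is `"YYYY"`, `"YYYY-MM"` or `"YYYY-MM-DD"` with a
#' real calendar month and day. `NA` is treated as valid (missing date).
#'
#' @param x character vector of candidate dates.
#' @return logical vector, `TRUE` where valid or missing.
#' @export
is_partial_date <- function(x) {
  ok <- is.na(x) | grepl(.pd_pattern, x)
  # day-level strings must name an existing calendar day
  day <- !is.na(x) & nchar(x) == 10L & ok
  if (any(day)) {
    ok[day] <- !is.na(as.Date(x[day], format = "%Y-%m-%d"))
  }
  ok
}

#' Precision of a partial date
#'
#' @param x character vector of partial dates.
#' @return character vector with values `"year"`, `"month"`, `"day"`, or
#'   `NA` for missing/invalid entries.
#' @export
date_precision <- function(x) {
  out <- rep(NA_character_, length(x))
  valid <- !is.na(x) & is_partial_date(x)
  n <- nchar(x[valid])
  out[valid] <- c("year", "month", "day")[match(n, c(4L, 7L, 10L))]
  out
}

#' Earliest complete date consistent with a partial date
#'
#' `"2016"` becomes 2016-01-01, `"2015-03"` becomes 2015-03-01 and a
#' day-complete string maps to itself. Used for analysis-window membership,
#' where the coercion rule is deliberately inclusive and deterministic.
#'
#' @param x character vector of partial dates.
#' @return [Date] vector (`NA` where input is missing or invalid).
#' @export
earliest_date <- function(x) {
  ux <- unique(x)
  valid <- !is.na(ux) & is_partial_date(ux)
  padded <- rep(NA_character_, length(ux))
  n <- nchar(ux[valid])
  padded[valid] <- paste0(ux[valid], c("-01-01", "-01", "")[match(n, c(4L, 7L, 10L))])
  res <- as.Date(padded, format = "%Y-%m-%d")
  res[match(x, ux)]
}

#' Is a partial date day-complete?
#'
#' @param x character vector of partial dates.
#' @return logical vector; `FALSE` for missing or partial entries.
#' @export
is_complete_date <- function(x) {
  !is.na(x) & nchar(x) == 10L & is_partial_date(x)
}

# year component as integer (NA-safe)
date_year <- function(x) {
  suppressWarnings(as.integer(substr(x, 1L, 4L)))
}
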