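## Month-precision calendar helpers.
##
## All dates handled by the package are truncated to the first of the month:
## the emulation computes age from month and year of birth and compares
## ascertainment dates at month precision, so finer resolution would only
## suggest accuracy the data model does not have.

#' Build a month-precision Date
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of months (1-12).
#' @return `Date` vector, day fixed to the 1st.
#' @keywords internal
ym <- function(year, month) {
  ## arithmetic days-from-civil (no string parsing; these run on long vectors)
  y <- as.integer(year); m <- as.integer(month); d <- 1L
  y <- y - (m <= 2L)
  era <- ifelse(y >= 0L, y, y - 399L) %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  as.Date(era * 146097L + doe - 719468L, origin = "1970-01-01")
}

#' Truncate a Date to month precision
#' @param x Date vector.
#' @keywords internal
floor_month <- function(x) {
  idx <- month_index(x)
  ym(idx %/% 12L + 1900L, idx %% 12L + 1L)
}

## month index since 1900-01 (integer); NA-safe
month_index <- function(x) {
  lt <- as.POSIXlt(x)
  lt$year * 12L + lt$mon
}

## calendar year of a Date vector, without string formatting
date_year <- function(x) as.POSIXlt(x)$year + 1900L

#' Shift a month-precision Date by whole months
#' @param x Date vector.
#' @param k integer vector of months to add (may be negative).
#' @keywords internal
add_months <- function(x, k) {
  idx <- month_index(x) + as.integer(round(k))
  ym(idx %/% 12L + 1900L, idx %% 12L + 1L)
}

#' Elapsed whole months between two month-precision Dates
#' @param from,to Date vectors.
#' @return integer vector, `to - from` in months.
#' @keywords internal
months_between <- function(from, to) {
  month_index(to) - month_index(from)
}

#' Elapsed time in years at month precision
#' @param from,to Date vectors.
#' @keywords internal
years_between <- function(from, to) {
  months_between(from, to) / 12
}

## convert a duration in years to whole months (round half up)
years_to_months <- function(y) {
  as.integer(floor(y * 12 + 0.5))
}

## draw n month-precision dates uniformly between two month-precision dates
runif_month <- function(n, from, to) {
  lo <- month_index(from)
  hi <- month_index(to)
  idx <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  ym(idx %/% 12L + 1900L, idx %% 12L + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## pmin/pmax over Dates that tolerate all-NA rows without warnings
pmin_date <- function(...) {
  args <- lapply(list(...), as.numeric)
  out <- args[[1]]
  for (x in args[-1]) {
    out <- ifelse(is.na(out), x, ifelse(is.na(x), out, pmin(out, x)))
  }
  as.Date(out, origin = "1970-01-01")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
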