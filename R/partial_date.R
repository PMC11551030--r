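#' Parse a FAERS partial date string
#'
#' FAERS date fields carry year ("YYYY"), year-month ("YYYYMM") or full
#' ("YYYYMMDD") precision. Anything else (empty, non-numeric, impossible
#' month/day) parses to `NA`.
#'
#' @param x character vector of raw date strings.
#' @return A data.table with integer columns `year`, `month`, `day`; a
#'   component is `NA` when absent or invalid. A fully invalid string yields
#'   an all-`NA` row.
#' @examples
#' parse_partial_date(c("20140301", "2014", "201413", "oops"))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  nc <- nchar(x)
  digits_only <- grepl("^[0-9]+$", x)
  year <- month <- day <- rep(NA_integer_, length(x))

  ok4 <- digits_only & nc == 4L
  ok6 <- digits_only & nc == 6L
  ok8 <- digits_only & nc == 8L

  year[ok4] <- as.integer(x[ok4])
  year[ok6] <- as.integer(substr(x[ok6], 1L, 4L))
  month[ok6] <- as.integer(substr(x[ok6], 5L, 6L))
  year[ok8] <- as.integer(substr(x[ok8], 1L, 4L))
  month[ok8] <- as.integer(substr(x[ok8], 5L, 6L))
  day[ok8] <- as.integer(substr(x[ok8], 7L, 8L))

  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  # day validity checked against the actual calendar month (leap years too)
  full <- !is.na(year) & !is.na(month) & !is.na(day) & !bad_month
  if (any(full)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", year[full], month[full], day[full]),
                 format = "%Y-%m-%d")
    bad_day <- is.na(d)
    idx <- which(full)[bad_day]
    year[idx] <- month[idx] <- day[idx] <- NA_integer_
  }
  idx <- which(bad_month)
  year[idx] <- month[idx] <- day[idx] <- NA_integer_
  # a stray day without month cannot occur by construction
  data.table::data.table(year = year, month = month, day = day)
}

#' Convert full partial dates to Date, NA otherwise
#'
#' @param x character vector of raw FAERS date strings.
#' @return `Date` vector; `NA` unless the string has full YYYYMMDD precision
#'   and is a valid calendar date.
#' @export
partial_date_as_date <- function(x) {
  pd <- parse_partial_date(x)
  out <- rep(as.Date(NA), nrow(pd))
  full <- stats::complete.cases(pd)
  if (any(full)) {
    out[full] <- as.Date(
      sprintf("%04d-%02d-%02d", pd$year[full], pd$month[full], pd$day[full]))
  }
  out
}

# numeric sort key for version selection: YYYYMMDD >> YYYYMM00 >> YYYY0000,
# NA -> -Inf so dated versions always win
date_sort_key <- function(x) {
  pd <- parse_partial_date(x)
  key <- pd$year * 10000 +
    data.table::fifelse(is.na(pd$month), 0L, pd$month) * 100 +
    data.table::fifelse(is.na(pd$day), 0L, pd$day)
  data.table::fifelse(is.na(key), -Inf, as.numeric(key))
}

format_yyyymmdd <- function(d) format(d, "%Y%m%d")
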