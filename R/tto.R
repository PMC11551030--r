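# Time-to-onset: days from first target-drug therapy start to the event.
#
# Only reports where both dates carry full day precision are evaluable;
# negative onsets (event before therapy) and implausibly long ones are
# excluded, mirroring the exclusion of unspecified or inaccurate timing
# information from spontaneous reports.

#' Compute per-report onset days for target-drug reports
#'
#' Onset is `event_dt` minus the earliest therapy start among the report's
#' target-drug rows, in whole days. `NA` when either date lacks full
#' year-month-day precision, when the onset is negative, or when it exceeds
#' `cap_days`.
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param target logical vector flagging target-drug reports (aligned with
#'   `cases$demo`).
#' @param names drug name patterns identifying target drug rows (the same
#'   list used for matching), so the therapy start comes from the target
#'   drug, not co-medication.
#' @param roles role codes whose drug rows may contribute a start date.
#' @param cap_days plausibility cap in days (default 3650).
#' @return numeric vector of onset days aligned with the target reports
#'   (`NA` where not evaluable), named by `primaryid`.
#' @export
compute_onsets <- function(cases, target, names = nab_paclitaxel_names(),
                           roles = "PS", cap_days = 3650) {
  stopifnot(length(target) == n_reports(cases))
  demo <- cases$demo[target]
  if (nrow(demo) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  norm <- function(x) gsub("[[:space:]]+", " ", trimws(tolower(x)))
  pat <- norm(names)
  drugs <- cases$drugs[primaryid %in% demo$primaryid &
                         role_cod %in% toupper(roles)]
  dn <- norm(drugs$drugname)
  ai <- norm(drugs$prod_ai)
  hit <- rep(FALSE, nrow(drugs))
  for (p in pat) {
    hit <- hit | grepl(p, dn, fixed = TRUE) |
      (!is.na(ai) & grepl(p, ai, fixed = TRUE))
  }
  drugs <- drugs[hit]
  drugs[, start_date := partial_date_as_date(start_dt)]
  starts <- drugs[!is.na(start_date),
                  .(start = min(start_date)), by = primaryid]
  ev <- data.table::data.table(primaryid = demo$primaryid,
                               event = partial_date_as_date(demo$event_dt))
  ev <- starts[ev, on = "primaryid"]
  days <- as.numeric(ev$event - ev$start)
  days[!is.na(days) & (days < 0 | days > cap_days)] <- NA_real_
  stats::setNames(days, ev$primaryid)
}

.onset_bins <- data.table::data.table(
  bin = c("0-30", "31-60", "61-90", "91-180", "181-360", ">360"),
  lo = c(0, 31, 61, 91, 181, 361),
  hi = c(30, 60, 90, 180, 360, Inf)
)

#' Summarize onset days
#'
#' Median and quartiles use the linear-interpolation convention
#' (`quantile` type 7, recorded in the output). Bins are whole-day
#' intervals closed on both ends: 0-30, 31-60, 61-90, 91-180, 181-360 and
#' >360 days; same-day onsets fall in the first bin.
#'
#' @param days numeric vector of onset days; `NA`s count as not evaluable.
#' @param n_total total number of target reports the onsets came from
#'   (default: `length(days)`), used for the evaluable percentage.
#' @return list of class `onset_summary`: `n_evaluable`, `n_total`,
#'   `pct_evaluable`, `median_days`, `q1_days`, `q3_days`, `bins` (a
#'   data.table with counts and percentages) and `quantile_type`.
#' @export
summarize_onsets <- function(days, n_total = length(days)) {
  ev <- days[!is.na(days)]
  if (length(ev) == 0L) stop("no evaluable onsets", call. = FALSE)
  stopifnot(n_total >= length(ev))
  qs <- stats::quantile(ev, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bins <- data.table::copy(.onset_bins)
  bins[, count := vapply(seq_len(.N),
                         function(i) sum(ev >= lo[i] & ev <= hi[i]),
                         numeric(1))]
  bins[, pct := 100 * count / length(ev)]
  out <- list(
    n_evaluable = length(ev),
    n_total = n_total,
    pct_evaluable = 100 * length(ev) / n_total,
    median_days = qs[2],
    q1_days = qs[1],
    q3_days = qs[3],
    bins = bins[, .(bin, lo, hi, count, pct)],
    quantile_type = 7L
  )
  class(out) <- "onset_summary"
  out
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("<onset_summary> %d/%d evaluable (%.2f%%)\n",
              x$n_evaluable, x$n_total, x$pct_evaluable))
  cat(sprintf("  median %.1f days (IQR %.1f-%.1f)\n",
              x$median_days, x$q1_days, x$q3_days))
  print(x$bins)
  invisible(x)
}
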