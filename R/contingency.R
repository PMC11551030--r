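# Case-level 2x2 contingency tables per event term.
#
# The counting unit is the deduplicated case: a case counts once for a term
# no matter how many of its reaction rows map there. The comparator is all
# other reports in the same database window (the spontaneous-reporting
# "background population").

#' Build per-term 2x2 disproportionality tables
#'
#' For every event term at the requested level (MedDRA PT, or SOC via a
#' PT-to-SOC vocabulary), counts `a` = target-drug cases reporting the
#' term, `b` = target-drug cases not reporting it, `c` = other cases
#' reporting it, `d` = other cases not reporting it; `n = a+b+c+d` is the
#' total number of cases. At SOC level a case with several PTs in the same
#' SOC counts once. PTs absent from the vocabulary are aggregated under
#' `"Unmapped"` with a logged count.
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param target logical vector flagging target-drug reports, aligned with
#'   `cases$demo` rows (as returned by [match_target_drug()]).
#' @param level `"pt"` or `"soc"`.
#' @param vocab data.frame with columns `pt`, `soc`; required for
#'   `level = "soc"`, optional otherwise.
#' @return data.table with columns `level`, `term`, `a`, `b`, `c`, `d`,
#'   `n`, one row per term, ordered by term.
#' @export
build_contingency <- function(cases, target, level = c("pt", "soc"),
                              vocab = NULL) {
  level <- match.arg(level)
  if (n_reports(cases) == 0L) {
    stop("cannot build contingency tables from an empty case collection",
         call. = FALSE)
  }
  stopifnot(length(target) == n_reports(cases))
  n <- n_reports(cases)
  n_target <- sum(target)
  target_ids <- cases$demo$primaryid[target]

  events <- data.table::copy(cases$reactions)
  if (level == "soc") {
    if (is.null(vocab)) stop("SOC-level tables need a pt->soc vocab",
                             call. = FALSE)
    v <- data.table::as.data.table(vocab)[, .(pt, soc)]
    events <- v[events, on = "pt"]
    n_unmapped <- sum(is.na(events$soc))
    if (n_unmapped > 0) {
      message(sprintf("build_contingency: %d reaction row(s) with PT not in vocab -> 'Unmapped'",
                      n_unmapped))
      events[is.na(soc), soc := "Unmapped"]
    }
    events <- unique(events[, .(primaryid, term = soc)])
  } else {
    events <- unique(events[, .(primaryid, term = pt)])
  }

  counts <- events[, .(
    a = sum(primaryid %in% target_ids),
    reported = .N
  ), by = term]
  counts[, `:=`(
    b = n_target - a,
    c = reported - a
  )]
  counts[, d := n - n_target - c]
  out <- counts[, .(level = level, term, a, b, c, d, n = n)]
  data.table::setorder(out, term)
  out[]
}

#' Read a PT-to-SOC vocabulary file
#'
#' Two-column CSV (`pt`, `soc`) standing in for a licensed MedDRA
#' dictionary export; the package never ships MedDRA itself.
#'
#' @param path CSV path.
#' @return data.table with columns `pt`, `soc`.
#' @export
read_pt_vocab <- function(path) {
  v <- data.table::fread(path, colClasses = "character")
  data.table::setnames(v, tolower(names(v)))
  if (!all(c("pt", "soc") %in% names(v))) {
    stop("vocab file must have columns pt, soc", call. = FALSE)
  }
  unique(v[, .(pt, soc)])
}
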