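# Gender-stratified disproportionality within target-drug reports: the
# reporting odds of each term in females relative to males, volcano-plot
# data, and a separate Bonferroni family for the subgroup term list.

#' Female-vs-male 2x2 tables within target-drug reports
#'
#' Restricted to deduplicated target-drug reports with known sex (unknown
#' sex is excluded with a logged count). For each PT: `a_f`/`b_f` female
#' cases with/without the term, `a_m`/`b_m` male cases with/without it.
#' In the fourfold layout a = a_f, b = b_f, c = a_m, d = b_m, so the odds
#' ratio reads "reporting odds of the term in females relative to males".
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param target logical vector flagging target-drug reports.
#' @param min_total drop terms with fewer than this many reports across
#'   both sexes (default 1, i.e. keep all).
#' @return data.table: `term`, `a_f`, `b_f`, `a_m`, `b_m`.
#' @export
gender_tables <- function(cases, target, min_total = 1L) {
  stopifnot(length(target) == n_reports(cases))
  demo <- cases$demo[target]
  excl <- sum(demo$sex == "unknown")
  if (excl > 0) {
    message(sprintf("gender_tables: excluded %d report(s) with unknown sex",
                    excl))
  }
  demo <- demo[sex %in% c("F", "M")]
  n_f <- sum(demo$sex == "F")
  n_m <- sum(demo$sex == "M")
  reac <- cases$reactions[primaryid %in% demo$primaryid]
  reac <- merge(reac, demo[, .(primaryid, sex)], by = "primaryid",
                sort = FALSE)
  tab <- reac[, .(a_f = sum(sex == "F"), a_m = sum(sex == "M")), by = .(term = pt)]
  tab[, `:=`(b_f = n_f - a_f, b_m = n_m - a_m)]
  tab <- tab[a_f + a_m >= min_total]
  data.table::setorder(tab, term)
  tab[, .(term, a_f, b_f, a_m, b_m)]
}

#' Gender-stratified reporting odds ratios with Bonferroni adjustment
#'
#' For each term, the female-vs-male ROR with 95% CI (Haldane–Anscombe
#' +0.5 when a cell is zero), a two-sided p-value ([fourfold_p_value()]:
#' Pearson or Fisher by expected counts), Bonferroni adjustment across the
#' subgroup's own term family, and the dominant direction.
#'
#' @param gtab output of [gender_tables()].
#' @param alpha family-wise significance level.
#' @return data.table (class `gender_signal`): term, counts, `ror_fm`,
#'   `lo`, `hi`, `p_raw`, `p_method`, `p_adj`, `direction`.
#' @export
gender_signals <- function(gtab, alpha = 0.05) {
  stopifnot(nrow(gtab) >= 1)
  rr <- ror_stat(gtab$a_f, gtab$b_f, gtab$a_m, gtab$b_m)
  pv <- fourfold_p_value(gtab$a_f, gtab$b_f, gtab$a_m, gtab$b_m)
  adj <- bonferroni_adjust(pv$p, alpha = alpha)
  out <- data.table::data.table(
    term = gtab$term,
    a_f = gtab$a_f, b_f = gtab$b_f, a_m = gtab$a_m, b_m = gtab$b_m,
    ror_fm = rr$ror, lo = rr$ror_lo, hi = rr$ror_hi,
    corrected = rr$corrected,
    p_raw = pv$p, p_method = pv$p_method, p_adj = adj$p_adj
  )
  sig <- out$p_adj < alpha
  out[, direction := data.table::fcase(
    sig & ror_fm > 1, "female-dominant",
    sig & ror_fm < 1, "male-dominant",
    default = "none"
  )]
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "bonferroni_threshold", adj$threshold)
  data.table::setattr(out, "class", c("gender_signal", class(out)))
  out[]
}

#' Volcano-plot data for gender signals
#'
#' x is the natural-log female-vs-male ROR, y the negative log10 of the
#' raw p-value (the Bonferroni-adjusted p drives the significance flag).
#' A term is significant when `p_adj < alpha` and the count on its
#' dominant side (female cases `a_f` when log ROR > 0, male cases `a_m`
#' when < 0) is at least 3.
#'
#' @param gsig output of [gender_signals()].
#' @param alpha significance level (default: the one recorded on `gsig`).
#' @return data.table: `term`, `log_ror`, `neg_log10_p`, `significant`,
#'   `side` (`"female"`, `"male"` or `"none"`).
#' @export
volcano_data <- function(gsig, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(gsig, "alpha") %||% 0.05
  log_ror <- log(gsig$ror_fm)
  side <- data.table::fcase(log_ror > 0, "female",
                            log_ror < 0, "male",
                            default = "none")
  dominant_a <- data.table::fifelse(log_ror >= 0, gsig$a_f, gsig$a_m)
  significant <- gsig$p_adj < alpha & dominant_a >= 3 & side != "none"
  data.table::data.table(
    term = gsig$term,
    log_ror = log_ror,
    neg_log10_p = -log10(pmax(gsig$p_raw, .Machine$double.xmin)),
    significant = significant,
    side = data.table::fifelse(significant, side, side)
  )
}
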