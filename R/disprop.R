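# Frequentist disproportionality statistics on the drug-event 2x2 table
#
#                event   no event
#   target drug    a        b
#   all others     c        d        n = a+b+c+d
#
# Signal criteria follow the community-standard four-algorithm rule set for
# spontaneous-report mining: ROR (a>=3 and lower CI>1), PRR (a>=3, PRR>=2,
# chi2>=4), BCPNN (IC025>0), MGPS (EB05>2 and a>=3).

.check_cells <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("contingency cells must be non-negative", call. = FALSE)
  }
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a*d)/(b*c); the CI is exp(log ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d)).
#' Tables containing a zero cell receive the Haldane–Anscombe +0.5
#' continuity correction on all four cells, recorded in `corrected`. The
#' signal flag requires `a >= 3` (on the uncorrected count) and a lower
#' confidence bound above 1.
#'
#' @param a,b,c,d vectors of cell counts (recycled to common length is NOT
#'   supported; supply equal lengths).
#' @return data.table with `ror`, `ror_lo`, `ror_hi`, `corrected`,
#'   `ror_sig`.
#' @examples
#' ror_stat(10, 90, 100, 9900)
#' @export
ror_stat <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a0 <- a; b0 <- b; c0 <- c; d0 <- d
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  data.table::data.table(
    ror = ror, ror_lo = lo, ror_hi = hi, corrected = corrected,
    ror_sig = a0 >= 3 & lo > 1
  )
}

#' Pearson chi-square statistic of a 2x2 table (no Yates correction)
#'
#' @param a,b,c,d cell count vectors.
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return numeric vector of chi-square statistics; 0 when a margin is
#'   empty (the statistic is undefined there and carries no evidence).
#' @export
chi2_stat <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  chi2 <- n * num^2 / (r1 * r2 * c1 * c2)
  chi2[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- 0
  chi2
}

#' Proportional reporting ratio with chi-square criterion
#'
#' PRR = (a/(a+b)) / (c/(c+d)); chi-square is the Pearson statistic of the
#' 2x2 (no Yates correction by default). Zero cells receive the same +0.5
#' correction as [ror_stat()] for the ratio; chi-square is computed on the
#' raw table. Flag: `a >= 3` and `PRR >= 2` and `chi2 >= 4`.
#'
#' @inheritParams ror_stat
#' @param yates use the Yates-corrected chi-square (default `FALSE`).
#' @return data.table with `prr`, `chi2`, `corrected`, `prr_sig`.
#' @examples
#' prr_stat(10, 90, 100, 9900)
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE) {
  .check_cells(a, b, c, d)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a1 <- a + 0.5 * corrected; b1 <- b + 0.5 * corrected
  c1 <- c + 0.5 * corrected; d1 <- d + 0.5 * corrected
  prr <- (a1 / (a1 + b1)) / (c1 / (c1 + d1))
  chi2 <- chi2_stat(a, b, c, d, yates = yates)
  data.table::data.table(
    prr = prr, chi2 = chi2, corrected = corrected,
    prr_sig = a >= 3 & prr >= 2 & chi2 >= 4
  )
}

#' Two-sided p-value for a 2x2 table
#'
#' Pearson chi-square (no continuity correction) when every expected cell
#' count is at least 5, otherwise the two-sided Fisher exact test; the
#' method used is recorded per table.
#'
#' @inheritParams ror_stat
#' @return data.table with `p` and `p_method` (`"chisq"` or `"fisher"`).
#' @export
fourfold_p_value <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  m <- length(a)
  p <- numeric(m)
  method <- character(m)
  for (i in seq_len(m)) {
    tab <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE)
    n <- sum(tab)
    if (n == 0) { p[i] <- 1; method[i] <- "fisher"; next }
    expected <- outer(rowSums(tab), colSums(tab)) / n
    if (all(expected >= 5)) {
      p[i] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
      method[i] <- "chisq"
    } else {
      p[i] <- stats::fisher.test(tab)$p.value
      method[i] <- "fisher"
    }
  }
  data.table::data.table(p = p, p_method = method)
}

#' Bonferroni adjustment
#'
#' Divides the significance level by the number of comparisons: the
#' per-test threshold is `alpha/m` and each adjusted p-value is
#' `min(1, m * p)`.
#'
#' @param p vector of raw p-values.
#' @param alpha family-wise significance level in (0, 1).
#' @return list with `p_adj` (vector) and `threshold` (`alpha/length(p)`).
#' @examples
#' bonferroni_adjust(rep(0.004, 10), alpha = 0.05)$threshold # 0.005
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, length(p) >= 1)
  m <- length(p)
  list(p_adj = pmin(1, m * p), threshold = alpha / m)
}

#' Run all four disproportionality algorithms over a set of tables
#'
#' Computes ROR, PRR (with chi-square), BCPNN IC and MGPS EBGM for every
#' term, a raw two-sided p-value (Pearson or Fisher), the Bonferroni
#' adjustment across the supplied family, and the per-algorithm and
#' consensus signal flags. The MGPS prior is fitted across all supplied
#' tables unless one is passed in.
#'
#' @param tables data.table as returned by [build_contingency()]: columns
#'   `term`, `a`, `b`, `c`, `d`, `n` (and optionally `level`).
#' @param alpha family-wise significance level (default 0.05).
#' @param prior optional pre-fitted [fit_gps_prior()] object; fitted from
#'   `tables` when `NULL` and there are at least 20 terms. With fewer terms
#'   and no prior the MGPS columns are `NA` and `mgps_sig` is `FALSE`.
#' @param yates use Yates-corrected chi-square in the PRR criterion.
#' @return data.table (class `signal_result`), one row per term with all
#'   statistics, p-values, flags and `consensus` (AND of the four flags).
#' @export
signal_scan <- function(tables, alpha = 0.05, prior = NULL, yates = FALSE) {
  tab <- data.table::as.data.table(tables)
  stopifnot(all(c("term", "a", "b", "c", "d", "n") %in% names(tab)))
  if (nrow(tab) == 0L) stop("no contingency tables supplied", call. = FALSE)
  res <- tab[, .(term, level = if ("level" %in% names(tab)) level else NA_character_,
                 a, b, c, d, n)]
  res <- cbind(res, ror_stat(tab$a, tab$b, tab$c, tab$d))
  prr <- prr_stat(tab$a, tab$b, tab$c, tab$d, yates = yates)
  res[, `:=`(prr = prr$prr, chi2 = prr$chi2, prr_sig = prr$prr_sig)]
  bc <- bcpnn_ic(tab$a, tab$b, tab$c, tab$d)
  res[, `:=`(ic = bc$ic, ic025 = bc$ic025, bcpnn_sig = bc$bcpnn_sig)]
  e_count <- (tab$a + tab$b) * (tab$a + tab$c) / tab$n
  if (is.null(prior) && nrow(tab) >= 20L) {
    prior <- fit_gps_prior(tab$a, e_count)
  }
  if (!is.null(prior)) {
    eb <- ebgm_stat(tab$a, e_count, prior)
    res[, `:=`(ebgm = eb$ebgm, eb05 = eb$eb05, mgps_sig = eb$mgps_sig)]
  } else {
    res[, `:=`(ebgm = NA_real_, eb05 = NA_real_, mgps_sig = FALSE)]
  }
  pv <- fourfold_p_value(tab$a, tab$b, tab$c, tab$d)
  adj <- bonferroni_adjust(pv$p, alpha = alpha)
  res[, `:=`(p_raw = pv$p, p_method = pv$p_method, p_adj = adj$p_adj)]
  res[, consensus := ror_sig & prr_sig & bcpnn_sig & mgps_sig]
  data.table::setattr(res, "alpha", alpha)
  data.table::setattr(res, "bonferroni_threshold", adj$threshold)
  data.table::setattr(res, "gps_prior", prior)
  data.table::setattr(res, "class", c("signal_result", class(res)))
  res[]
}

#' Consensus filtering and ROR ranking
#'
#' Keeps terms flagged by all four algorithms (and, by default, with a
#' Bonferroni-adjusted p-value below `alpha`), ranks them by descending
#' ROR, and returns the top fraction. Ties are broken lexicographically by
#' term so the selection is deterministic.
#'
#' @param results a [signal_scan()] result.
#' @param top_fraction fraction of the consensus set to keep (default 0.2,
#'   the "top 20% of RORs" view); 1 returns every consensus term.
#' @param alpha significance level applied to `p_adj` (default the scan's).
#' @param require_adjusted_p also require `p_adj < alpha` (default `TRUE`).
#' @return data.table of the selected rows, ranked.
#' @export
consensus_and_rank <- function(results, top_fraction = 0.2, alpha = NULL,
                               require_adjusted_p = TRUE) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (is.null(alpha)) alpha <- attr(results, "alpha") %||% 0.05
  res <- data.table::as.data.table(results)
  keep <- res$consensus
  if (require_adjusted_p) keep <- keep & res$p_adj < alpha
  sel <- res[which(keep)]
  if (nrow(sel) == 0L) return(sel)
  data.table::setorderv(sel, c("ror", "term"), order = c(-1L, 1L))
  sel[seq_len(ceiling(top_fraction * nrow(sel)))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
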