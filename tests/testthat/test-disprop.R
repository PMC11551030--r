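test_that("ROR point estimate, CI and flag behave as specified", {
  # symmetric table: ROR = 1, CI straddles 1, no signal
  r <- ror_stat(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_lt(r$ror_lo, 1)
  expect_gt(r$ror_hi, 1)
  expect_false(r$ror_sig)
  # worked table against the scripted oracle
  r <- ror_stat(10, 90, 100, 9900)
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(r$ror, unname(o["est"]), tolerance = 1e-12)
  expect_equal(r$ror_lo, unname(o["lo"]), tolerance = 1e-12)
  expect_equal(r$ror_hi, unname(o["hi"]), tolerance = 1e-12)
  expect_true(r$ror_sig)
  # minimum-count rule: a = 2 never flags, however strong the lower bound
  r2 <- ror_stat(2, 8, 10, 9980)
  expect_gt(r2$ror_lo, 1)
  expect_false(r2$ror_sig)
  # zero cell: Haldane-Anscombe correction applied and recorded
  rz <- ror_stat(3, 7, 0, 90)
  expect_true(rz$corrected)
  expect_true(is.finite(rz$ror) && is.finite(rz$ror_hi))
  expect_equal(rz$ror, (3.5 * 90.5) / (7.5 * 0.5))
})

test_that("PRR and its chi-square criterion behave as specified", {
  # proportional table: PRR = 1, chi2 = 0
  p <- prr_stat(1, 9, 10, 90)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_false(p$prr_sig)
  # worked table against oracles
  p <- prr_stat(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, oracle_chi2(10, 90, 100, 9900), tolerance = 1e-12)
  expect_equal(p$chi2,
               unname(suppressWarnings(
                 chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                            correct = FALSE)$statistic)),
               tolerance = 1e-10)
  expect_true(p$prr_sig)
  # threshold conjunction: PRR below 2 never flags, whatever the chi2
  big <- prr_stat(1990, 8010, 1000, 9000)
  expect_lt(big$prr, 2)
  expect_gt(big$chi2, 100)
  expect_false(big$prr_sig)
})

test_that("the scan statistics are scale-invariant where they should be", {
  base <- c(a = 12, b = 488, c = 40, d = 4460)
  for (k in c(2L, 5L)) {
    r1 <- ror_stat(base["a"], base["b"], base["c"], base["d"])
    r2 <- ror_stat(k * base["a"], k * base["b"], k * base["c"], k * base["d"])
    expect_equal(r1$ror, r2$ror, tolerance = 1e-12)
    p1 <- prr_stat(base["a"], base["b"], base["c"], base["d"])
    p2 <- prr_stat(k * base["a"], k * base["b"], k * base["c"], k * base["d"])
    expect_equal(p1$prr, p2$prr, tolerance = 1e-12)
  }
})

test_that("p-values switch correctly between Pearson and Fisher", {
  # all expected counts >= 5: Pearson, matching stats::chisq.test
  pv <- fourfold_p_value(50, 950, 500, 8500)
  expect_equal(pv$p_method, "chisq")
  expect_equal(pv$p,
               suppressWarnings(
                 chisq.test(matrix(c(50, 950, 500, 8500), 2, byrow = TRUE),
                            correct = FALSE)$p.value),
               tolerance = 1e-12)
  # the worked sparse table (expected a-cell ~1.1): exact test, matching
  # the hypergeometric enumeration oracle
  pv1 <- fourfold_p_value(10, 90, 100, 9900)
  expect_equal(pv1$p_method, "fisher")
  expect_equal(pv1$p, oracle_fisher(10, 90, 100, 9900), tolerance = 1e-10)
  pv2 <- fourfold_p_value(3, 7, 2, 88)
  expect_equal(pv2$p_method, "fisher")
  expect_equal(pv2$p, oracle_fisher(3, 7, 2, 88), tolerance = 1e-10)
  # independence: p = 1 under Fisher
  pv3 <- fourfold_p_value(1, 9, 9, 81)
  expect_equal(pv3$p, 1, tolerance = 1e-12)
})

test_that("p-values decrease monotonically as a grows past independence", {
  # row margin fixed at 1000, background rate 2.9%: independence sits at
  # a = 29, so the scan runs strictly into the signal region
  ps <- vapply(30:60, function(a) {
    fourfold_p_value(a, 1000 - a, 290, 9710)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Bonferroni adjustment matches the worked definition", {
  adj <- bonferroni_adjust(rep(0.004, 10), alpha = 0.05)
  expect_identical(adj$threshold, 0.005)
  expect_equal(adj$p_adj, rep(0.04, 10))
  # m = 1: threshold = alpha, p unchanged
  one <- bonferroni_adjust(0.03, alpha = 0.05)
  expect_equal(one$threshold, 0.05)
  expect_equal(one$p_adj, 0.03)
  # cap at 1 and agreement with stats::p.adjust
  p <- c(0.2, 0.004, 0.03)
  expect_equal(bonferroni_adjust(p)$p_adj, p.adjust(p, "bonferroni"))
})

test_that("BCPNN IC shrinks to zero under independence and orders its interval", {
  b <- bcpnn_ic(1, 9, 9, 81)
  expect_lt(abs(b$ic), 0.15)
  expect_false(b$bcpnn_sig)
  g <- grid_tables()
  res <- bcpnn_ic(g$a, g$b, g$c, g$d)
  expect_true(all(res$ic025 < res$ic))
  # zero cells need no correction: everything stays finite
  z <- bcpnn_ic(0, 100, 50, 9850)
  expect_true(is.finite(z$ic) && is.finite(z$ic025))
  expect_lt(z$ic, 0)
})

test_that("the closed-form IC025 agrees with the Monte-Carlo posterior", {
  g <- grid_tables()[c(1, 4, 9, 12, 20), ] # spot-check; full grid in acceptance
  set.seed(401)
  for (i in seq_len(nrow(g))) {
    mc <- oracle_ic025_mc(g$a[i], g$b[i], g$c[i], g$d[i])
    cf <- bcpnn_ic(g$a[i], g$b[i], g$c[i], g$d[i])$ic025
    expect_lt(abs(cf - mc), 0.05)
  }
})

test_that("GPS prior fitting recovers a known prior and the null", {
  set.seed(77)
  true <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  n_terms <- 5000
  E <- rlnorm(n_terms, log(5), 1)
  comp <- runif(n_terms) < true$w
  lambda <- ifelse(comp, rgamma(n_terms, 0.2, 0.1), rgamma(n_terms, 2, 4))
  a <- rpois(n_terms, lambda * E)
  fit <- fit_gps_prior(a, E)
  # held-out grid: mean EBGM under fitted prior within 10% of truth's
  g <- grid_tables()
  Eg <- (g$a + g$b) * (g$a + g$c) / (g$a + g$b + g$c + g$d)
  eb_true <- ebgm_stat(g$a, Eg, true)$ebgm
  eb_fit <- ebgm_stat(g$a, Eg, fit)$ebgm
  expect_lt(abs(mean(eb_fit) - mean(eb_true)) / mean(eb_true), 0.10)
  # null data: posterior mass concentrates near lambda = 1
  set.seed(78)
  E0 <- rlnorm(2000, log(8), 0.8)
  a0 <- rpois(2000, E0)
  fit0 <- fit_gps_prior(a0, E0)
  eb0 <- ebgm_stat(a0, E0, fit0)$ebgm
  expect_gt(median(eb0), 0.8)
  expect_lt(median(eb0), 1.25)
})

test_that("GPS fitting is order-invariant and guards small families", {
  set.seed(79)
  E <- rlnorm(200, log(5), 1)
  a <- rpois(200, E)
  f1 <- fit_gps_prior(a, E)
  perm <- sample(200)
  f2 <- fit_gps_prior(a[perm], E[perm])
  expect_equal(f1[c("shape1", "rate1", "shape2", "rate2", "w")],
               f2[c("shape1", "rate1", "shape2", "rate2", "w")],
               tolerance = 1e-6)
  expect_error(fit_gps_prior(a[1:10], E[1:10]), "at least 20")
})

test_that("EBGM shrinks a zero count below 1 and EB05 stays below EBGM", {
  prior <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  z <- ebgm_stat(0, 5, prior)
  expect_lt(z$ebgm, 1)
  expect_false(z$mgps_sig)
  g <- grid_tables()
  Eg <- (g$a + g$b) * (g$a + g$c) / (g$a + g$b + g$c + g$d)
  eb <- ebgm_stat(g$a, Eg, prior)
  expect_true(all(eb$eb05 < eb$ebgm))
})

test_that("consensus selection ranks by ROR with deterministic ties", {
  tab <- data.table::data.table(
    term = c("B", "A", "C", "D"),
    a = c(30, 30, 40, 2), b = c(70, 70, 60, 98),
    c = c(50, 50, 50, 50), d = c(9850, 9850, 9850, 9850),
    n = 10000)
  prior <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  sc <- signal_scan(tab, prior = prior)
  sel <- consensus_and_rank(sc, top_fraction = 1)
  # identical tables A and B tie on ROR; lexicographic order breaks the tie
  ab <- sel$term[sel$term %in% c("A", "B")]
  expect_equal(ab, c("A", "B"))
  expect_false("D" %in% sel$term) # a = 2 can never reach consensus
  # top_fraction = 1 returns the whole consensus set; 0.5 its ceiling-half
  half <- consensus_and_rank(sc, top_fraction = 0.5)
  expect_equal(nrow(half), ceiling(nrow(sel) / 2))
  # no consensus terms -> empty result
  null_tab <- data.table::data.table(term = "X", a = 5, b = 995, c = 50,
                                     d = 8950, n = 10000)
  sc0 <- signal_scan(null_tab, prior = prior)
  expect_equal(nrow(consensus_and_rank(sc0, top_fraction = 1)), 0L)
})

test_that("signal_scan output satisfies its structural invariants", {
  gen <- suppressMessages(generate_cases(synth_config(n_cases = 8000, seed = 31)))
  tgt <- match_target_drug(gen$cases, nab_paclitaxel_names())
  tab <- build_contingency(gen$cases, tgt, "pt")
  sc <- signal_scan(tab)
  expect_true(all(sc$ror_lo <= sc$ror & sc$ror <= sc$ror_hi))
  expect_true(all(sc$ic025 <= sc$ic))
  # percentile-vs-geometric-mean ordering holds whenever one posterior
  # component dominates (all elevated terms); a fitted prior with a
  # near-point-mass null component can flip it by a hair for null terms
  elevated <- sc$ebgm > 1.2
  expect_true(all(sc$eb05[elevated] <= sc$ebgm[elevated]))
  expect_true(all(sc$eb05 <= sc$ebgm * 1.02))
  expect_true(all(sc$p_adj >= sc$p_raw))
  expect_equal(sc$consensus,
               sc$ror_sig & sc$prr_sig & sc$bcpnn_sig & sc$mgps_sig)
})
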