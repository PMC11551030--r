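# Independent brute-force oracles for the disproportionality statistics.
# These deliberately avoid the package's code paths: plain arithmetic,
# hypergeometric enumeration for the exact test, Monte-Carlo posterior
# draws for the BCPNN interval, and numerical quadrature of the
# unnormalized posterior for the MGPS quantities.

# fixed grid of 20 realistic drug-event tables (a, b, c, d)
grid_tables <- function() {
  data.frame(
    a = c(3, 5, 8, 10, 12, 20, 25, 40, 50, 75,
          100, 115, 128, 150, 200, 213, 300, 412, 500, 60),
    b = c(997, 1995, 2992, 990, 4988, 4980, 9975, 9960, 4950, 9925,
          19900, 9885, 14872, 9850, 19800, 9787, 29700, 19588, 49500, 9940),
    c = c(30, 60, 40, 100, 120, 100, 300, 200, 150, 300,
          500, 400, 300, 450, 800, 700, 1200, 1500, 2500, 900),
    d = c(8970, 17940, 26960, 9900, 44880, 44920, 89700, 89800, 44850, 89700,
          179500, 89600, 134700, 89550, 179200, 88300, 268500, 178500,
          447500, 89100)
  )
}

oracle_ror <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = est, lo = exp(log(est) - 1.96 * se), hi = exp(log(est) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a / (a + b)) / (c / (c + d))
}

# Pearson chi-square from explicitly enumerated expected counts
oracle_chi2 <- function(a, b, c, d) {
  obs <- c(a, b, c, d)
  n <- sum(obs)
  expd <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / n
  sum((obs - expd)^2 / expd)
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of all table
# probabilities not exceeding the observed one (standard two-sided rule)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # target-drug row total
  k <- a + c          # event column total
  n_other <- c + d
  support <- max(0, k - n_other):min(m, k)
  probs <- dhyper(support, m, n_other, k)
  p_obs <- dhyper(a, m, n_other, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# MC posterior of the BCPNN IC under the same Bate-style priors:
# independent Beta draws for the cell and the two margins
oracle_ic025_mc <- function(a, b, c, d, n_draws = 1e5) {
  n <- a + b + c + d
  n1 <- a + b; n2 <- a + c
  g <- (n + 2) * (n + 2) / ((n1 + 1) * (n2 + 1))
  p11 <- rbeta(n_draws, 1 + a, g - 1 + n - a)
  p1 <- rbeta(n_draws, 1 + n1, 1 + n - n1)
  p2 <- rbeta(n_draws, 1 + n2, 1 + n - n2)
  unname(quantile(log2(p11) - log2(p1) - log2(p2), 0.025))
}

# quadrature oracle for the MGPS posterior: integrate the unnormalized
# posterior prior(lambda) * Poisson(a | lambda * E) directly
oracle_gps <- function(a, E, prior) {
  dens <- function(l) {
    (prior$w * dgamma(l, prior$shape1, rate = prior$rate1) +
       (1 - prior$w) * dgamma(l, prior$shape2, rate = prior$rate2)) *
      dpois(a, l * E)
  }
  z <- integrate(dens, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  elog <- integrate(function(l) log(l) * dens(l) / z, 0, Inf,
                    rel.tol = 1e-12, abs.tol = 0)$value
  cdf <- function(x) integrate(dens, 0, x, rel.tol = 1e-12, abs.tol = 0)$value / z
  # bracket the 5th percentile then root-find
  lo <- 1e-8; hi <- (a + 10) / E + 10
  eb05 <- uniroot(function(x) cdf(x) - 0.05, lower = lo, upper = hi,
                  tol = 1e-12)$root
  c(ebgm = exp(elog), eb05 = eb05)
}

# brute-force contingency counting over a flat (caseid, exposed, pt) frame
oracle_counts <- function(case_pt, term) {
  per_case <- unique(case_pt[, c("caseid", "exposed")])
  has <- unique(case_pt$caseid[case_pt$pt == term])
  a <- sum(per_case$exposed & per_case$caseid %in% has)
  b <- sum(per_case$exposed) - a
  c <- sum(!per_case$exposed & per_case$caseid %in% has)
  d <- sum(!per_case$exposed) - c
  c(a = a, b = b, c = c, d = d)
}
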