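# hand-built collection: 8 target-drug cases with known sex and terms
subgroup_fixture <- function() {
  n <- 8
  pid <- as.character(101:108)
  demo <- data.table::data.table(
    primaryid = pid, caseid = pid,
    fda_dt = "20220101", event_dt = "20211201",
    sex = c("F", "F", "F", "F", "M", "M", "M", "unknown"),
    age_years = 60, weight_kg = 70, reporter = "MD", country = "US")
  reactions <- data.table::data.table(
    primaryid = c("101", "102", "103", "105", "106", "104", "107", "108"),
    pt = c("Nausea", "Nausea", "Nausea", "Nausea", "Rash", "Rash", "Rash",
           "Nausea"))
  obj <- list(demo = demo,
              drugs = data.table::data.table(
                primaryid = pid, drug_seq = "1", role_cod = "PS",
                drugname = "ABRAXANE", prod_ai = NA_character_,
                start_dt = NA_character_),
              reactions = data.table::setorder(reactions, primaryid, pt),
              outcomes = data.table::data.table(primaryid = character(),
                                                outc_cod = character()),
              indications = data.table::data.table(primaryid = character(),
                                                   indi_pt = character()),
              log = list())
  class(obj) <- "faers_cases"
  obj
}

test_that("gender tables match the 8-case hand enumeration", {
  cases <- subgroup_fixture()
  tgt <- match_target_drug(cases, nab_paclitaxel_names())
  expect_message(gender_tables(cases, tgt), "unknown sex")
  gtab <- suppressMessages(gender_tables(cases, tgt))
  # females: 4 known-sex, 3 with Nausea, 1 with Rash; males: 3, 1 and 2
  expect_equal(as.list(gtab[term == "Nausea"]),
               list(term = "Nausea", a_f = 3L, b_f = 1L, a_m = 1L, b_m = 2L))
  expect_equal(as.list(gtab[term == "Rash"]),
               list(term = "Rash", a_f = 1L, b_f = 3L, a_m = 2L, b_m = 1L))
})

test_that("swapping the sex labels inverts the gender ROR", {
  cases <- subgroup_fixture()
  tgt <- match_target_drug(cases, nab_paclitaxel_names())
  gtab <- suppressMessages(gender_tables(cases, tgt))
  swapped <- data.table::copy(gtab)
  data.table::setnames(swapped, c("a_f", "b_f", "a_m", "b_m"),
                       c("a_m", "b_m", "a_f", "b_f"))
  g1 <- gender_signals(gtab)
  g2 <- gender_signals(swapped)
  expect_equal(g1$ror_fm, 1 / g2$ror_fm, tolerance = 1e-12)
})

test_that("equal rates in both sexes give ROR near 1 and no direction", {
  g <- gender_signals(data.table::data.table(
    term = "X", a_f = 50, b_f = 450, a_m = 50, b_m = 450))
  expect_equal(g$ror_fm, 1)
  expect_equal(g$direction, "none")
})

test_that("volcano data carries one row per term with sign-consistent sides", {
  gtab <- data.table::data.table(
    term = c("F-dom", "M-dom", "Flat"),
    a_f = c(40, 5, 20), b_f = c(460, 495, 480),
    a_m = c(5, 40, 20), b_m = c(495, 460, 480))
  gs <- gender_signals(gtab)
  v <- volcano_data(gs)
  expect_equal(nrow(v), nrow(gtab))
  expect_equal(v$side[v$term == "F-dom"], "female")
  expect_equal(v$side[v$term == "M-dom"], "male")
  expect_equal(v$log_ror[v$term == "Flat"], 0)
  expect_equal(v$side[v$term == "Flat"], "none")
  expect_true(v$significant[v$term == "F-dom"])
  expect_false(v$significant[v$term == "Flat"])
  # significance set invariant under term reordering
  perm <- c(3, 1, 2)
  v2 <- volcano_data(gender_signals(gtab[perm]))
  expect_equal(sort(v2$term[v2$significant]), sort(v$term[v$significant]))
})

test_that("an injected female-specific effect is recovered on the female side", {
  vocab <- data.frame(pt = c("TargetPT", "FillerPT1", "FillerPT2"), soc = "S",
                      background_rate = c(0.02, 0.995, 0.99))
  effects <- data.frame(pt = "TargetPT", rho = 2, rho_f = 4, rho_m = 1)
  covered <- 0L
  for (seed in 51:55) {
    cfg <- synth_config(n_cases = 30000, p_target_drug = 0.2,
                        pt_vocab = vocab, effects = effects,
                        missing_date_rate = 0, duplicate_rate = 0, seed = seed)
    gen <- suppressMessages(generate_cases(cfg))
    tgt <- match_target_drug(gen$cases, nab_paclitaxel_names())
    gtab <- suppressMessages(gender_tables(gen$cases, tgt))
    gs <- gender_signals(gtab)
    v <- as.data.frame(volcano_data(gs))
    row <- v[v$term == "TargetPT", ]
    # power at these counts is essentially 1: detection must hold every time
    expect_true(row$significant)
    expect_equal(row$side, "female")
    # the 95% CI should cover the true odds ratio rho_f / rho_m = 4 in
    # most draws (each single draw misses with probability ~0.05)
    est <- as.data.frame(gs)[gs$term == "TargetPT", ]
    covered <- covered + (est$lo <= 4 && 4 <= est$hi)
  }
  expect_gte(covered, 4L)
})
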