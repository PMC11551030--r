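# Fixture builders: everything is generated in code at test time.

# raw FAERS-dialect tables for a hand-enumerated 5-case database:
# cases 1-2 exposed (nab-paclitaxel PS), cases 3-5 background drugs.
# PT "Neutropenia": only exposed case 1 -> a=1, b=1, c=0, d=3
# PT "Nausea": exposed case 2 plus background cases 3 and 4 -> a=1,b=1,c=2,d=1
# PT "Rash": background case 5 only -> a=0, b=2, c=1, d=2
five_case_raw <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, lines) writeLines(lines, file.path(dir, name))
  w("DEMO.txt", c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occp_cod$occr_country",
    "101$1$20210510$20210401$F$55$YR$62.5$KG$MD$US",
    "201$2$20210611$20210501$M$70$YR$$$MD$JP",
    "301$3$20210712$20210601$F$40$YR$55$KG$CN$US",
    "401$4$20210813$20210701$M$61$YR$80$KG$MD$DE",
    "501$5$20210914$20210801$F$35$YR$48$KG$MD$US"))
  w("DRUG.txt", c(
    "primaryid$drug_seq$role_cod$drugname$prod_ai",
    "101$1$PS$ABRAXANE$PACLITAXEL PROTEIN-BOUND PARTICLES",
    "201$1$PS$Albumin-Bound Paclitaxel$",
    "301$1$PS$CARBOPLATIN$",
    "401$1$PS$DOCETAXEL$",
    "501$1$PS$PACLITAXEL$"))
  w("REAC.txt", c(
    "primaryid$pt",
    "101$Neutropenia",
    "201$Nausea",
    "301$Nausea",
    "401$Nausea",
    "501$Rash"))
  w("THER.txt", c(
    "primaryid$dsg_drug_seq$start_dt",
    "101$1$20210301",
    "201$1$20210415"))
  w("OUTC.txt", c(
    "primaryid$outc_cod",
    "101$HO",
    "201$DE"))
  w("INDI.txt", c(
    "primaryid$indi_drug_seq$indi_pt",
    "101$1$Breast cancer",
    "201$1$Pancreatic cancer"))
  dir
}

five_case_vocab <- function() {
  data.frame(
    pt = c("Neutropenia", "Nausea", "Rash"),
    soc = c("Blood and lymphatic system disorders",
            "Gastrointestinal disorders",
            "Skin and subcutaneous tissue disorders")
  )
}

# assembled + deduplicated five-case collection and its target flags
five_case_cases <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  five_case_raw(dir)
  cases <- suppressMessages(assemble_cases(read_faers_dir_quiet(dir)))
  deduplicate_cases(cases)
}

read_faers_dir_quiet <- function(dir, ...) {
  suppressMessages(read_faers_dir(dir, ...))
}

# tiny synthetic config used throughout: a high-rate filler PT keeps the
# uniform-PT fallback for empty reaction sets from contaminating the
# effect PTs' backgrounds
recovery_config <- function(n_cases, rhos, q = 0.01, seed = 1,
                            p_target = 0.1, ...) {
  pts <- sprintf("EffectPT%02d", seq_along(rhos))
  # two near-certain fillers push P(empty reaction set) to ~5e-5, so the
  # uniform-PT fallback cannot contaminate the effect PTs' backgrounds
  vocab <- data.frame(
    pt = c(pts, "FillerPT1", "FillerPT2"),
    soc = "Test SOC",
    background_rate = c(rep(q, length(rhos)), 0.995, 0.99)
  )
  effects <- data.frame(pt = pts, rho = rhos)
  synth_config(n_cases = n_cases, p_target_drug = p_target,
               pt_vocab = vocab, effects = effects,
               missing_date_rate = 0, duplicate_rate = 0, seed = seed, ...)
}

# null config: many PTs, all rho = 1, mixed background rates
null_config <- function(n_cases, n_pts = 100, seed = 1) {
  rates <- round(seq(0.002, 0.02, length.out = n_pts), 5)
  vocab <- data.frame(pt = sprintf("NullPT%03d", seq_len(n_pts)),
                      soc = "Test SOC", background_rate = rates)
  synth_config(n_cases = n_cases, p_target_drug = 0.1, pt_vocab = vocab,
               effects = data.frame(pt = character(), rho = numeric()),
               missing_date_rate = 0, duplicate_rate = 0, seed = seed)
}

# mixed config: n_null background PTs plus a few injected effects
spiked_config <- function(n_cases, n_null = 200, n_effect = 5, rho = 8,
                          q_effect = 0.01, seed = 1) {
  rates <- round(seq(0.002, 0.02, length.out = n_null), 6)
  vocab <- data.frame(
    pt = c(sprintf("NullPT%03d", seq_len(n_null)),
           sprintf("EffectPT%02d", seq_len(n_effect))),
    soc = "Test SOC",
    background_rate = c(rates, rep(q_effect, n_effect))
  )
  effects <- data.frame(pt = sprintf("EffectPT%02d", seq_len(n_effect)),
                        rho = rho)
  synth_config(n_cases = n_cases, p_target_drug = 0.1, pt_vocab = vocab,
               effects = effects, missing_date_rate = 0,
               duplicate_rate = 0, seed = seed)
}

expect_cases_equal <- function(x, y) {
  for (comp in c("demo", "drugs", "reactions", "outcomes", "indications")) {
    expect_equal(as.data.frame(x[[comp]]), as.data.frame(y[[comp]]),
                 label = comp)
  }
}
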