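test_that("the same seed yields a bit-identical case collection", {
  cfg <- synth_config(n_cases = 500, seed = 11)
  g1 <- suppressMessages(generate_cases(cfg))
  g2 <- suppressMessages(generate_cases(cfg))
  expect_cases_equal(g1$cases, g2$cases)
  expect_equal(g1$truth$effects, g2$truth$effects)
  g3 <- suppressMessages(generate_cases(synth_config(n_cases = 500, seed = 12)))
  expect_false(identical(g1$cases$demo$fda_dt, g3$cases$demo$fda_dt))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_cases = 0), "n_cases")
  expect_error(synth_config(p_target_drug = 1.2), "p_target_drug")
  expect_error(synth_config(sex_probs = c(F = 0.9, M = 0.4)), "sum")
  vocab <- data.frame(pt = "X", soc = "S", background_rate = 1.5)
  expect_error(synth_config(pt_vocab = vocab), "background")
  expect_error(
    synth_config(effects = data.frame(pt = "NotInVocab", rho = 2)),
    "outside the vocab")
  expect_error(
    synth_config(onset_dist = list(family = "gamma", shape = 1, scale = 1)),
    "onset_dist")
})

test_that("every report carries at least one reaction", {
  cfg <- recovery_config(2000, c(2), seed = 3)
  # drop the filler so empty reaction sets actually occur
  cfg$pt_vocab <- cfg$pt_vocab[1]
  cfg$pt_vocab[, background_rate := 0.01]
  gen <- suppressMessages(generate_cases(cfg))
  expect_true(all(gen$cases$demo$primaryid %in% gen$cases$reactions$primaryid))
})

test_that("categorical marginals match their configured probabilities", {
  cfg <- synth_config(n_cases = 20000, seed = 5)
  gen <- suppressMessages(generate_cases(cfg))
  demo <- gen$cases$demo
  for (what in list(list(demo$sex, cfg$sex_probs),
                    list(demo$reporter, cfg$reporter_probs),
                    list(demo$country, cfg$country_probs))) {
    obs <- table(factor(what[[1]], levels = names(what[[2]])))
    for (lev in names(what[[2]])) {
      p <- what[[2]][[lev]]
      se <- sqrt(p * (1 - p) / nrow(demo))
      expect_lt(abs(obs[[lev]] / nrow(demo) - p), 3 * se + 1e-12)
    }
  }
})

test_that("the exact-odds construction recovers rho at large n", {
  cfg <- recovery_config(200000, c(2, 5, 10), seed = 17)
  gen <- suppressMessages(generate_cases(cfg))
  tgt <- match_target_drug(gen$cases, nab_paclitaxel_names())
  tab <- as.data.frame(build_contingency(gen$cases, tgt, "pt"))
  for (i in 1:3) {
    row <- tab[tab$term == sprintf("EffectPT%02d", i), ]
    est <- ror_stat(row$a, row$b, row$c, row$d)$ror
    rho <- c(2, 5, 10)[i]
    expect_lt(abs(est - rho) / rho, 0.10)
  }
})

test_that("the onset sampler hits the configured median", {
  cfg <- synth_config(n_cases = 12000, p_target_drug = 0.5,
                      missing_date_rate = 0, seed = 23)
  gen <- suppressMessages(generate_cases(cfg))
  tgt <- match_target_drug(gen$cases, nab_paclitaxel_names())
  days <- compute_onsets(gen$cases, tgt)
  expect_gt(sum(!is.na(days)), 5000)
  expect_lt(abs(median(days, na.rm = TRUE) - 41) / 41, 0.15)
  # weibull option works too
  cfgw <- synth_config(n_cases = 3000, p_target_drug = 0.5,
                       missing_date_rate = 0,
                       onset_dist = list(family = "weibull", shape = 0.8,
                                         scale = 60), seed = 24)
  genw <- suppressMessages(generate_cases(cfgw))
  dw <- compute_onsets(genw$cases, match_target_drug(genw$cases,
                                                     nab_paclitaxel_names()))
  expect_gt(sum(!is.na(dw)), 1000)
})

test_that("duplicate injection is invertible by deduplication", {
  gen <- suppressMessages(generate_cases(recovery_config(1000, c(3), seed = 9)))
  expect_cases_equal(inject_duplicates(gen$cases, 0), gen$cases)
  dup <- inject_duplicates(gen$cases, 0.2, seed = 4)
  expect_gt(n_reports(dup), n_reports(gen$cases))
  # duplicate versions share the caseid but never the primaryid
  expect_equal(anyDuplicated(dup$demo$primaryid), 0L)
  expect_cases_equal(deduplicate_cases(dup), gen$cases)
})

test_that("dialect writing round-trips and is delimiter-safe", {
  dir <- withr::local_tempdir()
  gen <- suppressMessages(generate_cases(synth_config(n_cases = 10, seed = 2)))
  write_faers_dialect(gen$cases, dir)
  back <- suppressMessages(assemble_cases(read_faers_dir_quiet(dir)))
  expect_cases_equal(back, gen$cases)
  # zero cases -> header-only files
  empty <- gen$cases
  empty <- pvsignal:::filter_cases(empty, character(0))
  d2 <- withr::local_tempdir()
  write_faers_dialect(empty, d2)
  expect_equal(nrow(data.table::fread(file.path(d2, "DEMO.txt"), sep = "$")), 0L)
  # a PT containing the delimiter is rejected with a clear error
  bad <- gen$cases
  bad$reactions[1, pt := "Nausea$vomiting"]
  expect_error(write_faers_dialect(bad, withr::local_tempdir()), "delimiter")
})
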