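# Synthetic spontaneous-report generator with known ground truth.
#
# Each case is generated independently: target-drug exposure is
# Bernoulli(p_target_drug); a PT with background reporting rate q and
# injected odds multiplier rho is included for an exposed case with
# probability q*rho / (1 - q + q*rho), i.e. the inclusion odds are
# q/(1-q) * rho, so the population reporting odds ratio for that PT equals
# rho exactly. Optional per-sex multipliers rho_f / rho_m replace rho for
# exposed female / male cases, making the within-drug female-vs-male
# reporting odds ratio exactly rho_f / rho_m. Demographic marginals default
# to the clinical profile typical of a nab-paclitaxel reporting population
# (slight female preponderance, adult ages, mostly healthcare-professional
# reporters). Onsets are right-skewed (log-normal by default) and a
# configurable fraction of event dates is degraded to month precision so
# that only part of the onsets is evaluable, as in real spontaneous data.

.norm_probs <- function(p, what) {
  if (any(p < 0)) stop("negative probability in ", what, call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 0.02) {
    stop(sprintf("%s probabilities sum to %.4f, not 1", what, s),
         call. = FALSE)
  }
  p / s
}

#' Default PT vocabulary for the synthetic generator
#'
#' A compact vocabulary of MedDRA-style preferred terms across the organ
#' classes prominent in cytotoxic-chemotherapy safety profiles, each with a
#' background reporting rate. Serves as the stand-in for a licensed MedDRA
#' export.
#'
#' @return data.table with columns `pt`, `soc`, `background_rate`.
#' @export
default_pt_vocab <- function() {
  soc_blood <- "Blood and lymphatic system disorders"
  soc_hep <- "Hepatobiliary disorders"
  soc_gi <- "Gastrointestinal disorders"
  soc_gen <- "General disorders and administration site conditions"
  soc_nerv <- "Nervous system disorders"
  soc_inf <- "Infections and infestations"
  soc_inv <- "Investigations"
  soc_resp <- "Respiratory, thoracic and mediastinal disorders"
  soc_skin <- "Skin and subcutaneous tissue disorders"
  soc_msk <- "Musculoskeletal and connective tissue disorders"
  soc_eye <- "Eye disorders"
  soc_vasc <- "Vascular disorders"
  # background rates sum to ~1.5, so most reports carry one to three terms;
  # a much lower total would make the uniform-PT fallback for empty
  # reaction sets a visible contaminant of the rare PTs' backgrounds
  data.table::data.table(rbind(
    c("Febrile neutropenia", soc_blood, 0.010),
    c("Neutropenia", soc_blood, 0.022),
    c("Neutrophil count decreased", soc_inv, 0.013),
    c("Anaemia", soc_blood, 0.045),
    c("Thrombocytopenia", soc_blood, 0.022),
    c("Bone marrow failure", soc_blood, 0.005),
    c("Disseminated intravascular coagulation", soc_blood, 0.003),
    c("Cholangitis", soc_hep, 0.003),
    c("Biliary tract infection", soc_inf, 0.002),
    c("Immune-mediated hepatitis", soc_hep, 0.002),
    c("Hepatic function abnormal", soc_hep, 0.013),
    c("Nausea", soc_gi, 0.130),
    c("Vomiting", soc_gi, 0.100),
    c("Diarrhoea", soc_gi, 0.100),
    c("Stomatitis", soc_gi, 0.016),
    c("Upper gastrointestinal haemorrhage", soc_gi, 0.004),
    c("Duodenal obstruction", soc_gi, 0.001),
    c("Fatigue", soc_gen, 0.150),
    c("Pyrexia", soc_gen, 0.090),
    c("Chest discomfort", soc_gen, 0.022),
    c("Peripheral sensory neuropathy", soc_nerv, 0.003),
    c("Neuropathy peripheral", soc_nerv, 0.013),
    c("Headache", soc_nerv, 0.100),
    c("Pneumonia", soc_inf, 0.045),
    c("Sepsis", soc_inf, 0.020),
    c("Interstitial lung disease", soc_resp, 0.009),
    c("Dyspnoea", soc_resp, 0.080),
    c("Rash", soc_skin, 0.100),
    c("Erythema", soc_skin, 0.022),
    c("Alopecia", soc_skin, 0.016),
    c("Bone pain", soc_msk, 0.011),
    c("Arthralgia", soc_msk, 0.045),
    c("Cystoid macular oedema", soc_eye, 0.001),
    c("Vision blurred", soc_eye, 0.016),
    c("Embolism", soc_vasc, 0.005),
    c("Hypertension", soc_vasc, 0.050),
    c("Malaise", soc_gen, 0.065),
    c("Oedema peripheral", soc_gen, 0.050),
    c("Decreased appetite", soc_gi, 0.065),
    c("Dizziness", soc_nerv, 0.065)
  ))[, .(pt = V1, soc = V2, background_rate = as.numeric(V3))]
}

#' Default injected reporting-odds multipliers
#'
#' The effect profile emulated by default: strong haematological,
#' hepatobiliary and neuropathy signals, with gender-specific multipliers
#' (`rho_f`, `rho_m` replace `rho` for exposed female/male cases) for the
#' terms whose reporting differs by sex.
#'
#' @return data.table with columns `pt`, `rho`, `rho_f`, `rho_m`.
#' @export
default_effects <- function() {
  data.table::data.table(
    pt = c("Febrile neutropenia", "Neutropenia", "Neutrophil count decreased",
           "Anaemia", "Thrombocytopenia", "Bone marrow failure",
           "Disseminated intravascular coagulation", "Cholangitis",
           "Biliary tract infection", "Immune-mediated hepatitis",
           "Peripheral sensory neuropathy", "Nausea", "Vomiting",
           "Erythema", "Bone pain", "Chest discomfort",
           "Upper gastrointestinal haemorrhage", "Interstitial lung disease",
           "Cystoid macular oedema", "Embolism"),
    rho = c(15, 8, 13, 4, 5, 6, 4, 55, 170, 10,
            50, 2, 2, 2.5, 3, 2, 3, 3, 12, 12.8),
    rho_f = c(10, 8, 13, 4, 5, 6, 2, 30, 170, 4,
              50, 2.6, 2.6, 3.4, 6.5, 2.8, 2, 2, 12, 12.8),
    rho_m = c(20, 8, 13, 4, 5, 6, 8, 75, 170, 33,
              50, 1.5, 1.5, 1.6, 0.8, 1.4, 4.5, 4.5, 12, 12.8)
  )
}

#' Synthetic-database configuration
#'
#' Assembles and validates the generator configuration. Defaults emulate
#' the clinical profile of a nab-paclitaxel reporting population: sex
#' 48.1% F / 42.13% M, age concentrated in adulthood, weight mostly
#' unreported, healthcare-professional reporters dominating, US-led country
#' mix, death/hospitalization-heavy outcomes, pancreatic/breast/lung cancer
#' indications, and a log-normal onset distribution with median 41 days
#' whose spread is fitted by least squares to target quartiles of 11 and
#' 97 days.
#'
#' @param n_cases number of reports to generate (default 50000).
#' @param p_target_drug probability a case is exposed to the target drug.
#' @param pt_vocab data.frame `pt`, `soc`, `background_rate`.
#' @param effects data.frame `pt`, `rho` and optional `rho_f`, `rho_m`;
#'   terms not listed have rho = 1.
#' @param sex_probs,age_probs,weight_probs,country_probs,reporter_probs,outcome_probs,indication_probs
#'   named probability vectors for the categorical marginals.
#' @param onset_dist list: `family` (`"lognormal"` or `"weibull"`) plus
#'   `meanlog`/`sdlog` or `shape`/`scale`.
#' @param missing_date_rate fraction of exposed cases whose event date is
#'   degraded to month precision (onset inevaluable).
#' @param duplicate_rate fraction of cases that gain extra report versions
#'   when [inject_duplicates()] is applied by the pipeline.
#' @param window character vector of two dates (therapy/report window).
#' @param seed integer RNG seed.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(
    n_cases = 50000,
    p_target_drug = 0.1,
    pt_vocab = default_pt_vocab(),
    effects = default_effects(),
    sex_probs = c(F = 0.481, M = 0.4213, unknown = 0.0977),
    age_probs = c("18-65" = 0.3588, ">65" = 0.3616, unknown = 0.2796),
    weight_probs = c("<50" = 0.0497, "50-80" = 0.2537, ">80" = 0.0994,
                     unknown = 0.5972),
    country_probs = c(US = 0.4402, JP = 0.1293, DE = 0.0897, CA = 0.0697,
                      ES = 0.0373, OTHER = 0.2338),
    reporter_probs = c(HP = 0.8924, CN = 0.0924, unknown = 0.0152),
    outcome_probs = c(DE = 0.3588, HO = 0.3247, OT = 0.1898, LT = 0.054,
                      DS = 0.0093, none = 0.0634),
    indication_probs = c("Pancreatic cancer" = 0.396, "Breast cancer" = 0.1786,
                         "Lung cancer" = 0.1249, "Other malignancy" = 0.3005),
    onset_dist = list(family = "lognormal", meanlog = log(41),
                      sdlog = log(97 / 11) / (2 * stats::qnorm(0.75))),
    missing_date_rate = 1 - 0.4616,
    duplicate_rate = 0.05,
    window = c("2005-01-01", "2023-12-31"),
    seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) {
    stop("n_cases must be a positive integer", call. = FALSE)
  }
  if (p_target_drug <= 0 || p_target_drug >= 1) {
    stop("p_target_drug must be in (0, 1)", call. = FALSE)
  }
  vocab <- data.table::as.data.table(pt_vocab)
  stopifnot(all(c("pt", "soc", "background_rate") %in% names(vocab)))
  if (any(vocab$background_rate <= 0 | vocab$background_rate >= 1)) {
    stop("background rates must lie in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(vocab$pt)) stop("duplicate PTs in vocab", call. = FALSE)
  eff <- data.table::as.data.table(effects)
  if (nrow(eff)) {
    stopifnot(all(c("pt", "rho") %in% names(eff)))
    if (!"rho_f" %in% names(eff)) eff[, rho_f := NA_real_]
    if (!"rho_m" %in% names(eff)) eff[, rho_m := NA_real_]
    extra <- setdiff(eff$pt, vocab$pt)
    if (length(extra)) {
      stop("effects reference PTs outside the vocab: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (any(eff$rho < 0, na.rm = TRUE)) {
      stop("odds multipliers must be >= 0", call. = FALSE)
    }
  } else {
    eff <- data.table::data.table(pt = character(), rho = numeric(),
                                  rho_f = numeric(), rho_m = numeric())
  }
  if (!onset_dist$family %in% c("lognormal", "weibull")) {
    stop("onset_dist$family must be 'lognormal' or 'weibull'", call. = FALSE)
  }
  if (onset_dist$family == "lognormal" &&
      (!is.finite(onset_dist$meanlog) || onset_dist$sdlog <= 0)) {
    stop("invalid lognormal onset parameters", call. = FALSE)
  }
  if (onset_dist$family == "weibull" &&
      (onset_dist$shape <= 0 || onset_dist$scale <= 0)) {
    stop("invalid weibull onset parameters", call. = FALSE)
  }
  if (missing_date_rate < 0 || missing_date_rate >= 1) {
    stop("missing_date_rate must be in [0, 1)", call. = FALSE)
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0, 1)", call. = FALSE)
  }
  cfg <- list(
    n_cases = as.integer(n_cases),
    p_target_drug = p_target_drug,
    pt_vocab = vocab,
    effects = eff,
    sex_probs = .norm_probs(sex_probs, "sex"),
    age_probs = .norm_probs(age_probs, "age"),
    weight_probs = .norm_probs(weight_probs, "weight"),
    country_probs = .norm_probs(country_probs, "country"),
    reporter_probs = .norm_probs(reporter_probs, "reporter"),
    outcome_probs = .norm_probs(outcome_probs, "outcome"),
    indication_probs = .norm_probs(indication_probs, "indication"),
    onset_dist = onset_dist,
    missing_date_rate = missing_date_rate,
    duplicate_rate = duplicate_rate,
    window = as.Date(window),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

.sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

.age_band_to_years <- function(band) {
  n <- length(band)
  out <- rep(NA_real_, n)
  i <- band == "<18"; out[i] <- round(runif(sum(i), 1, 17))
  i <- band == "18-65"; out[i] <- round(runif(sum(i), 18, 65))
  i <- band == ">65"; out[i] <- round(runif(sum(i), 66, 90))
  out
}

.weight_band_to_kg <- function(band) {
  n <- length(band)
  out <- rep(NA_real_, n)
  i <- band == "<50"; out[i] <- round(runif(sum(i), 35, 49.9), 1)
  i <- band == "50-80"; out[i] <- round(runif(sum(i), 50, 80), 1)
  i <- band == ">80"; out[i] <- round(runif(sum(i), 80.1, 120), 1)
  out
}

.sample_onset <- function(n, dist) {
  switch(dist$family,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    weibull = stats::rweibull(n, dist$shape, dist$scale)
  )
}

.background_drugs <- c("CARBOPLATIN", "GEMCITABINE HCL", "DOCETAXEL",
                       "PEMBROLIZUMAB", "CAPECITABINE", "OXALIPLATIN",
                       "PACLITAXEL", "CISPLATIN", "FLUOROURACIL",
                       "BEVACIZUMAB")

#' Generate a synthetic spontaneous-report database with ground truth
#'
#' See [synth_config()] for the generative model. The same seed yields a
#' bit-identical case collection. Cases that draw zero PTs are assigned one
#' uniformly-random PT so that every report carries at least one reaction.
#'
#' @param config a `synth_config` object.
#' @return list with `cases` (a `faers_cases` collection, one version per
#'   case, ordered by caseid) and `truth` (injected multipliers per PT and
#'   the onset parameters).
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_cases
  vocab <- config$pt_vocab
  P <- nrow(vocab)

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  exposed <- runif(n) < config$p_target_drug
  sex <- .sample_cat(n, config$sex_probs)
  age_band <- .sample_cat(n, config$age_probs)
  weight_band <- .sample_cat(n, config$weight_probs)
  country <- .sample_cat(n, config$country_probs)
  reporter <- .sample_cat(n, config$reporter_probs)
  outcome <- .sample_cat(n, config$outcome_probs)
  indication <- .sample_cat(n, config$indication_probs)
  age_years <- .age_band_to_years(age_band)
  weight_kg <- .weight_band_to_kg(weight_band)

  # per-case, per-PT inclusion probability with exact-odds construction
  q <- vocab$background_rate
  rho <- rho_f <- rho_m <- rep(1, P)
  if (nrow(config$effects)) {
    idx <- match(config$effects$pt, vocab$pt)
    rho[idx] <- config$effects$rho
    rho_f[idx] <- data.table::fifelse(is.na(config$effects$rho_f),
                                      config$effects$rho, config$effects$rho_f)
    rho_m[idx] <- data.table::fifelse(is.na(config$effects$rho_m),
                                      config$effects$rho, config$effects$rho_m)
  }
  mult <- matrix(1, n, P)
  for (grp in list(list(exposed & sex == "F", rho_f),
                   list(exposed & sex == "M", rho_m),
                   list(exposed & sex == "unknown", rho))) {
    k <- sum(grp[[1]])
    if (k > 0) mult[grp[[1]], ] <- matrix(grp[[2]], k, P, byrow = TRUE)
  }
  qmat <- matrix(q, n, P, byrow = TRUE)
  p_incl <- qmat * mult / (1 - qmat + qmat * mult)
  incl <- matrix(runif(n * P), n, P) < p_incl
  none <- rowSums(incl) == 0L
  if (any(none)) {
    # every report must carry at least one reaction
    fill <- sample.int(P, sum(none), replace = TRUE)
    incl[cbind(which(none), fill)] <- TRUE
  }
  hits <- which(incl, arr.ind = TRUE)
  reactions <- data.table::data.table(primaryid = primaryid[hits[, 1]],
                                      pt = vocab$pt[hits[, 2]])

  # dates: exposed cases get a therapy start and an onset-driven event date
  win <- config$window
  start_pool <- as.integer(win[2] - win[1]) - 430L
  therapy_start <- rep(as.Date(NA), n)
  event_date <- win[1] + floor(runif(n, 0, as.integer(win[2] - win[1]) + 1))
  onset <- rep(NA_real_, n)
  ne <- sum(exposed)
  if (ne > 0) {
    therapy_start[exposed] <- win[1] + floor(runif(ne, 0, start_pool + 1))
    onset[exposed] <- .sample_onset(ne, config$onset_dist)
    event_date[exposed] <- therapy_start[exposed] + round(onset[exposed])
  }
  fda_date <- event_date + floor(runif(n, 3, 121))
  event_dt <- format_yyyymmdd(event_date)
  degrade <- exposed & runif(n) < config$missing_date_rate
  event_dt[degrade] <- substr(event_dt[degrade], 1, 6)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format_yyyymmdd(fda_date), event_dt = event_dt,
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    reporter = reporter, country = country
  )

  target_names <- c("ABRAXANE", "PACLITAXEL PROTEIN-BOUND PARTICLES",
                    "ALBUMIN-BOUND PACLITAXEL",
                    "PACLITAXEL FOR INJECTION (ALBUMIN BOUND)")
  drugname <- character(n)
  drugname[exposed] <- target_names[sample.int(4, ne, replace = TRUE)]
  drugname[!exposed] <- .background_drugs[
    sample.int(length(.background_drugs), n - ne, replace = TRUE)]
  prod_ai <- data.table::fifelse(exposed, "PACLITAXEL PROTEIN-BOUND PARTICLES",
                                 NA_character_)
  drugs <- data.table::data.table(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = drugname, prod_ai = prod_ai,
    start_dt = data.table::fifelse(is.na(therapy_start), NA_character_,
                                   format_yyyymmdd(therapy_start))
  )
  conco <- exposed & runif(n) < 0.3
  if (any(conco)) {
    drugs <- rbind(drugs, data.table::data.table(
      primaryid = primaryid[conco], drug_seq = "2", role_cod = "C",
      drugname = .background_drugs[sample.int(length(.background_drugs),
                                              sum(conco), replace = TRUE)],
      prod_ai = NA_character_, start_dt = NA_character_
    ))
  }

  outcomes <- data.table::data.table(primaryid = primaryid,
                                     outc_cod = outcome)[outc_cod != "none"]
  indications <- data.table::data.table(primaryid = primaryid,
                                        indi_pt = indication)

  obj <- list(
    demo = data.table::setorder(demo, caseid, primaryid),
    drugs = data.table::setorder(drugs, primaryid, drug_seq),
    reactions = data.table::setorder(unique(reactions), primaryid, pt),
    outcomes = data.table::setorder(outcomes, primaryid, outc_cod),
    indications = data.table::setorder(indications, primaryid, indi_pt),
    log = list()
  )
  class(obj) <- "faers_cases"

  truth <- list(
    effects = data.table::data.table(pt = vocab$pt, rho = rho,
                                     rho_f = rho_f, rho_m = rho_m),
    onset = config$onset_dist,
    exposed_primaryids = primaryid[exposed],
    seed = config$seed
  )
  list(cases = obj, truth = truth)
}

#' Inject duplicate report versions
#'
#' A random subset of cases gains one or two extra report versions with the
#' same `caseid`, a strictly earlier `fda_dt` and a distinct `primaryid`
#' (all child rows copied), so that [deduplicate_cases()] restores the
#' original collection exactly.
#'
#' @param cases a `faers_cases` collection (one version per case).
#' @param rate fraction of cases duplicated, in `[0, 1)`.
#' @param seed RNG seed for the duplicate draw.
#' @return A `faers_cases` collection containing original plus duplicate
#'   versions.
#' @export
inject_duplicates <- function(cases, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || n_reports(cases) == 0L) return(cases)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  demo <- cases$demo
  pick <- which(runif(nrow(demo)) < rate)
  if (!length(pick)) return(cases)
  n_extra <- sample(1:2, length(pick), replace = TRUE)
  src <- rep(pick, n_extra)
  version <- unlist(lapply(n_extra, seq_len)) # 1..k within each picked case

  new_demo <- demo[src]
  old_pid <- new_demo$primaryid
  # earlier versions: smaller primaryid suffix and strictly earlier fda_dt
  new_pid <- paste0(new_demo$caseid, "0", version)
  back <- floor(runif(length(src), 30, 401)) + 180 * (version - 1)
  new_demo[, primaryid := new_pid]
  new_demo[, fda_dt := format_yyyymmdd(partial_date_as_date(fda_dt) - back)]

  clone <- function(dt) {
    idx <- which(dt$primaryid %in% old_pid)
    if (!length(idx)) return(dt[0])
    out <- dt[rep(idx, 1)][0] # empty with same structure
    pieces <- lapply(seq_along(old_pid), function(k) {
      rows <- dt[primaryid == old_pid[k]]
      rows[, primaryid := new_pid[k]]
      rows
    })
    data.table::rbindlist(pieces)
  }

  obj <- list(
    demo = data.table::setorder(rbind(demo, new_demo), caseid, primaryid),
    drugs = data.table::setorder(rbind(cases$drugs, clone(cases$drugs)),
                                 primaryid, drug_seq),
    reactions = data.table::setorder(rbind(cases$reactions, clone(cases$reactions)),
                                     primaryid, pt),
    outcomes = data.table::setorder(rbind(cases$outcomes, clone(cases$outcomes)),
                                    primaryid, outc_cod),
    indications = data.table::setorder(rbind(cases$indications, clone(cases$indications)),
                                       primaryid, indi_pt),
    log = cases$log
  )
  class(obj) <- "faers_cases"
  obj
}

#' Write a case collection as FAERS-dialect ASCII files
#'
#' Emits DEMO.txt, DRUG.txt, REAC.txt, THER.txt, OUTC.txt and INDI.txt in
#' the "$"-delimited dialect accepted by [read_faers_table()]. Any field
#' value containing the delimiter is rejected with an error rather than
#' silently corrupting the files.
#'
#' @param cases a `faers_cases` collection.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_faers_dialect <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output dir: ", dir, call. = FALSE)

  check_dollar <- function(dt, file) {
    chr <- names(dt)[vapply(dt, is.character, logical(1))]
    for (col in chr) {
      if (any(grepl("$", dt[[col]], fixed = TRUE))) {
        stop(sprintf("value containing the '$' delimiter in column %s of %s",
                     col, file), call. = FALSE)
      }
    }
  }
  blank <- function(x) data.table::fifelse(is.na(x), "", as.character(x))

  d <- cases$demo
  demo_out <- data.table::data.table(
    primaryid = d$primaryid, caseid = d$caseid,
    fda_dt = blank(d$fda_dt), event_dt = blank(d$event_dt),
    sex = data.table::fifelse(d$sex %in% c("F", "M"), d$sex, ""),
    age = blank(d$age_years),
    age_cod = data.table::fifelse(is.na(d$age_years), "", "YR"),
    wt = blank(d$weight_kg),
    wt_cod = data.table::fifelse(is.na(d$weight_kg), "", "KG"),
    occp_cod = data.table::fifelse(d$reporter == "unknown", "", d$reporter),
    occr_country = data.table::fifelse(d$country == "unknown", "", d$country)
  )
  dr <- cases$drugs
  drug_out <- dr[, .(primaryid, drug_seq, role_cod,
                     drugname = blank(drugname), prod_ai = blank(prod_ai))]
  ther_out <- dr[!is.na(start_dt),
                 .(primaryid, dsg_drug_seq = drug_seq, start_dt)]
  reac_out <- cases$reactions[, .(primaryid, pt)]
  outc_out <- cases$outcomes[, .(primaryid, outc_cod)]
  indi_out <- cases$indications[, .(primaryid, indi_drug_seq = "1",
                                    indi_pt)]

  files <- c(DEMO = "DEMO.txt", DRUG = "DRUG.txt", REAC = "REAC.txt",
             THER = "THER.txt", OUTC = "OUTC.txt", INDI = "INDI.txt")
  tabs <- list(demo_out, drug_out, reac_out, ther_out, outc_out, indi_out)
  names(tabs) <- files
  paths <- character(0)
  for (f in names(tabs)) {
    check_dollar(tabs[[f]], f)
    p <- file.path(dir, f)
    data.table::fwrite(tabs[[f]], p, sep = "$", quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a directory written by [write_faers_dialect()]
#'
#' @param dir directory holding DEMO.txt .. INDI.txt.
#' @param aliases optional column alias map, see [read_faers_table()].
#' @return named list of raw tables suitable for [assemble_cases()].
#' @export
read_faers_dir <- function(dir, aliases = NULL) {
  kinds <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
             ther = "THER.txt", outc = "OUTC.txt", indi = "INDI.txt")
  out <- list()
  for (k in names(kinds)) {
    p <- file.path(dir, kinds[[k]])
    if (file.exists(p)) out[[k]] <- read_faers_table(p, k, aliases = aliases)
  }
  out
}
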