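# End-to-end orchestration: ingest or simulate, deduplicate, match the
# target drug, contingency tables at PT and SOC level, four-algorithm
# signal scan, time-to-onset, gender subgroup, descriptive and Sankey flow
# tables — all from one validated config, with a manifest recording the
# seed and a config hash so runs are reproducible.

.age_bands <- function(age) {
  data.table::fcase(
    is.na(age), "unknown",
    age < 18, "<18",
    age <= 65, "18-65",
    default = ">65"
  )
}

.weight_bands <- function(kg) {
  data.table::fcase(
    is.na(kg), "unknown",
    kg < 50, "<50",
    kg <= 80, "50-80",
    default = ">80"
  )
}

#' Pipeline run configuration
#'
#' Validates and freezes everything a run depends on. Either `input_dir`
#' (a directory of FAERS-dialect files) or `synthetic = TRUE` (generate a
#' database from `synth`) must be chosen.
#'
#' @param input_dir directory with DEMO.txt .. INDI.txt, or `NULL`.
#' @param synthetic generate the database instead of reading one.
#' @param synth a [synth_config()] used when `synthetic` is `TRUE`.
#' @param drug_names target drug name patterns.
#' @param roles role codes counted as target exposure.
#' @param alpha family-wise significance level.
#' @param top_fraction fraction of ranked consensus PTs reported.
#' @param levels event levels to scan (`"pt"`, `"soc"`).
#' @param vocab_path optional PT-to-SOC CSV; the synthetic vocab is used
#'   for synthetic runs when omitted.
#' @param window year range kept (reports filtered on `fda_dt` year).
#' @param out_dir output directory.
#' @param seed integer seed for the synthetic generator and duplicate
#'   injection.
#' @param aliases optional column alias map for pre-2012Q4 dialects.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synthetic = is.null(input_dir),
                       synth = synth_config(seed = seed),
                       drug_names = nab_paclitaxel_names(), roles = "PS",
                       alpha = 0.05, top_fraction = 0.2,
                       levels = c("pt", "soc"), vocab_path = NULL,
                       window = c(2005L, 2023L), out_dir = tempfile("pvrun"),
                       seed = 1L, aliases = NULL) {
  if (is.null(input_dir) && !synthetic) {
    stop("config error: either input_dir or synthetic = TRUE is required",
         call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("config error: input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (!length(drug_names)) stop("config error: drug_names is empty", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must be in (0,1)", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("config error: top_fraction must be in (0,1]", call. = FALSE)
  }
  levels <- match.arg(levels, c("pt", "soc"), several.ok = TRUE)
  if (length(window) != 2L || window[1] > window[2]) {
    stop("config error: window must be c(first_year, last_year)", call. = FALSE)
  }
  cfg <- list(input_dir = input_dir, synthetic = synthetic, synth = synth,
              drug_names = drug_names, roles = roles, alpha = alpha,
              top_fraction = top_fraction, levels = levels,
              vocab_path = vocab_path, window = as.integer(window),
              out_dir = out_dir, seed = as.integer(seed), aliases = aliases)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `synth`
#' block maps onto [synth_config()].
#'
#' @param path YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  y$synth <- NULL
  seed <- y$seed %||% 1L
  if (is.null(synth_args$seed)) synth_args$seed <- seed
  args <- y
  args$synth <- do.call(synth_config, synth_args)
  do.call(run_config, args)
}

#' Sankey flow data across adjacent category axes
#'
#' For each adjacent pair of axes, counts the flow between category pairs.
#' Missing values are routed to an explicit `"unknown"` node, so flows out
#' of every interior node sum to the flows in.
#'
#' @param case_df data.frame with one row per case and one column per
#'   axis (e.g. sex, age band, weight band, indication, outcome).
#' @param axes ordered character vector of column names.
#' @return data.table: `axis_from`, `axis_to`, `from`, `to`, `flow`.
#' @export
sankey_flows <- function(case_df, axes) {
  dt <- data.table::as.data.table(case_df)
  stopifnot(all(axes %in% names(dt)), length(axes) >= 2L)
  for (ax in axes) {
    v <- as.character(dt[[ax]])
    v[is.na(v)] <- "unknown"
    data.table::set(dt, j = ax, value = v)
  }
  out <- list()
  for (i in seq_len(length(axes) - 1L)) {
    from_ax <- axes[i]; to_ax <- axes[i + 1L]
    fl <- dt[, .(flow = .N), by = c(from_ax, to_ax)]
    data.table::setnames(fl, c(from_ax, to_ax), c("from", "to"))
    fl[, `:=`(axis_from = from_ax, axis_to = to_ax)]
    out[[i]] <- fl[, .(axis_from, axis_to, from, to, flow)]
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, axis_from, from, to)
  res[]
}

# per-case descriptive frame for target reports (one row per case)
.case_frame <- function(cases, target) {
  demo <- cases$demo[target]
  outc <- cases$outcomes[, head(.SD, 1L), by = primaryid] # primary outcome
  indi <- cases$indications[, head(.SD, 1L), by = primaryid]
  df <- merge(demo, outc, by = "primaryid", all.x = TRUE, sort = FALSE)
  df <- merge(df, indi, by = "primaryid", all.x = TRUE, sort = FALSE)
  df[, `:=`(
    age_band = .age_bands(age_years),
    weight_band = .weight_bands(weight_kg),
    outcome = data.table::fifelse(is.na(outc_cod), "none", outc_cod),
    indication = data.table::fifelse(is.na(indi_pt), "unknown", indi_pt),
    year = parse_partial_date(fda_dt)$year
  )]
  df
}

# counts and percentages by category, long format
.descriptive_table <- function(df) {
  vars <- c("sex", "age_band", "weight_band", "reporter", "country",
            "outcome", "indication")
  n <- nrow(df)
  pieces <- lapply(vars, function(v) {
    tab <- df[, .(count = .N), by = c(v)]
    data.table::setnames(tab, v, "category")
    tab[, `:=`(variable = v, pct = 100 * count / n)]
    data.table::setorder(tab, -count)
    tab[, .(variable, category, count, pct)]
  })
  data.table::rbindlist(pieces)
}

#' Run the full signal-detection pipeline
#'
#' Stages run in order: ingest or simulate (synthetic runs also inject
#' duplicate versions, write the dialect files and read them back, so the
#' IO path is exercised end to end) -> deduplicate -> match target drug ->
#' contingency tables -> four-algorithm scan with Bonferroni and consensus
#' ranking -> time-to-onset -> gender subgroup -> descriptive, annual and
#' Sankey tables. Every stage logs its input/output counts; identical
#' config and seed give an identical bundle.
#'
#' @param config a [run_config()] object.
#' @param write write the output files under `config$out_dir` (default
#'   `TRUE`).
#' @return list of class `report_bundle` with elements `cases`, `target`,
#'   `signals_pt`, `signals_soc`, `top_pt`, `onset`, `gender`, `volcano`,
#'   `descriptive`, `annual`, `sankey`, `truth` (synthetic runs), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- "ingest"
  bundle <- list()
  tryCatch({
    if (config$synthetic) {
      gen <- generate_cases(config$synth)
      bundle$truth <- gen$truth
      with_dups <- inject_duplicates(gen$cases, config$synth$duplicate_rate,
                                     seed = config$seed + 1L)
      io_dir <- file.path(config$out_dir, "faers_ascii")
      write_faers_dialect(with_dups, io_dir)
      raw <- read_faers_dir(io_dir)
      vocab <- config$synth$pt_vocab[, .(pt, soc)]
    } else {
      raw <- read_faers_dir(config$input_dir, aliases = config$aliases)
      vocab <- if (!is.null(config$vocab_path)) read_pt_vocab(config$vocab_path)
               else NULL
    }
    cases <- assemble_cases(raw)
    message(sprintf("stage ingest: %d report(s)", n_reports(cases)))

    stage <- "dedup"
    cases <- deduplicate_cases(cases)
    yrs <- parse_partial_date(cases$demo$fda_dt)$year
    in_window <- !is.na(yrs) & yrs >= config$window[1] &
      yrs <= config$window[2]
    # report versions are selected before windowing so the current version
    # decides the case's date
    cases <- filter_cases(cases, cases$demo$primaryid[in_window])
    message(sprintf("stage dedup: %d case(s) in window", n_reports(cases)))

    stage <- "match"
    target <- match_target_drug(cases, config$drug_names, config$roles)
    message(sprintf("stage match: %d target-drug case(s)", sum(target)))

    stage <- "contingency/disprop"
    bundle$signals_pt <- NULL
    if ("pt" %in% config$levels) {
      tab_pt <- build_contingency(cases, target, "pt", vocab)
      bundle$signals_pt <- signal_scan(tab_pt, alpha = config$alpha)
      bundle$top_pt <- consensus_and_rank(bundle$signals_pt,
                                          top_fraction = config$top_fraction,
                                          alpha = config$alpha)
    }
    if ("soc" %in% config$levels && !is.null(vocab)) {
      tab_soc <- build_contingency(cases, target, "soc", vocab)
      # SOC families are small; reuse the PT-level prior for shrinkage
      prior <- attr(bundle$signals_pt, "gps_prior")
      bundle$signals_soc <- signal_scan(tab_soc, alpha = config$alpha,
                                        prior = prior)
    }

    stage <- "tto"
    onsets <- compute_onsets(cases, target, names = config$drug_names,
                             roles = config$roles)
    bundle$onset <- if (any(!is.na(onsets))) {
      summarize_onsets(onsets, n_total = length(onsets))
    } else NULL

    stage <- "subgroup"
    gtab <- gender_tables(cases, target)
    if (nrow(gtab)) {
      bundle$gender <- gender_signals(gtab, alpha = config$alpha)
      bundle$volcano <- volcano_data(bundle$gender, alpha = config$alpha)
    }

    stage <- "report"
    df <- .case_frame(cases, target)
    bundle$descriptive <- .descriptive_table(df)
    bundle$annual <- df[, .(count = .N), by = year][order(year)]
    bundle$sankey <- sankey_flows(
      df, c("sex", "age_band", "weight_band", "indication", "outcome"))
    bundle$cases <- cases
    bundle$target <- target
    bundle$manifest <- list(
      seed = config$seed,
      alpha = config$alpha,
      window = config$window,
      n_reports = n_reports(cases),
      n_target = sum(target),
      config_hash = config_hash(config),
      files = character(0)
    )
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (write) {
    bundle$manifest$files <- write_bundle(bundle, config$out_dir)
  }
  class(bundle) <- "report_bundle"
  bundle
}

#' Stable hash of a run configuration
#'
#' md5 of the canonical serialized config, used in the manifest to tie
#' outputs to the exact configuration.
#'
#' @param config a `run_config`.
#' @return character md5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  essence <- unclass(config)
  essence$out_dir <- NULL # where outputs land does not change what they are
  essence <- lapply(essence, function(x) {
    if (data.table::is.data.table(x)) as.list(as.data.frame(x)) else x
  })
  saveRDS(essence, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# write the bundle's tables; returns the file names written
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(dt, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(dt, p)
    files <<- c(files, name)
  }
  if (!is.null(bundle$signals_pt)) wr(bundle$signals_pt, "signals_pt.csv")
  if (!is.null(bundle$signals_soc)) wr(bundle$signals_soc, "signals_soc.csv")
  if (!is.null(bundle$top_pt)) wr(bundle$top_pt, "top_pt.csv")
  if (!is.null(bundle$gender)) wr(bundle$gender, "gender_signals.csv")
  if (!is.null(bundle$volcano)) wr(bundle$volcano, "volcano.csv")
  wr(bundle$descriptive, "descriptive.csv")
  wr(bundle$annual, "annual_counts.csv")
  wr(bundle$sankey, "sankey_flows.csv")
  wr(cases_to_audit_table(bundle$cases), "cases_normalized.csv")
  if (!is.null(bundle$onset)) {
    wr(bundle$onset$bins, "tto_bins.csv")
    p <- file.path(out_dir, "tto_summary.json")
    jsonlite::write_json(
      bundle$onset[c("n_evaluable", "n_total", "pct_evaluable",
                     "median_days", "q1_days", "q3_days", "quantile_type")],
      p, auto_unbox = TRUE, digits = NA)
    files <- c(files, "tto_summary.json")
  }
  p <- file.path(out_dir, "manifest.json")
  manifest <- bundle$manifest
  manifest$files <- files
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  c(files, "manifest.json")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  %d case(s), %d target-drug case(s)\n",
              x$manifest$n_reports, x$manifest$n_target))
  if (!is.null(x$signals_pt)) {
    cat(sprintf("  PT terms scanned: %d; consensus signals: %d\n",
                nrow(x$signals_pt), sum(x$signals_pt$consensus)))
  }
  if (!is.null(x$onset)) {
    cat(sprintf("  onset: median %.0f d (IQR %.0f-%.0f), %.1f%% evaluable\n",
                x$onset$median_days, x$onset$q1_days, x$onset$q3_days,
                x$onset$pct_evaluable))
  }
  invisible(x)
}
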