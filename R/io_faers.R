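# FAERS quarterly ASCII ingestion: "$"-delimited tables keyed by primaryid
# (report version) and caseid (case). One case may appear as several report
# versions; deduplication keeps the current version per case.

.faers_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "wt", "wt_cod", "occp_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

.faers_mandatory <- list(
  demo = c("primaryid", "caseid"),
  drug = c("primaryid", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "start_dt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_pt")
)

#' Read one FAERS-dialect quarterly ASCII table
#'
#' Reads a "$"-delimited file with a header row. All fields are read as
#' character; downstream assembly performs typed normalization so that a
#' malformed value in one field never aborts the run. Pre-2012Q4 LAERS
#' column names (e.g. `ISR`, `CASE`) can be mapped via `aliases`.
#'
#' @param path file path.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`,
#'   `"indi"`.
#' @param aliases optional named character vector mapping dialect column
#'   names to the modern ones, e.g. `c(isr = "primaryid", case = "caseid")`.
#' @return A data.table with lower-case column names; a logged message
#'   reports the row count.
#' @export
read_faers_table <- function(path, kind = c("demo", "drug", "reac", "ther",
                                            "outc", "indi"),
                             aliases = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("FAERS table file not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "$", header = TRUE,
                          colClasses = "character", quote = "\"",
                          na.strings = c("", "NA"), showProgress = FALSE)
  data.table::setnames(dt, tolower(names(dt)))
  if (!is.null(aliases)) {
    have <- intersect(tolower(names(aliases)), names(dt))
    if (length(have)) {
      data.table::setnames(dt, have, unname(aliases[match(have, tolower(names(aliases)))]))
    }
  }
  missing_cols <- setdiff(.faers_mandatory[[kind]], names(dt))
  if (length(missing_cols)) {
    stop(sprintf("FAERS %s table %s lacks mandatory column(s): %s",
                 toupper(kind), path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  # carry only known columns; absent optional columns become NA
  for (col in setdiff(.faers_columns[[kind]], names(dt))) {
    dt[, (col) := NA_character_]
  }
  dt <- dt[, .SD, .SDcols = .faers_columns[[kind]]]
  message(sprintf("read_faers_table: %s %s -> %d rows", toupper(kind),
                  basename(path), nrow(dt)))
  dt[]
}

# age_cod units -> years; unknown codes -> NA
.age_to_years <- function(age, age_cod) {
  age_num <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25,
            HR = 1 / 8766)
  m <- unname(mult[cod])
  m[is.na(cod) & !is.na(age_num)] <- 1 # bare numeric age defaults to years
  yrs <- age_num * m
  yrs[!is.na(yrs) & yrs < 0] <- NA_real_
  yrs
}

.wt_to_kg <- function(wt, wt_cod) {
  wt_num <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(wt_cod))
  mult <- c(KG = 1, KGS = 1, LBS = 0.45359237, GMS = 0.001)
  m <- unname(mult[cod])
  m[is.na(cod) & !is.na(wt_num)] <- 1
  kg <- wt_num * m
  kg[!is.na(kg) & kg < 0] <- NA_real_
  kg
}

.normalize_sex <- function(x) {
  x <- toupper(trimws(x))
  data.table::fifelse(x %in% c("F", "M"), x, "unknown", na = "unknown")
}

#' Assemble case-level records from raw FAERS tables
#'
#' Joins the FAERS star schema on `primaryid`: demographics are normalized
#' (sex to F/M/unknown, age to years via `age_cod`, weight to kg via
#' `wt_cod`), therapy start dates are joined to drug rows via
#' `dsg_drug_seq = drug_seq`, and reactions become a set of PT strings per
#' report. Rows in child tables whose `primaryid` is absent from DEMO are
#' dropped with a logged count, as are DEMO rows with no reactions (a safety
#' report must carry at least one event term).
#'
#' @param tables named list with elements `demo`, `drug`, `reac` and
#'   optionally `ther`, `outc`, `indi`, each as returned by
#'   [read_faers_table()].
#' @return A `faers_cases` object: a list of data.tables `demo`, `drugs`,
#'   `reactions`, `outcomes`, `indications` plus a `log` of drop counters.
#' @export
assemble_cases <- function(tables) {
  stopifnot(all(c("demo", "drug", "reac") %in% names(tables)))
  demo <- data.table::as.data.table(tables$demo)
  drug <- data.table::as.data.table(tables$drug)
  reac <- data.table::as.data.table(tables$reac)
  ther <- if (!is.null(tables$ther)) data.table::as.data.table(tables$ther)
          else data.table::data.table(primaryid = character(),
                                      dsg_drug_seq = character(),
                                      start_dt = character())
  outc <- if (!is.null(tables$outc)) data.table::as.data.table(tables$outc)
          else data.table::data.table(primaryid = character(),
                                      outc_cod = character())
  indi <- if (!is.null(tables$indi)) data.table::as.data.table(tables$indi)
          else data.table::data.table(primaryid = character(),
                                      indi_drug_seq = character(),
                                      indi_pt = character())

  log <- list()
  ids <- unique(demo$primaryid)
  drop_orphans <- function(dt, what) {
    orphan <- !(dt$primaryid %in% ids)
    if (any(orphan)) {
      message(sprintf("assemble_cases: dropped %d orphan %s row(s)",
                      sum(orphan), what))
    }
    log[[paste0("orphan_", what)]] <<- sum(orphan)
    dt[!orphan]
  }
  drug <- drop_orphans(drug, "drug")
  reac <- drop_orphans(reac, "reac")
  ther <- drop_orphans(ther, "ther")
  outc <- drop_orphans(outc, "outc")
  indi <- drop_orphans(indi, "indi")

  demo_norm <- demo[, .(
    primaryid = primaryid,
    caseid = caseid,
    fda_dt = fda_dt,
    event_dt = event_dt,
    sex = .normalize_sex(sex),
    age_years = .age_to_years(age, age_cod),
    weight_kg = .wt_to_kg(wt, wt_cod),
    reporter = data.table::fifelse(is.na(occp_cod), "unknown",
                                   toupper(trimws(occp_cod))),
    country = data.table::fifelse(is.na(occr_country), "unknown",
                                  toupper(trimws(occr_country)))
  )]

  reactions <- unique(reac[!is.na(pt), .(primaryid, pt = trimws(pt))])
  has_reac <- demo_norm$primaryid %in% reactions$primaryid
  log$no_reaction <- sum(!has_reac)
  if (any(!has_reac)) {
    message(sprintf("assemble_cases: dropped %d report(s) with no reactions",
                    sum(!has_reac)))
  }
  demo_norm <- demo_norm[has_reac]
  keep_ids <- demo_norm$primaryid

  drugs <- drug[primaryid %in% keep_ids,
                .(primaryid, drug_seq, role_cod = toupper(trimws(role_cod)),
                  drugname, prod_ai)]
  ther2 <- ther[, .(primaryid, drug_seq = dsg_drug_seq, start_dt)]
  drugs <- ther2[drugs, on = c("primaryid", "drug_seq")]
  data.table::setcolorder(drugs, c("primaryid", "drug_seq", "role_cod",
                                   "drugname", "prod_ai", "start_dt"))

  obj <- list(
    demo = data.table::setorder(demo_norm, caseid, primaryid),
    drugs = data.table::setorder(drugs, primaryid, drug_seq),
    reactions = data.table::setorder(reactions[primaryid %in% keep_ids], primaryid, pt),
    outcomes = data.table::setorder(
      unique(outc[primaryid %in% keep_ids & !is.na(outc_cod),
                  .(primaryid, outc_cod = toupper(trimws(outc_cod)))]),
      primaryid, outc_cod),
    indications = data.table::setorder(
      unique(indi[primaryid %in% keep_ids & !is.na(indi_pt),
                  .(primaryid, indi_pt = trimws(indi_pt))]),
      primaryid, indi_pt),
    log = log
  )
  class(obj) <- "faers_cases"
  obj
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d report(s), %d distinct case id(s)\n",
              nrow(x$demo), data.table::uniqueN(x$demo$caseid)))
  cat(sprintf("  drugs: %d rows; reactions: %d rows; outcomes: %d rows\n",
              nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  invisible(x)
}

#' Number of reports in a case collection
#' @param cases a `faers_cases` object.
#' @return integer count of report rows.
#' @export
n_reports <- function(cases) nrow(cases$demo)

# subset a faers_cases object to a set of primaryids, preserving order rules
filter_cases <- function(cases, keep_ids) {
  obj <- list(
    demo = data.table::setorder(cases$demo[primaryid %in% keep_ids], caseid, primaryid),
    drugs = data.table::setorder(cases$drugs[primaryid %in% keep_ids], primaryid, drug_seq),
    reactions = data.table::setorder(cases$reactions[primaryid %in% keep_ids], primaryid, pt),
    outcomes = data.table::setorder(cases$outcomes[primaryid %in% keep_ids], primaryid, outc_cod),
    indications = data.table::setorder(cases$indications[primaryid %in% keep_ids], primaryid, indi_pt),
    log = cases$log
  )
  class(obj) <- "faers_cases"
  obj
}

#' Deduplicate case versions
#'
#' FAERS cases accumulate report versions; per FDA guidance the analysis
#' keeps, for each `caseid`, the version with the latest `fda_dt`, breaking
#' ties by the largest numeric `primaryid`. The result is ordered by
#' `caseid`, so the operation is deterministic and idempotent.
#'
#' @param cases a `faers_cases` object.
#' @return A `faers_cases` object with one report per `caseid`.
#' @export
deduplicate_cases <- function(cases) {
  demo <- cases$demo
  if (nrow(demo) == 0L) return(cases)
  key <- data.table::data.table(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    dkey = date_sort_key(demo$fda_dt),
    pkey = suppressWarnings(as.numeric(demo$primaryid))
  )
  key[is.na(pkey), pkey := -Inf]
  data.table::setorder(key, caseid, -dkey, -pkey)
  keep <- key[, head(.SD, 1L), by = caseid]$primaryid
  filter_cases(cases, keep)
}

#' Match the target drug in each report
#'
#' A report matches when at least one of its drug rows has a role code in
#' `roles` and a `drugname` or `prod_ai` that contains one of `names` as a
#' substring after lower-casing and whitespace normalization. Substring
#' matching reflects FAERS free-text drug names, which carry dose and
#' formulation suffixes.
#'
#' @param cases a `faers_cases` object.
#' @param names character vector of drug name patterns (non-empty).
#' @param roles role codes to accept; default `"PS"` (primary suspect).
#' @return Named logical vector, one element per report row of
#'   `cases$demo`, names being `primaryid`s.
#' @export
match_target_drug <- function(cases, names, roles = "PS") {
  stopifnot(length(names) >= 1L)
  norm <- function(x) gsub("[[:space:]]+", " ", trimws(tolower(x)))
  pat <- norm(names)
  drugs <- cases$drugs[role_cod %in% toupper(roles)]
  dn <- norm(drugs$drugname)
  ai <- norm(drugs$prod_ai)
  hit <- rep(FALSE, nrow(drugs))
  for (p in pat) {
    hit <- hit | grepl(p, dn, fixed = TRUE) |
      (!is.na(ai) & grepl(p, ai, fixed = TRUE))
  }
  matched_ids <- unique(drugs$primaryid[hit])
  stats::setNames(cases$demo$primaryid %in% matched_ids, cases$demo$primaryid)
}

#' Flatten a case collection to an audit table
#'
#' One row per (caseid, pt) with per-case demographics; the normalized form
#' written alongside pipeline outputs for audit.
#'
#' @param cases a `faers_cases` object (deduplicated).
#' @return data.table with caseid, primaryid, pt and demographic columns.
#' @export
cases_to_audit_table <- function(cases) {
  out <- merge(cases$reactions, cases$demo, by = "primaryid", sort = FALSE)
  data.table::setcolorder(out, c("caseid", "primaryid", "pt"))
  data.table::setorder(out, caseid, pt)[]
}

#' The four target drug-name patterns for albumin-bound paclitaxel
#'
#' Generic names and brand name under which albumin-bound (nab-)paclitaxel
#' appears in spontaneous reports; conventional paclitaxel does not match
#' any of them.
#'
#' @return character vector of length 4.
#' @export
nab_paclitaxel_names <- function() {
  c("paclitaxel for injection (albumin bound)",
    "paclitaxel protein-bound particles",
    "albumin-bound paclitaxel",
    "abraxane")
}
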