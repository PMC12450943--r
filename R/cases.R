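# Deduplication and field normalization: one analysable case per CASEID.

#' Deduplicate FAERS report versions into cases
#'
#' Applies the FDA-recommended rule: among report versions sharing a
#' `caseid`, keep the one with the most recent FDA receipt date (`fda_dt`);
#' on ties, keep the largest `primaryid`. Cases named in the quarterly
#' deletion lists are then removed. The operation is idempotent.
#'
#' Partial `fda_dt` values (month or year precision) are completed to the
#' first day of their period for ordering only; `event_dt` below day
#' precision becomes missing because time-to-onset needs day arithmetic.
#'
#' @param tables a `faers_tables` object (from [read_faers_tables()] or
#'   [generate_cohort()]), or a `faers_cases` object (then a no-op modulo
#'   re-derivation).
#' @param deletion_caseids optional character vector of caseids to remove in
#'   addition to any bundled `deleted` table.
#' @return a `faers_cases` object: list of data.frames `demo` (one row per
#'   caseid, with derived `fda_date`, `event_date`, `age_years`, `wt_kg`,
#'   `reporter`), `drug` (with `drug_norm`), `reac`, `ther`, `indi`, `outc`;
#'   attribute `log` records counts at each stage.
#' @export
deduplicate <- function(tables, deletion_caseids = NULL) {
  demo <- as.data.frame(tables$demo)
  .assert_cols(demo, c("primaryid", "caseid", "fda_dt"), "demo")
  n_versions <- nrow(demo)

  deletions <- unique(c(
    as.character(deletion_caseids),
    if (!is.null(tables$deleted)) as.character(tables$deleted$caseid)
  ))

  if (n_versions) {
    fda_date <- parse_faers_date(demo$fda_dt, partial = "complete")
    pid_num <- suppressWarnings(as.numeric(demo$primaryid))
    keep <- rep(FALSE, n_versions)
    ord <- order(demo$caseid, fda_date, pid_num, method = "radix")
    last_of_case <- !duplicated(demo$caseid[ord], fromLast = TRUE)
    keep[ord[last_of_case]] <- TRUE
    demo <- demo[keep, , drop = FALSE]
  }
  n_cases_predel <- nrow(demo)
  if (length(deletions)) demo <- demo[!(demo$caseid %in% deletions), , drop = FALSE]
  n_cases <- nrow(demo)

  demo <- .derive_demo_fields(demo)
  keep_pid <- demo$primaryid

  sub <- function(df) {
    df <- as.data.frame(df)
    if (!nrow(df)) return(df)
    df[df$primaryid %in% keep_pid, , drop = FALSE]
  }
  drug <- sub(tables$drug)
  if (nrow(drug) || !("drug_norm" %in% names(drug))) {
    drug$drug_norm <- normalize_drug_name(drug$drugname)
  }

  out <- list(
    demo = demo,
    drug = drug,
    reac = sub(tables$reac),
    ther = sub(tables$ther %||% .empty_faers_table("ther")),
    indi = sub(tables$indi %||% .empty_faers_table("indi")),
    outc = sub(tables$outc %||% .empty_faers_table("outc"))
  )
  structure(out, class = "faers_cases",
            log = list(n_versions = n_versions,
                       n_cases_before_deletion = n_cases_predel,
                       n_deleted = n_cases_predel - n_cases,
                       n_cases = n_cases))
}

.derive_demo_fields <- function(demo) {
  demo$fda_date <- parse_faers_date(demo$fda_dt, partial = "complete")
  demo$event_date <- parse_faers_date(demo$event_dt, partial = "na")
  demo$age_years <- normalize_age(suppressWarnings(as.numeric(demo$age)),
                                  demo$age_cod)
  demo$wt_kg <- suppressWarnings(as.numeric(demo$wt))
  sex <- toupper(trimws(demo$sex))
  demo$sex <- ifelse(sex %in% c("F", "M"), sex, "unknown")
  demo$reporter <- .reporter_label(demo$occp_cod)
  demo
}

.reporter_label <- function(occp_cod) {
  map <- c(MD = "physician", PH = "pharmacist",
           OT = "other health-professional", CN = "consumer", LW = "lawyer")
  lab <- map[toupper(trimws(occp_cod))]
  # already-normalized labels pass through (keeps deduplicate idempotent)
  lab[is.na(lab) & trimws(occp_cod) %in% map] <- trimws(occp_cod)[is.na(lab) & trimws(occp_cod) %in% map]
  lab[is.na(lab)] <- "unknown"
  unname(lab)
}

#' Convert FAERS age value/unit pairs to years
#'
#' Unit codes: `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY`
#' days, `HR` hours. An unrecognised unit is assumed to be years unless the
#' value exceeds 150, which is treated as missing; negative values become
#' missing with a warning.
#'
#' @param age_value numeric vector.
#' @param age_unit character vector of unit codes.
#' @return numeric vector of ages in years (`NA` where unresolvable).
#' @export
normalize_age <- function(age_value, age_unit) {
  age_value <- as.numeric(age_value)
  if (any(!is.na(age_value) & age_value < 0)) {
    warning("negative age values treated as missing")
    age_value[!is.na(age_value) & age_value < 0] <- NA_real_
  }
  factor_for <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1429,
                  DY = 1 / 365.25, HR = 1 / 8766)
  unit <- toupper(trimws(as.character(age_unit)))
  known <- !is.na(unit) & unit %in% names(factor_for)
  f <- rep(1, length(unit))        # unknown unit: assume years ...
  f[known] <- factor_for[unit[known]]
  out <- age_value * f
  # ... unless implausible under that assumption, then missing
  out[!known & !is.na(out) & out > 150] <- NA_real_
  out
}

#' Normalize a drug name to its canonical token
#'
#' Uppercases, trims, strips dosage/form suffixes (e.g. `"200 MG"`,
#' `"INJECTION"`), and collapses trade/generic synonyms through a lookup
#' table. Deliberately rule-based with no fuzzy matching, so that repeated
#' application is a fixed point and runs are reproducible.
#'
#' @param x character vector of raw drug names.
#' @param synonyms named character vector mapping alias to canonical name;
#'   defaults to [default_drug_synonyms()].
#' @return character vector of canonical tokens.
#' @export
normalize_drug_name <- function(x, synonyms = default_drug_synonyms()) {
  out <- toupper(trimws(as.character(x)))
  out <- gsub("\\s+", " ", out)
  # dosage and form suffixes
  out <- gsub("\\s*\\(.*\\)$", "", out)
  out <- gsub("\\s+[0-9.]+\\s*(MG|MCG|G|ML|MG/ML)(\\b.*)?$", "", out)
  out <- gsub("\\s+(INJECTION|INJ|SOLUTION|TABLET|TABLETS|CAPSULE|CAPSULES|PREFILLED SYRINGE)$", "", out)
  out <- trimws(out)
  hit <- !is.na(out) & out %in% names(synonyms)
  out[hit] <- unname(synonyms[out[hit]])
  out
}

#' Default trade-name to generic synonym table
#'
#' A small, static alias table for the drugs used in the bundled analyses;
#' extend by passing your own vector to [normalize_drug_name()].
#'
#' @return named character vector (alias -> canonical).
#' @export
default_drug_synonyms <- function() {
  c(KEVZARA = "SARILUMAB",
    RINVOQ = "UPADACITINIB",
    ORENCIA = "ABATACEPT",
    ACTEMRA = "TOCILIZUMAB",
    HUMIRA = "ADALIMUMAB",
    ENBREL = "ETANERCEPT",
    TREXALL = "METHOTREXATE",
    OTREXUP = "METHOTREXATE",
    XELJANZ = "TOFACITINIB",
    PLAQUENIL = "HYDROXYCHLOROQUINE",
    DELTASONE = "PREDNISONE")
}

#' Load a preferred-term to system-organ-class map
#'
#' Real MedDRA is licensed and cannot be redistributed; the bundled default
#' (`pt_soc_map_synthetic.csv`) is a small synthetic map with the same
#' interface: columns `pt`, `soc_name`, `soc_code`, one primary SOC per PT.
#'
#' @param path CSV path; `NULL` for the bundled synthetic map.
#' @return data.frame of class `pt_soc_map`.
#' @export
load_pt_soc_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pt_soc_map_synthetic.csv",
                                package = "faersignal", mustWork = TRUE)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(map, c("pt", "soc_name", "soc_code"), "pt_soc_map")
  if (!nrow(map)) stop("PT-to-SOC map is empty")
  if (anyDuplicated(map$pt)) stop("PT-to-SOC map assigns some PT more than one SOC")
  class(map) <- c("pt_soc_map", class(map))
  map
}

#' Annotate reaction records with their system organ class
#'
#' PTs found in the map gain `soc_name`/`soc_code`; unmapped PTs are kept at
#' PT level (SOC columns `NA`) and collected — never silently dropped — in
#' the `unmapped` attribute for the diagnostics report.
#'
#' @param reac data.frame of reaction records with column `pt`.
#' @param pt_soc_map a `pt_soc_map`, e.g. from [load_pt_soc_map()].
#' @return `reac` with `soc_name`, `soc_code` columns; attribute `unmapped`
#'   holds the unique unmapped PTs.
#' @export
map_pt_to_soc <- function(reac, pt_soc_map) {
  if (is.null(pt_soc_map) || !nrow(pt_soc_map)) stop("PT-to-SOC map is empty")
  reac <- as.data.frame(reac)
  pt_clean <- trimws(reac$pt)
  idx <- match(pt_clean, pt_soc_map$pt)
  reac$soc_name <- pt_soc_map$soc_name[idx]
  reac$soc_code <- pt_soc_map$soc_code[idx]
  unmapped <- sort(unique(pt_clean[is.na(idx) & nzchar(pt_clean)]))
  structure(reac, unmapped = unmapped)
}

#' Select the cases reporting a target drug
#'
#' Keeps cases with at least one drug entry whose normalized name matches
#' the target and whose role code is in `roles` (default: primary suspect
#' only, the conventional exposure definition for disproportionality).
#'
#' @param cases a `faers_cases` object.
#' @param drug target drug name (normalized internally, so trade names work).
#' @param roles drug role codes to accept, subset of `PS`, `SS`, `C`, `I`.
#' @return a `faers_cases` object restricted to the matching cases.
#' @export
select_target_reports <- function(cases, drug, roles = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  roles <- match.arg(roles, c("PS", "SS", "C", "I"), several.ok = TRUE)
  target <- normalize_drug_name(drug)
  hit <- cases$drug$drug_norm == target & cases$drug$role_cod %in% roles
  pids <- unique(cases$drug$primaryid[hit])
  if (!length(pids)) {
    warning(sprintf("no case reports drug '%s' with role(s) %s",
                    target, paste(roles, collapse = "/")))
  }
  subset_cases(cases, pids)
}

#' Restrict a case set to the given primaryids
#'
#' @param cases a `faers_cases` object.
#' @param primaryids character vector of report identifiers to keep.
#' @return a `faers_cases` object.
#' @export
subset_cases <- function(cases, primaryids) {
  out <- lapply(cases, function(df) df[df$primaryid %in% primaryids, , drop = FALSE])
  structure(out, class = "faers_cases",
            log = c(attr(cases, "log"), list(n_subset = nrow(out$demo))))
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d cases, %d drug rows, %d reaction rows\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac)))
  invisible(x)
}
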