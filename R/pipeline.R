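# Orchestration: overall, stratified and indication-restricted analyses.

#' Build a validated run configuration
#'
#' @param target_drug drug under surveillance (normalized internally).
#' @param roles exposure role codes (default primary suspect only).
#' @param strata stratification axes for [run_stratified()]; any of
#'   `"sex"`, `"age_group"`, `"reporter"`.
#' @param indication indication PT for the sensitivity analysis (default
#'   `"Rheumatoid arthritis"`).
#' @param co_drugs co-drug names for the interaction screen (empty = skip).
#' @param top_k rows kept in ranked PT tables (default 50).
#' @param ddi_top_k_events events per drug pair in the DDI screen.
#' @param min_stratum_cases strata with fewer target-drug cases are flagged
#'   sparse (default 20).
#' @param seed integer seed recorded in the run manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(target_drug, roles = "PS",
                       strata = c("sex", "age_group", "reporter"),
                       indication = "Rheumatoid arthritis",
                       co_drugs = character(0), top_k = 50L,
                       ddi_top_k_events = 10L,
                       min_stratum_cases = 20L, seed = NULL) {
  stopifnot(is.character(target_drug), length(target_drug) == 1L)
  strata <- match.arg(strata, several.ok = TRUE)
  structure(list(target_drug = normalize_drug_name(target_drug),
                 roles = roles, strata = strata, indication = indication,
                 co_drugs = co_drugs, top_k = as.integer(top_k),
                 ddi_top_k_events = as.integer(ddi_top_k_events),
                 min_stratum_cases = as.integer(min_stratum_cases),
                 seed = seed),
            class = "run_config")
}

.as_cases <- function(x, deletion_caseids = NULL) {
  if (inherits(x, "faers_cases")) x else deduplicate(x, deletion_caseids)
}

#' Run the overall signal analysis
#'
#' Deduplicates (if given raw tables), summarises demographics, scans for
#' disproportionality signals at PT and SOC level, models time-to-onset,
#' and (when co-drugs are configured) screens drug pairs for interaction
#' signals. Deterministic given inputs and config; the `log` element
#' records case counts at every stage.
#'
#' @param x a `faers_tables` or `faers_cases` object.
#' @param config a `run_config`.
#' @param pt_soc_map PT-to-SOC map (default: the bundled synthetic map).
#' @param outdir optional directory; when set, all outputs are written as
#'   CSV plus a JSON run manifest.
#' @return list of class `faers_run`: `demographic`, `signals_pt`,
#'   `signals_soc`, `tto` (records/bins/summary/fit/ecdf), `ddi`, `log`.
#' @export
run_overall <- function(x, config, pt_soc_map = load_pt_soc_map(),
                        outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cases <- .as_cases(x)
  if (!any(cases$drug$drug_norm == config$target_drug)) {
    close <- unique(cases$drug$drug_norm[substr(cases$drug$drug_norm, 1, 3) ==
                                           substr(config$target_drug, 1, 3)])
    stop(sprintf("target drug '%s' absent from the data%s", config$target_drug,
                 if (length(close)) paste0("; did you mean: ",
                                           paste(head(close, 5), collapse = ", "))
                 else ""))
  }
  target_cases <- select_target_reports(cases, config$target_drug, config$roles)

  tto <- compute_tto(cases, config$target_drug, config$roles)
  demographic <- demographic_summary(target_cases, tto)

  signals_pt <- signal_scan(cases, config$target_drug, "pt", pt_soc_map,
                            config$roles)
  signals_soc <- signal_scan(cases, config$target_drug, "soc", pt_soc_map,
                             config$roles)

  tto_out <- list(records = tto, exclusions = attr(tto, "exclusions"))
  if (nrow(tto)) {
    tto_out$bins <- bin_tto(tto)
    tto_out$summary <- tto_summary(tto)
    tto_out$ecdf <- cumulative_incidence(tto)
    if (nrow(tto) >= 10 && length(unique(tto$tto_days)) >= 2) {
      tto_out$fit <- fit_weibull(tto)
    }
  }

  ddi <- if (length(config$co_drugs)) {
    detect_ddi(cases, config$target_drug, config$co_drugs,
               config$ddi_top_k_events)
  } else NULL

  res <- structure(
    list(demographic = demographic,
         signals_pt = signals_pt, signals_soc = signals_soc,
         tto = tto_out, ddi = ddi, config = config,
         log = c(attr(cases, "log"),
                 list(n_target_cases = nrow(target_cases$demo),
                      n_target_event_pairs = sum(signals_pt$a),
                      n_tto_known = attr(tto, "exclusions")$n_known,
                      n_pt_terms = nrow(signals_pt),
                      n_positive_pt = sum(signals_pt$positive),
                      n_soc_terms = nrow(signals_soc),
                      n_positive_soc = sum(signals_soc$positive)))),
    class = "faers_run")
  if (!is.null(outdir)) write_run_outputs(res, outdir)
  res
}

#' Run stratified disproportionality analyses
#'
#' Strata: sex (male, female), age group (18-44, 45-64, >=65; under-18 and
#' unknown excluded), reporter type (healthcare professional = physician +
#' other health-professional, consumer, pharmacist; unknown excluded). The
#' 2x2 background within each stratum is restricted to that stratum's
#' reports. Strata with fewer target-drug cases than
#' `config$min_stratum_cases` are flagged `sparse`; strata with none yield
#' an empty table with a warning, never an error.
#'
#' @inheritParams run_overall
#' @return named list of signals data.frames (one per stratum level), each
#'   with attributes `n_cases`, `n_target_cases`, `sparse`.
#' @export
run_stratified <- function(x, config, pt_soc_map = load_pt_soc_map()) {
  stopifnot(inherits(config, "run_config"))
  cases <- .as_cases(x)
  demo <- cases$demo
  strata <- list()
  if ("sex" %in% config$strata) {
    strata[["sex:female"]] <- demo$primaryid[demo$sex == "F"]
    strata[["sex:male"]] <- demo$primaryid[demo$sex == "M"]
  }
  if ("age_group" %in% config$strata) {
    ay <- demo$age_years
    strata[["age:18-44"]] <- demo$primaryid[!is.na(ay) & ay >= 18 & ay < 45]
    strata[["age:45-64"]] <- demo$primaryid[!is.na(ay) & ay >= 45 & ay < 65]
    strata[["age:>=65"]] <- demo$primaryid[!is.na(ay) & ay >= 65]
  }
  if ("reporter" %in% config$strata) {
    strata[["reporter:healthcare professional"]] <-
      demo$primaryid[demo$reporter %in% c("physician", "other health-professional")]
    strata[["reporter:consumer"]] <- demo$primaryid[demo$reporter == "consumer"]
    strata[["reporter:pharmacist"]] <- demo$primaryid[demo$reporter == "pharmacist"]
  }
  out <- list()
  for (nm in names(strata)) {
    sub <- subset_cases(cases, strata[[nm]])
    n_sub <- nrow(sub$demo)
    n_target <- length(unique(
      sub$drug$primaryid[sub$drug$drug_norm == config$target_drug &
                           sub$drug$role_cod %in% config$roles]))
    tab <- if (n_sub == 0L || n_target == 0L) {
      warning(sprintf("stratum '%s' has no target-drug reports; emitting empty table", nm))
      signals <- signal_scan(cases, config$target_drug, "pt", pt_soc_map,
                             config$roles)
      signals[0, , drop = FALSE]
    } else {
      signal_scan(sub, config$target_drug, "pt", pt_soc_map, config$roles)
    }
    attr(tab, "n_cases") <- n_sub
    attr(tab, "n_target_cases") <- n_target
    attr(tab, "sparse") <- n_target < config$min_stratum_cases
    out[[nm]] <- tab
  }
  out
}

#' Indication-restricted sensitivity analysis
#'
#' Repeats the PT-level signal scan and onset summary on the subset of
#' reports where the target drug's recorded indication matches
#' `config$indication`, and emits a comparison against the overall
#' analysis: positive-PT counts, overlap, per-PT ROR deltas, and onset
#' medians in both sets.
#'
#' @inheritParams run_overall
#' @return list: `signals_pt` (restricted), `tto_summary` (restricted),
#'   `comparison` (list with counts and a per-PT delta table), `n_cases`.
#' @export
run_indication_sensitivity <- function(x, config,
                                       pt_soc_map = load_pt_soc_map()) {
  stopifnot(inherits(config, "run_config"))
  cases <- .as_cases(x)
  # indication rows tied to the target drug's entries on each report
  dr <- cases$drug[cases$drug$drug_norm == config$target_drug, , drop = FALSE]
  key_dr <- paste(dr$primaryid, dr$drug_seq, sep = "\r")
  ind <- cases$indi
  key_ind <- paste(ind$primaryid, ind$indi_drug_seq, sep = "\r")
  hit <- key_ind %in% key_dr & trimws(ind$indi_pt) == config$indication
  pids_target_ind <- unique(ind$primaryid[hit])
  if (!length(pids_target_ind)) {
    stop(sprintf("indication filter '%s' matches no report", config$indication))
  }
  # keep the full background minus target-drug reports with other indications
  pids_target <- unique(cases$drug$primaryid[cases$drug$drug_norm == config$target_drug])
  keep <- setdiff(cases$demo$primaryid, setdiff(pids_target, pids_target_ind))
  sub <- subset_cases(cases, keep)

  signals_sub <- signal_scan(sub, config$target_drug, "pt", pt_soc_map,
                             config$roles)
  signals_all <- signal_scan(cases, config$target_drug, "pt", pt_soc_map,
                             config$roles)
  tto_sub <- compute_tto(sub, config$target_drug, config$roles)
  tto_all <- compute_tto(cases, config$target_drug, config$roles)

  merged <- merge(signals_all[c("term", "a", "ror", "positive")],
                  signals_sub[c("term", "a", "ror", "positive")],
                  by = "term", suffixes = c("_overall", "_restricted"),
                  all = TRUE)
  merged$ror_delta <- merged$ror_restricted - merged$ror_overall
  pos_all <- signals_all$term[signals_all$positive]
  pos_sub <- signals_sub$term[signals_sub$positive]
  comparison <- list(
    n_positive_overall = length(pos_all),
    n_positive_restricted = length(pos_sub),
    n_positive_overlap = length(intersect(pos_all, pos_sub)),
    tto_median_overall = if (nrow(tto_all)) median(tto_all$tto_days) else NA_real_,
    tto_median_restricted = if (nrow(tto_sub)) median(tto_sub$tto_days) else NA_real_,
    per_pt = merged)
  list(signals_pt = signals_sub,
       tto_summary = if (nrow(tto_sub)) tto_summary(tto_sub) else NULL,
       comparison = comparison,
       n_cases = nrow(sub$demo),
       n_target_cases = length(pids_target_ind))
}

#' Write the outputs of an overall run to disk
#'
#' Emits CSV tables (written even when empty, with headers) and a JSON run
#' manifest with the stage counts, configuration echo and seed.
#'
#' @param res a `faers_run` from [run_overall()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_run_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(res$demographic, "demographic_summary.csv")
  wr(res$signals_pt, "signals_pt.csv")
  wr(res$signals_soc, "signals_soc.csv")
  if (!is.null(res$tto$records)) wr(res$tto$records, "tto_records.csv")
  if (!is.null(res$tto$bins)) wr(res$tto$bins, "tto_bins.csv")
  if (!is.null(res$tto$ecdf)) wr(res$tto$ecdf, "tto_ecdf.csv")
  if (!is.null(res$ddi)) wr(res$ddi, "ddi_signals.csv")
  manifest <- list(log = res$log,
                   config = unclass(res$config),
                   weibull = if (!is.null(res$tto$fit)) unclass(res$tto$fit))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, file.path(outdir, "run_manifest.json")))
}

#' @export
print.faers_run <- function(x, ...) {
  cat(sprintf("<faers_run> target %s: %d cases (%d target), %d PT terms (%d positive), %d SOC terms\n",
              x$config$target_drug, x$log$n_cases %||% NA,
              x$log$n_target_cases, x$log$n_pt_terms, x$log$n_positive_pt,
              x$log$n_soc_terms))
  invisible(x)
}
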