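# Synthetic FAERS-shaped cohorts with a ground-truth manifest: injected
# disproportionality signals, drug-pair interaction effects, duplicate
# report versions, deletion lists, demographics and Weibull onset times.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the reporting environment the bundled analyses assume:
#' demographics, report years, outcome frequencies and the known-onset
#' fraction follow the published characteristics of a real biologic's
#' spontaneous-report cohort (75.60% female, physician-majority reporters,
#' 2017-2025 reporting window, ~13% of reports with day-resolution onset),
#' and onset times follow a Weibull with shape 0.60 and scale 161.14 days —
#' an early-failure profile. Reporting-rate multipliers default to 1
#' everywhere (a null cohort); inject signals via `signal_injections` /
#' `ddi_injections`.
#'
#' @param n_cases number of true (deduplicated) cases.
#' @param seed integer seed; mandatory, every run is a pure function of the
#'   config.
#' @param drugs data.frame (`name`, `p_use`) of the drug catalog; the first
#'   row is the target drug, always reported as primary suspect.
#' @param events data.frame (`pt`, `p_base`) of the event catalog with
#'   per-report baseline probabilities.
#' @param signal_injections data.frame (`drug`, `event`, `multiplier`) of
#'   reporting-rate multipliers applied when the case carries the drug.
#' @param ddi_injections data.frame (`drug_a`, `drug_b`, `event`,
#'   `multiplier`) applied when the case carries both drugs.
#' @param sex_probs,reporter_probs,year_probs,age_group_probs named
#'   probability vectors for the demographic samplers.
#' @param outcome_probs named per-report probabilities of each outcome code.
#' @param tto list: `shape`, `scale` (days) of the onset distribution and
#'   `p_known`, the fraction of target-drug cases given day-resolution
#'   start and event dates.
#' @param p_indication_ra probability that a target-drug case carries
#'   "Rheumatoid arthritis" as the indication.
#' @param duplicate_rate fraction of cases given 1-3 extra report versions.
#' @param deletion_rate fraction of cases added to the deletion list.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 20000L,
                          seed,
                          drugs = default_drug_catalog(),
                          events = default_event_catalog(),
                          signal_injections = NULL,
                          ddi_injections = NULL,
                          sex_probs = c(F = 0.7560, M = 0.1590, unknown = 0.0850),
                          age_group_probs = c("<18" = 0.0009, "18-44" = 0.0847,
                                              "45-64" = 0.3707, ">=65" = 0.2000,
                                              unknown = 0.3437),
                          reporter_probs = c(MD = 0.5423, CN = 0.3759,
                                             PH = 0.0676, OT = 0.0131,
                                             LW = 0.0001, unknown = 0.0010),
                          year_probs = c("2017" = 0.0064, "2018" = 0.0608,
                                         "2019" = 0.1068, "2020" = 0.1011,
                                         "2021" = 0.1269, "2022" = 0.1550,
                                         "2023" = 0.1469, "2024" = 0.2162,
                                         "2025" = 0.0799),
                          outcome_probs = c(LT = 0.0124, HO = 0.0876,
                                            DS = 0.0288, DE = 0.0174,
                                            CA = 0.0017, RI = 0.0003,
                                            OT = 0.2214),
                          tto = list(shape = 0.60, scale = 161.14,
                                     p_known = 1951 / 14940),
                          p_indication_ra = 0.8,
                          duplicate_rate = 0.1,
                          deletion_rate = 0.02) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  cfg <- list(n_cases = as.integer(n_cases), seed = as.integer(seed),
              drugs = drugs, events = events,
              signal_injections = signal_injections,
              ddi_injections = ddi_injections,
              sex_probs = sex_probs, age_group_probs = age_group_probs,
              reporter_probs = reporter_probs, year_probs = year_probs,
              outcome_probs = outcome_probs, tto = tto,
              p_indication_ra = p_indication_ra,
              duplicate_rate = duplicate_rate, deletion_rate = deletion_rate)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_cases > 0,
            all(cfg$drugs$p_use > 0 & cfg$drugs$p_use <= 1),
            all(cfg$events$p_base > 0 & cfg$events$p_base <= 1),
            cfg$tto$shape > 0, cfg$tto$scale > 0,
            cfg$tto$p_known >= 0, cfg$tto$p_known <= 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1,
            cfg$deletion_rate >= 0, cfg$deletion_rate < 1)
  for (inj in list(cfg$signal_injections, cfg$ddi_injections)) {
    if (is.null(inj)) next
    stopifnot(all(inj$multiplier > 0))
    p <- cfg$events$p_base[match(inj$event, cfg$events$pt)]
    if (anyNA(p)) stop("injection references an event absent from the catalog")
    if (any(p * inj$multiplier > 1)) {
      stop("infeasible injection: baseline probability x multiplier exceeds 1")
    }
  }
  invisible(cfg)
}

#' Default drug catalog for synthetic cohorts
#'
#' The first row (`SARILUMAB`) is the target drug; the rest are plausible
#' rheumatology co-medications and background drugs with marginal use
#' probabilities.
#' @return data.frame (`name`, `p_use`).
#' @export
default_drug_catalog <- function() {
  data.frame(
    name = c("SARILUMAB", "METHOTREXATE", "UPADACITINIB", "ABATACEPT",
             "TOCILIZUMAB", "ADALIMUMAB", "PREDNISONE", "IBUPROFEN"),
    p_use = c(0.10, 0.18, 0.05, 0.05, 0.06, 0.10, 0.15, 0.20),
    stringsAsFactors = FALSE)
}

#' Default event catalog for synthetic cohorts
#'
#' Twenty PTs drawn from the bundled PT-to-SOC map with baseline per-report
#' probabilities spanning common to rare events.
#' @return data.frame (`pt`, `p_base`).
#' @export
default_event_catalog <- function() {
  data.frame(
    pt = c("Drug ineffective", "Pain", "Arthralgia", "Rheumatoid arthritis",
           "Joint swelling", "Injection site erythema", "Injection site rash",
           "Nausea", "Headache", "Fatigue", "Alopecia", "Nasopharyngitis",
           "COVID-19", "Pneumonia", "Neutropenia",
           "White blood cell count decreased", "Hepatic enzyme increased",
           "Malaise", "Dizziness", "Anaphylactic reaction"),
    p_base = c(0.10, 0.09, 0.06, 0.03, 0.03, 0.02, 0.015,
               0.05, 0.06, 0.04, 0.01, 0.02,
               0.015, 0.012, 0.006, 0.008, 0.01,
               0.02, 0.03, 0.003),
    stringsAsFactors = FALSE)
}

#' Generate a FAERS-shaped synthetic cohort
#'
#' Samples demographics, drug sets (independent Bernoulli per catalog drug,
#' at least one drug per case), and events (independent Bernoulli per event
#' given the case's drugs: baseline times any applicable injected
#' multipliers, at least one reaction per case). Target-drug cases selected
#' for known onset get day-resolution therapy start and event dates with
#' the onset interval drawn from the configured Weibull and rounded to
#' whole days. Duplicate versions and a deletion list are then layered on
#' per the config. Fully reproducible from the seed.
#'
#' @param config a `cohort_config`.
#' @return list with `tables` (a `faers_tables` object, duplicates and
#'   deletion list included) and `manifest` (a `ground_truth_manifest`:
#'   true case count, per drug-event and pair-event realized counts,
#'   injections, deletion caseids).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_cases
  drugs <- config$drugs
  events <- config$events
  k <- nrow(drugs); m <- nrow(events)
  target <- drugs$name[1]

  caseid <- sprintf("%07d", seq_len(n) + 1000000L)

  # --- drug sets: independent Bernoulli, at least one drug per case
  use <- matrix(runif(n * k) < rep(drugs$p_use, each = n), n, k)
  none <- !rowSums(use)
  if (any(none)) {
    use[cbind(which(none), sample.int(k, sum(none), replace = TRUE,
                                      prob = drugs$p_use))] <- TRUE
  }
  colnames(use) <- drugs$name

  # --- event probabilities: baseline x injected multipliers
  p <- matrix(rep(events$p_base, each = n), n, m)
  colnames(p) <- events$pt
  si <- config$signal_injections
  if (!is.null(si)) {
    for (i in seq_len(nrow(si))) {
      rows <- use[, si$drug[i]]
      p[rows, si$event[i]] <- p[rows, si$event[i]] * si$multiplier[i]
    }
  }
  di <- config$ddi_injections
  if (!is.null(di)) {
    for (i in seq_len(nrow(di))) {
      rows <- use[, di$drug_a[i]] & use[, di$drug_b[i]]
      p[rows, di$event[i]] <- p[rows, di$event[i]] * di$multiplier[i]
    }
  }
  if (any(p > 1)) stop("infeasible injection: event probability exceeds 1")
  # every report carries >=1 reaction: redraw event vectors for empty rows
  # (rejection sampling keeps each case's relative event rates intact)
  ev <- matrix(runif(n * m) < p, n, m)
  none_ev <- which(!rowSums(ev))
  while (length(none_ev)) {
    redraw <- matrix(runif(length(none_ev) * m), length(none_ev), m) <
      p[none_ev, , drop = FALSE]
    ev[none_ev, ] <- redraw
    none_ev <- none_ev[!rowSums(redraw)]
  }
  colnames(ev) <- events$pt

  # --- demographics
  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  sex[sex == "unknown"] <- ""
  agegrp <- sample(names(config$age_group_probs), n, TRUE, config$age_group_probs)
  age <- rep(NA_real_, n)
  age[agegrp == "<18"] <- round(runif(sum(agegrp == "<18"), 2, 17))
  age[agegrp == "18-44"] <- round(runif(sum(agegrp == "18-44"), 18, 44))
  age[agegrp == "45-64"] <- round(runif(sum(agegrp == "45-64"), 45, 64))
  age[agegrp == ">=65"] <- round(runif(sum(agegrp == ">=65"), 65, 92))
  occp <- sample(names(config$reporter_probs), n, TRUE, config$reporter_probs)
  occp[occp == "unknown"] <- ""
  year <- as.integer(sample(names(config$year_probs), n, TRUE, config$year_probs))
  fda_date <- as.Date(sprintf("%d-01-01", year)) +
    floor(runif(n) * ifelse(year == 2025, 90, 365))
  wt <- ifelse(runif(n) < 0.097, pmax(1, round(stats::rnorm(n, 82.9, 27.14), 1)),
               NA_real_)
  country <- sample(c("US", "CA", "GB", "FR", "JP"), n, TRUE,
                    c(0.9162, 0.0138, 0.03, 0.02, 0.02))

  # --- onset dates for target-drug cases
  has_target <- use[, 1]
  known <- has_target & runif(n) < config$tto$p_known
  tto_days <- rep(NA_integer_, n)
  tto_days[known] <- as.integer(round(
    rweibull(sum(known), config$tto$shape, config$tto$scale)))
  start_date <- rep(as.Date(NA), n)
  start_date[known] <- fda_date[known] - tto_days[known] -
    floor(runif(sum(known)) * 30)
  event_date <- start_date + tto_days
  event_dt <- character(n)
  event_dt[known] <- format(event_date[known], "%Y%m%d")
  # a slice of the remainder gets month-precision onset: unusable for TTO
  partial <- !known & runif(n) < 0.25
  event_dt[partial] <- format(fda_date[partial], "%Y%m")

  demo <- data.frame(
    primaryid = paste0(caseid, "09"), caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"), event_dt = event_dt,
    sex = sex, age = ifelse(is.na(age), "", as.character(age)),
    age_cod = ifelse(is.na(age), "", "YR"),
    wt = ifelse(is.na(wt), "", as.character(wt)),
    occp_cod = occp, reporter_country = country,
    stringsAsFactors = FALSE)

  # --- drug table: target is always primary suspect; otherwise the first
  # listed drug on the report is; other drugs get SS/C/I roles
  drug_idx <- which(use, arr.ind = TRUE)
  drug_idx <- drug_idx[order(drug_idx[, 1], drug_idx[, 2]), , drop = FALSE]
  row_case <- drug_idx[, 1]
  row_drug <- drug_idx[, 2]
  seq_in_case <- sequence(rle(row_case)$lengths)
  role <- sample(c("SS", "C", "I"), length(row_case), TRUE, c(0.3, 0.5, 0.2))
  is_ps <- ifelse(has_target[row_case], row_drug == 1L, seq_in_case == 1L)
  role[is_ps] <- "PS"
  drug_tab <- data.frame(
    primaryid = demo$primaryid[row_case], caseid = caseid[row_case],
    drug_seq = as.character(seq_in_case), role_cod = role,
    drugname = drugs$name[row_drug], stringsAsFactors = FALSE)

  # --- reactions
  ev_idx <- which(ev, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  reac_tab <- data.frame(
    primaryid = demo$primaryid[ev_idx[, 1]], caseid = caseid[ev_idx[, 1]],
    pt = events$pt[ev_idx[, 2]], stringsAsFactors = FALSE)

  # --- therapy starts for the target drug (known-onset cases only)
  t_rows <- which(is_ps & has_target[row_case] & known[row_case])
  ther_tab <- data.frame(
    primaryid = demo$primaryid[row_case[t_rows]],
    caseid = caseid[row_case[t_rows]],
    dsg_drug_seq = as.character(seq_in_case[t_rows]),
    start_dt = format(start_date[row_case[t_rows]], "%Y%m%d"),
    stringsAsFactors = FALSE)

  # --- indications for the target drug
  i_rows <- which(row_drug == 1L)
  indi_tab <- data.frame(
    primaryid = demo$primaryid[row_case[i_rows]],
    caseid = caseid[row_case[i_rows]],
    indi_drug_seq = as.character(seq_in_case[i_rows]),
    indi_pt = ifelse(runif(length(i_rows)) < config$p_indication_ra,
                     "Rheumatoid arthritis", "Psoriatic arthropathy"),
    stringsAsFactors = FALSE)

  # --- outcomes
  oc <- names(config$outcome_probs)
  om <- matrix(runif(n * length(oc)) < rep(config$outcome_probs, each = n),
               n, length(oc))
  oi <- which(om, arr.ind = TRUE)
  oi <- oi[order(oi[, 1], oi[, 2]), , drop = FALSE]
  outc_tab <- data.frame(
    primaryid = demo$primaryid[oi[, 1]], caseid = caseid[oi[, 1]],
    outc_cod = oc[oi[, 2]], stringsAsFactors = FALSE)

  tables <- structure(list(demo = demo, drug = drug_tab, reac = reac_tab,
                           ther = ther_tab, indi = indi_tab, outc = outc_tab,
                           deleted = .empty_faers_table("deleted")),
                      class = "faers_tables")

  # --- ground truth bookkeeping
  de <- expand.grid(drug = drugs$name, event = events$pt,
                    stringsAsFactors = FALSE)
  de$n_reports <- mapply(function(dg, evn) sum(use[, dg] & ev[, evn]),
                         de$drug, de$event)
  pe <- expand.grid(drug_b = drugs$name[-1], event = events$pt,
                    stringsAsFactors = FALSE)
  pe$drug_a <- target
  pe$n11 <- mapply(function(dg, evn) sum(use[, 1] & use[, dg] & ev[, evn]),
                   pe$drug_b, pe$event)
  manifest <- structure(
    list(seed = config$seed, n_true_cases = n,
         n_target_cases = sum(has_target),
         n_tto_known = sum(known),
         drug_event_counts = de,
         pair_event_counts = pe[, c("drug_a", "drug_b", "event", "n11")],
         signal_injections = config$signal_injections,
         ddi_injections = config$ddi_injections,
         deletion_caseids = character(0)),
    class = "ground_truth_manifest")

  out <- inject_duplicates_and_deletions(
    list(tables = tables, manifest = manifest), config)
  out
}

#' Layer duplicate report versions and a deletion list onto a cohort
#'
#' A `duplicate_rate` fraction of cases receive 1-3 extra versions whose
#' `primaryid` is always smaller than the original's and whose `fda_dt` is
#' earlier (or, for a third of duplicates, tied — exercising the
#' largest-primaryid tie-break). A `deletion_rate` fraction of caseids is
#' written to the deletion list. [deduplicate()] must return exactly the
#' original cases minus deletions.
#'
#' @param cohort list with `tables` and `manifest` as from
#'   [generate_cohort()].
#' @param config the `cohort_config` (rates and seed context are read from
#'   it; the RNG stream continues from the caller).
#' @return the cohort with updated `tables` and `manifest`.
#' @export
inject_duplicates_and_deletions <- function(cohort, config) {
  tables <- cohort$tables
  manifest <- cohort$manifest
  demo <- tables$demo
  n <- nrow(demo)

  if (config$duplicate_rate > 0 && n > 0) {
    dup_case <- which(runif(n) < config$duplicate_rate)
    dup_rows <- list()
    for (i in dup_case) {
      for (v in seq_len(sample(3L, 1L))) {
        row <- demo[i, , drop = FALSE]
        row$primaryid <- paste0(row$caseid, sprintf("%02d", v))  # < "09"
        tied <- runif(1) < 1 / 3
        if (!tied) {
          d <- as.Date(row$fda_dt, "%Y%m%d") - sample(90L, 1L)
          row$fda_dt <- format(d, "%Y%m%d")
        }
        dup_rows[[length(dup_rows) + 1L]] <- row
      }
    }
    if (length(dup_rows)) {
      extra <- do.call(rbind, dup_rows)
      tables$demo <- rbind(demo, extra)
      # duplicate versions carry their own copies of the detail rows
      for (tb in c("drug", "reac", "ther", "indi", "outc")) {
        df <- tables[[tb]]
        orig_pid <- paste0(extra$caseid, "09")
        idx <- match(df$primaryid, orig_pid)
        copies <- df[!is.na(idx), , drop = FALSE]
        if (nrow(copies)) {
          copies$primaryid <- extra$primaryid[idx[!is.na(idx)]]
          tables[[tb]] <- rbind(df, copies)
        }
      }
      manifest$n_duplicate_versions <- nrow(extra)
    }
  }

  if (config$deletion_rate > 0 && n > 0) {
    del <- sort(sample(demo$caseid, round(config$deletion_rate * n)))
    tables$deleted <- data.frame(caseid = del, stringsAsFactors = FALSE)
    manifest$deletion_caseids <- del
  }
  manifest$n_expected_after_dedup <-
    manifest$n_true_cases - length(manifest$deletion_caseids)
  list(tables = tables, manifest = manifest)
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat(sprintf("<ground_truth_manifest> %d true cases (%d target-drug, %d with known onset), %d deletions\n",
              x$n_true_cases, x$n_target_cases, x$n_tto_known,
              length(x$deletion_caseids)))
  invisible(x)
}
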