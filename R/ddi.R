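# Drug-drug interaction screening with the Omega shrinkage measure.
#
# For a drug pair and event: N11 = reports with both drugs and the event,
# E11 = (N1. x N.1)/N the two-margin independence expectation, where N1. is
# the reports with both drugs, N.1 the reports with the event, and N all
# reports in scope. Omega = log2((N11 + alpha)/(E11 + alpha)).

#' Count co-reports for a drug pair and event
#'
#' The target drug is matched as primary suspect; the co-drug in any role
#' (co-medications are usually not the suspect drug, so role-restricting the
#' co-drug would discard most co-reports). Counting is report-level.
#'
#' @param cases a `faers_cases` object (deduplicated).
#' @param drug_a target drug (primary suspect).
#' @param drug_b co-reported drug (any role).
#' @param event_pt MedDRA preferred term.
#' @return object of class `pair_event_counts`: `n11`, `n1dot`, `ndot1`,
#'   `n_total` plus the pair/event labels.
#' @export
pair_counts <- function(cases, drug_a, drug_b, event_pt) {
  stopifnot(inherits(cases, "faers_cases"))
  a_norm <- normalize_drug_name(drug_a)
  b_norm <- normalize_drug_name(drug_b)
  with_a <- unique(cases$drug$primaryid[cases$drug$drug_norm == a_norm &
                                          cases$drug$role_cod == "PS"])
  with_b <- unique(cases$drug$primaryid[cases$drug$drug_norm == b_norm])
  both <- intersect(with_a, with_b)
  with_ev <- unique(cases$reac$primaryid[trimws(cases$reac$pt) == event_pt])
  structure(list(drug_a = a_norm, drug_b = b_norm, event_pt = event_pt,
                 n11 = length(intersect(both, with_ev)),
                 n1dot = length(both),
                 ndot1 = length(with_ev),
                 n_total = nrow(cases$demo)),
            class = "pair_event_counts")
}

#' Omega shrinkage statistic for a drug-pair x event
#'
#' `omega = log2((N11 + alpha)/(E11 + alpha))` with
#' `E11 = N1. x N.1 / N` and shrinkage constant `alpha` (0.5 by
#' convention); the 95% interval is `omega -/+ 1.96 * SE` with
#' `SE = 1/(ln 2 * sqrt(N11))`. The signal is significant when the lower
#' bound exceeds zero. With `N11 = 0` the point estimate is still computed
#' but the interval is undefined and the signal cannot be significant.
#'
#' @param counts a `pair_event_counts` (or list with `n11`, `n1dot`,
#'   `ndot1`, `n_total`).
#' @param alpha shrinkage constant (default 0.5).
#' @return one-row data.frame of class `ddi_result`: pair/event labels,
#'   `n11`, `e11`, `omega`, `omega_lo`, `omega_hi`, `significant`.
#' @export
omega_statistic <- function(counts, alpha = 0.5) {
  stopifnot(counts$n_total > 0, alpha >= 0)
  e11 <- counts$n1dot * counts$ndot1 / counts$n_total
  omega <- log2((counts$n11 + alpha) / (e11 + alpha))
  if (counts$n11 > 0) {
    half <- 1.96 * omega_se(counts$n11)
    lo <- omega - half
    hi <- omega + half
  } else {
    lo <- hi <- NA_real_
  }
  out <- data.frame(drug_a = counts$drug_a %||% NA_character_,
                    drug_b = counts$drug_b %||% NA_character_,
                    event_pt = counts$event_pt %||% NA_character_,
                    n11 = counts$n11, e11 = e11, alpha = alpha,
                    omega = omega, omega_lo = lo, omega_hi = hi,
                    significant = !is.na(lo) && lo > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("ddi_result", class(out))
  out
}

#' Standard error of the Omega statistic
#'
#' `SE = 1/(ln 2 * sqrt(N11))` on the log2 scale.
#'
#' @param n11 co-report count (positive).
#' @return numeric standard error.
#' @export
omega_se <- function(n11) {
  stopifnot(all(n11 > 0))
  1 / (log(2) * sqrt(n11))
}

#' Screen co-drugs for interaction signals with a target drug
#'
#' For each co-drug, evaluates the Omega statistic on its `top_k_events`
#' most frequently co-reported PTs. No minimum co-report count is imposed —
#' all results are emitted with `n11` attached so that sparse pairs can be
#' read as exploratory.
#'
#' @param cases a `faers_cases` object.
#' @param drug_a target drug (primary suspect).
#' @param co_drugs character vector of co-drug names.
#' @param top_k_events events per pair to evaluate (default 10).
#' @param alpha shrinkage constant (default 0.5).
#' @return data.frame of `ddi_result` rows (empty for pairs never
#'   co-reported), ordered by pair then descending `n11`.
#' @export
detect_ddi <- function(cases, drug_a, co_drugs, top_k_events = 10L,
                       alpha = 0.5) {
  res <- list()
  for (b in co_drugs) {
    b_norm <- normalize_drug_name(b)
    a_norm <- normalize_drug_name(drug_a)
    with_a <- unique(cases$drug$primaryid[cases$drug$drug_norm == a_norm &
                                            cases$drug$role_cod == "PS"])
    with_b <- unique(cases$drug$primaryid[cases$drug$drug_norm == b_norm])
    both <- intersect(with_a, with_b)
    if (!length(both)) next
    co_pts <- table(trimws(cases$reac$pt[cases$reac$primaryid %in% both]))
    co_pts <- co_pts[order(-as.integer(co_pts), names(co_pts))]
    for (pt in head(names(co_pts), top_k_events)) {
      res[[length(res) + 1L]] <-
        omega_statistic(pair_counts(cases, drug_a, b, pt), alpha = alpha)
    }
  }
  if (!length(res)) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      event_pt = character(0), n11 = integer(0),
                      e11 = numeric(0), alpha = numeric(0),
                      omega = numeric(0), omega_lo = numeric(0),
                      omega_hi = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
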