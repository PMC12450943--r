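# Drug-event 2x2 contingency tables and the four disproportionality
# statistics (ROR, PRR/MHRA, BCPNN-style IC, MGPS-style EBGM).
#
# Layout of the 2x2, counted at report level within the current stratum:
#                target event   other events
#   target drug       a              b
#   other drugs       c              d

#' Build a drug-event 2x2 contingency table
#'
#' A report contributes to `a` (or `c`) if at least one of its reactions
#' matches the event — a PT repeated on one report still counts once. At SOC
#' level a report counts once per SOC even when several of its PTs share it.
#' All four cells are computed from the reports in `cases`, so passing a
#' stratum's cases yields the stratum-restricted background.
#'
#' @param cases a `faers_cases` object (deduplicated; possibly a stratum).
#' @param drug target drug name.
#' @param event a PT (when `level = "pt"`) or SOC name (`level = "soc"`).
#' @param level counting level, `"pt"` or `"soc"`.
#' @param stratum label recorded on the table (default `"overall"`).
#' @param roles drug role codes defining exposure (default `"PS"`).
#' @param pt_soc_map needed for `level = "soc"` unless `cases$reac` already
#'   carries a `soc_name` column.
#' @return object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n`, `drug`, `event`, `level`, `stratum`.
#' @export
build_contingency <- function(cases, drug, event, level = c("pt", "soc"),
                              stratum = "overall", roles = "PS",
                              pt_soc_map = NULL) {
  level <- match.arg(level)
  n <- nrow(cases$demo)
  if (n == 0L) stop("empty stratum: no reports to tabulate")
  target <- normalize_drug_name(drug)
  exposed <- unique(cases$drug$primaryid[cases$drug$drug_norm == target &
                                           cases$drug$role_cod %in% roles])
  reac <- cases$reac
  if (level == "soc" && !("soc_name" %in% names(reac))) {
    if (is.null(pt_soc_map)) stop("SOC-level table needs 'pt_soc_map' or pre-annotated reactions")
    reac <- map_pt_to_soc(reac, pt_soc_map)
  }
  term <- if (level == "pt") trimws(reac$pt) else reac$soc_name
  with_event <- unique(reac$primaryid[!is.na(term) & term == event])
  a <- sum(with_event %in% exposed)
  b <- length(exposed) - a
  c_ <- length(with_event) - a
  d <- n - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d, n = n,
                 drug = target, event = event, level = level,
                 stratum = stratum),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table> %s x %s (%s, %s): a=%d b=%d c=%d d=%d N=%d\n",
              x$drug, x$event, x$level, x$stratum, x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

.as_cells <- function(t) {
  if (inherits(t, "contingency_table")) {
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  } else if (is.list(t) && all(c("a", "b", "c", "d") %in% names(t))) {
    t[c("a", "b", "c", "d")]
  } else {
    stop("expected a contingency_table or a list with cells a, b, c, d")
  }
}

# vectorized core: all four statistics from cell vectors.
# Haldane-Anscombe 0.5 correction on all four cells feeds the ROR/PRR
# intervals whenever any of b, c, d is zero; point estimates stay on raw
# counts where defined.
.disprop <- function(a, b, c, d) {
  # doubles throughout: cell products overflow 32-bit integers at FAERS scale
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  zero <- b == 0 | c == 0 | d == 0
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- c + 0.5 * zero; d2 <- d + 0.5 * zero

  ror <- (a * d) / (b * c)
  se_ror <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ror_ci <- (a2 * d2) / (b2 * c2)
  ror_lo <- exp(log(ror_ci) - 1.96 * se_ror)
  ror_hi <- exp(log(ror_ci) + 1.96 * se_ror)

  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  prr_ci <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  prr_lo <- exp(log(prr_ci) - 1.96 * se_prr)
  prr_hi <- exp(log(prr_ci) + 1.96 * se_prr)
  # infinite PRR (c = 0) is reported without an interval
  prr_lo[c == 0] <- NA_real_
  prr_hi[c == 0] <- NA_real_

  num <- a * d - b * c
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- n * num^2 / denom
  chi2_yates <- n * pmax(0, abs(num) - n / 2)^2 / denom

  # shared expected count E = (a+b)(a+c)/N, so ic == log2(ebgm) exactly
  ebgm <- a * n / ((a + b) * (a + c))
  ebgm05 <- exp(log(ebgm) - 1.645 * sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  ic <- log2(ebgm)
  se_ic <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)) / log(2)
  ic025 <- ic - 1.96 * se_ic

  data.frame(a = a, n = n, ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
             prr = prr, prr_lo = prr_lo, prr_hi = prr_hi,
             chi2 = chi2, chi2_yates = chi2_yates,
             ic = ic, ic025 = ic025, ebgm = ebgm, ebgm05 = ebgm05,
             zero_corrected = zero)
}

.flags <- function(s) {
  ok <- function(x) !is.na(x) & is.finite(x)
  flag_ror <- s$a >= 3 & ok(s$ror_lo) & s$ror_lo > 1
  flag_prr <- s$a >= 3 & ok(s$prr) & s$prr >= 2 & ok(s$chi2_yates) & s$chi2_yates >= 4
  flag_bcpnn <- ok(s$ic025) & s$ic025 > 0
  flag_mgps <- s$a >= 3 & ok(s$ebgm05) & s$ebgm05 > 2
  cbind(s,
        data.frame(flag_ror = flag_ror, flag_prr_mhra = flag_prr,
                   flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
                   positive = flag_ror | flag_prr | flag_bcpnn | flag_mgps))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ror = (a d)/(b c)`; the interval is `exp(log ror -/+ 1.96 se)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. When any of `b`, `c`, `d` is zero the
#' Haldane-Anscombe 0.5 correction (all four cells) is used for the interval
#' (and the point estimate, which is otherwise undefined), with a message.
#'
#' @param t a `contingency_table` (or list with `a`,`b`,`c`,`d`).
#' @param zero_cell `"haldane"` (default) or `"error"` to refuse zero cells.
#' @return named numeric vector `c(ror, lo, hi)`.
#' @export
ror_stat <- function(t, zero_cell = c("haldane", "error")) {
  zero_cell <- match.arg(zero_cell)
  cl <- .as_cells(t)
  if (cl$b * cl$c == 0 || cl$d == 0) {
    if (zero_cell == "error") {
      stop("zero cell in 2x2 table; use zero_cell = \"haldane\" for the continuity-corrected interval")
    }
    message("ror_stat: zero cell, applying Haldane-Anscombe 0.5 correction")
  }
  s <- .disprop(cl$a, cl$b, cl$c, cl$d)
  ror <- if (cl$b * cl$c == 0) (cl$a + 0.5) * (cl$d + 0.5) / ((cl$b + 0.5) * (cl$c + 0.5)) else s$ror
  c(ror = ror, lo = s$ror_lo, hi = s$ror_hi)
}

#' Proportional reporting ratio, interval and chi-squared statistics
#'
#' `prr = (a/(a+b)) / (c/(c+d))`; interval on the log scale with
#' `se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Returns both the uncorrected
#' Pearson chi-squared of the 2x2 and the Yates continuity-corrected value;
#' the MHRA composite rule consumes the corrected one. A zero `c` gives an
#' infinite PRR with no interval.
#'
#' @inheritParams ror_stat
#' @return named numeric vector `c(prr, lo, hi, chi2, chi2_yates)`.
#' @export
prr_chi2 <- function(t) {
  cl <- .as_cells(t)
  if ((cl$a + cl$b) == 0 || (cl$c + cl$d) == 0) stop("PRR undefined: empty table margin")
  s <- .disprop(cl$a, cl$b, cl$c, cl$d)
  c(prr = s$prr, lo = s$prr_lo, hi = s$prr_hi,
    chi2 = s$chi2, chi2_yates = s$chi2_yates)
}

#' Information component (BCPNN-style observed/expected form)
#'
#' `ic = log2(a / E)` with expected count `E = (a+b)(a+c)/N`, the same
#' baseline as the EBGM, so `ic == log2(ebgm)` identically. `ic025` is the
#' delta-method lower bound on the log2 scale.
#'
#' @inheritParams ror_stat
#' @return named numeric vector `c(ic, ic025)`.
#' @export
bcpnn_ic <- function(t) {
  cl <- .as_cells(t)
  if (cl$a <= 0) stop("information component undefined for a = 0")
  e <- (cl$a + cl$b) * (cl$a + cl$c) / (cl$a + cl$b + cl$c + cl$d)
  if (e == 0) stop("expected count is zero")
  s <- .disprop(cl$a, cl$b, cl$c, cl$d)
  c(ic = s$ic, ic025 = s$ic025)
}

#' Empirical Bayes geometric mean (MGPS-style relative reporting ratio form)
#'
#' `ebgm = a N / ((a+b)(a+c))` — the relative reporting ratio against the
#' two-margin expected count — with `ebgm05` the one-sided 5% lower bound
#' `exp(log ebgm - 1.645 sqrt(1/a + 1/b + 1/c + 1/d))`. The full DuMouchel
#' gamma-mixture shrinkage is an extension point, not implemented here.
#'
#' @inheritParams ror_stat
#' @return named numeric vector `c(ebgm, ebgm05)`.
#' @export
mgps_ebgm <- function(t) {
  cl <- .as_cells(t)
  if (cl$a <= 0) stop("EBGM undefined for a = 0")
  s <- .disprop(cl$a, cl$b, cl$c, cl$d)
  c(ebgm = s$ebgm, ebgm05 = s$ebgm05)
}

#' Evaluate all four disproportionality algorithms on one 2x2 table
#'
#' Positivity rules: ROR — `n >= 3` and `ror_lo > 1`; PRR (MHRA composite) —
#' `n >= 3`, `prr >= 2`, Yates chi-squared `>= 4`; BCPNN — `ic025 > 0`;
#' MGPS — `n >= 3` and `ebgm05 > 2`. The overall `positive` flag is the OR
#' of the four: a pair is a signal when at least one algorithm fires.
#'
#' @inheritParams ror_stat
#' @return one-row data.frame of class `signal_result` with the statistics,
#'   per-algorithm flags, and `positive`.
#' @export
evaluate_signal <- function(t) {
  cl <- .as_cells(t)
  s <- .flags(.disprop(cl$a, cl$b, cl$c, cl$d))
  if (inherits(t, "contingency_table")) {
    s <- cbind(data.frame(drug = t$drug, event = t$event, level = t$level,
                          stratum = t$stratum), s)
  }
  class(s) <- c("signal_result", class(s))
  s
}

#' Scan every event for disproportionality against a target drug
#'
#' Builds all drug-event 2x2 tables at once (PT or SOC level) and returns a
#' signals table mirroring the conventional output layout: term, case
#' count, ROR/PRR with intervals, both chi-squared forms, IC (IC025),
#' EBGM (EBGM05), per-algorithm flags and the any-method `positive` flag.
#'
#' @param cases a `faers_cases` object (deduplicated; possibly a stratum).
#' @param drug target drug name.
#' @param level `"pt"` or `"soc"`.
#' @param pt_soc_map PT-to-SOC map; required for SOC level, and used at PT
#'   level to annotate each PT's SOC when supplied.
#' @param roles exposure role codes (default `"PS"`).
#' @param min_n drop terms with `a < min_n` from the output (default 1).
#' @return data.frame, one row per event term, sorted by descending `a`.
#' @export
signal_scan <- function(cases, drug, level = c("pt", "soc"),
                        pt_soc_map = NULL, roles = "PS", min_n = 1L) {
  level <- match.arg(level)
  n <- nrow(cases$demo)
  if (n == 0L) stop("empty stratum: no reports to tabulate")
  target <- normalize_drug_name(drug)
  exposed <- unique(cases$drug$primaryid[cases$drug$drug_norm == target &
                                           cases$drug$role_cod %in% roles])
  reac <- cases$reac
  if (!is.null(pt_soc_map) && !("soc_name" %in% names(reac))) {
    reac <- map_pt_to_soc(reac, pt_soc_map)
  }
  if (level == "soc") {
    if (!("soc_name" %in% names(reac))) stop("SOC-level scan needs 'pt_soc_map'")
    pairs <- unique(data.frame(primaryid = reac$primaryid,
                               term = reac$soc_name,
                               soc_name = reac$soc_name,
                               soc_code = reac$soc_code))
  } else {
    soc_name <- if ("soc_name" %in% names(reac)) reac$soc_name else NA_character_
    soc_code <- if ("soc_code" %in% names(reac)) reac$soc_code else NA
    pairs <- unique(data.frame(primaryid = reac$primaryid,
                               term = trimws(reac$pt),
                               soc_name = soc_name, soc_code = soc_code))
  }
  pairs <- pairs[!is.na(pairs$term) & nzchar(pairs$term), , drop = FALSE]
  if (!nrow(pairs)) {
    return(cbind(data.frame(term = character(0), soc_name = character(0),
                            soc_code = integer(0)),
                 .flags(.disprop(integer(0), integer(0), integer(0), integer(0)))))
  }
  n_event <- table(pairs$term)
  a_tab <- table(pairs$term[pairs$primaryid %in% exposed])
  terms <- names(n_event)
  a <- as.integer(a_tab[terms]); a[is.na(a)] <- 0L
  ev <- as.integer(n_event)
  b <- length(exposed) - a
  c_ <- ev - a
  d <- n - a - b - c_
  soc_idx <- match(terms, pairs$term)
  out <- cbind(data.frame(term = terms,
                          soc_name = pairs$soc_name[soc_idx],
                          soc_code = pairs$soc_code[soc_idx],
                          stringsAsFactors = FALSE),
               .flags(.disprop(a, b, c_, d)))
  out <- out[out$a >= min_n, , drop = FALSE]
  out <- out[.order_desc_then_name(out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank a signals table by frequency or signal strength
#'
#' Stable descending sort by the chosen key with ties broken
#' alphabetically by term, truncated to the top `k`.
#'
#' @param results data.frame from [signal_scan()].
#' @param by `"frequency"` (case count `a`) or `"ror"`.
#' @param k number of rows to keep (default 50).
#' @return the ranked, truncated data.frame.
#' @export
rank_signals <- function(results, by = c("frequency", "ror"), k = 50L) {
  by <- match.arg(by)
  key <- if (by == "frequency") results$a else results$ror
  key[!is.finite(key)] <- -Inf
  out <- results[.order_desc_then_name(key, results$term), , drop = FALSE]
  rownames(out) <- NULL
  head(out, k)
}
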