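# Time-to-onset: event date minus earliest target-drug start date, onset
# binning, Weibull maximum likelihood, and hazard ("failure") typing.

.tto_bin_breaks <- c(-0.5, 30.5, 60.5, 90.5, 120.5, 150.5, 180.5, 360.5, Inf)
.tto_bin_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                     "151-180", "181-360", ">360")

#' Compute time-to-onset for a target drug
#'
#' TTO is the whole-day interval from the earliest start date of the target
#' drug's therapy records to the report's event date. Both dates must have
#' day precision; reports with a missing date or a negative interval are
#' excluded and tallied as "missing or outlier" (the exclusion count is kept
#' in the `exclusions` attribute).
#'
#' @param cases a `faers_cases` object.
#' @param drug target drug name.
#' @param roles exposure role codes (default `"PS"`).
#' @return data.frame (`caseid`, `primaryid`, `tto_days`) of usable records;
#'   attribute `exclusions` is a list with `n_reports`, `n_known`,
#'   `n_missing_or_outlier`.
#' @export
compute_tto <- function(cases, drug, roles = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  target <- normalize_drug_name(drug)
  demo <- cases$demo
  dr <- cases$drug[cases$drug$drug_norm == target &
                     cases$drug$role_cod %in% roles, , drop = FALSE]
  th <- cases$ther
  key_dr <- paste(dr$primaryid, dr$drug_seq, sep = "\r")
  key_th <- paste(th$primaryid, th$dsg_drug_seq, sep = "\r")
  th <- th[key_th %in% key_dr, , drop = FALSE]
  th$start_date <- parse_faers_date(th$start_dt, partial = "na")
  th <- th[!is.na(th$start_date), , drop = FALSE]
  start <- if (nrow(th)) {
    tapply(th$start_date, th$primaryid, min)
  } else {
    numeric(0)
  }
  start_date <- as.Date(as.numeric(start[demo$primaryid]),
                        origin = "1970-01-01")
  tto <- as.integer(demo$event_date - start_date)
  ok <- !is.na(tto) & tto >= 0
  out <- data.frame(caseid = demo$caseid[ok], primaryid = demo$primaryid[ok],
                    tto_days = tto[ok], stringsAsFactors = FALSE)
  structure(out,
            exclusions = list(n_reports = nrow(demo), n_known = sum(ok),
                              n_missing_or_outlier = nrow(demo) - sum(ok)))
}

#' Bin time-to-onset into the conventional onset windows
#'
#' Bins are closed integer ranges 0-30, 31-60, 61-90, 91-120, 121-150,
#' 151-180, 181-360 and >360 days. Percentages are reported against two
#' denominators: the TTO-known records, and (when `n_total` is given) all
#' reports including those with unknown onset.
#'
#' @param records data.frame from [compute_tto()], or a numeric vector of
#'   onset days.
#' @param n_total optional all-reports denominator; defaults to the
#'   `exclusions` attribute of `records` when present.
#' @return data.frame (`bin`, `n`, `pct_tto_known`, `pct_all_reports`).
#' @export
bin_tto <- function(records, n_total = NULL) {
  tto <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  if (!length(tto)) stop("no time-to-onset records to bin")
  if (is.null(n_total)) {
    excl <- attr(records, "exclusions")
    n_total <- if (!is.null(excl)) excl$n_reports else NA_integer_
  }
  bin <- cut(tto, breaks = .tto_bin_breaks, labels = .tto_bin_labels)
  n <- as.integer(table(bin))
  data.frame(bin = .tto_bin_labels, n = n,
             pct_tto_known = 100 * n / length(tto),
             pct_all_reports = if (is.na(n_total)) NA_real_ else 100 * n / n_total)
}

#' Numeric summary of onset times
#'
#' @param records as in [bin_tto()].
#' @return one-row data.frame: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
tto_summary <- function(records) {
  tto <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  q <- quantile(tto, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = length(tto), mean = mean(tto), sd = sd(tto),
             median = q[2], q1 = q[1], q3 = q[3],
             min = min(tto), max = max(tto))
}

#' Fit a two-parameter Weibull distribution to onset times
#'
#' Maximum likelihood on the log-parameter scale (Nelder-Mead), with 95%
#' confidence intervals from the inverse observed information by the delta
#' method. Zero-day onsets (same-day events are legitimate data) are shifted
#' to 0.5 day for the likelihood only — the Weibull density is singular at 0
#' when the shape is below 1 — while reported records keep their zeros.
#'
#' @param records as in [bin_tto()]; needs `n >= 10` with at least two
#'   distinct values.
#' @param conf confidence level for the intervals (default 0.95).
#' @return object of class `weibull_fit`: `shape`, `scale` (days), their
#'   CIs, `n`, `loglik`, and the `failure_type` from [classify_failure()].
#' @export
fit_weibull <- function(records, conf = 0.95) {
  x <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  x <- x[!is.na(x)]
  if (length(x) < 10L) stop("need at least 10 onset records to fit")
  if (length(unique(x)) < 2L) stop("degenerate sample: all onset values identical")
  if (any(x < 0)) stop("negative onset times must be excluded upstream")
  x[x == 0] <- 0.5
  nll <- function(p) -sum(dweibull(x, shape = exp(p[1]), scale = exp(p[2]),
                                   log = TRUE))
  init <- c(0, log(mean(x)))
  opt <- optim(init, nll, method = "Nelder-Mead", hessian = TRUE,
               control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) stop("Weibull likelihood optimisation did not converge")
  se <- sqrt(diag(solve(opt$hessian)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  est <- exp(opt$par)
  ci <- rbind(shape = exp(opt$par[1] + c(-1, 1) * z * se[1]),
              scale = exp(opt$par[2] + c(-1, 1) * z * se[2]))
  fit <- structure(list(shape = est[1], scale = est[2],
                        shape_ci = unname(ci["shape", ]),
                        scale_ci = unname(ci["scale", ]),
                        n = length(x), conf = conf,
                        loglik = -opt$value),
                   class = "weibull_fit")
  fit$failure_type <- classify_failure(fit)
  fit
}

#' Classify the hazard ("failure") type from a Weibull shape CI
#'
#' Shape below 1 means a decreasing hazard — early failure, the pattern of
#' adverse events concentrated shortly after drug start; above 1 an
#' increasing hazard (wear-out); a CI containing 1 is indistinguishable from
#' a constant hazard (random failure, the exponential special case).
#'
#' @param fit a `weibull_fit`, or a length-2 numeric shape CI.
#' @return one of `"early"`, `"random"`, `"wear-out"`.
#' @export
classify_failure <- function(fit) {
  ci <- if (inherits(fit, "weibull_fit")) fit$shape_ci else as.numeric(fit)
  stopifnot(length(ci) == 2L, all(is.finite(ci)), ci[1] <= ci[2])
  if (ci[2] < 1) "early" else if (ci[1] > 1) "wear-out" else "random"
}

#' Median of a fitted Weibull distribution
#'
#' Closed form `scale * log(2)^(1/shape)`.
#'
#' @param fit a `weibull_fit` (or numeric `c(shape, scale)`).
#' @return median onset time in days.
#' @export
weibull_median <- function(fit) {
  p <- if (inherits(fit, "weibull_fit")) c(fit$shape, fit$scale) else as.numeric(fit)
  p[2] * log(2)^(1 / p[1])
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d): shape %.3f (%.3f-%.3f), scale %.2f (%.2f-%.2f) days; %s failure\n",
              x$n, x$shape, x$shape_ci[1], x$shape_ci[2],
              x$scale, x$scale_ci[1], x$scale_ci[2], x$failure_type))
  invisible(x)
}

#' Empirical cumulative incidence of onset
#'
#' Right-continuous empirical CDF over days; the final value is 1.
#'
#' @param records as in [bin_tto()].
#' @return data.frame (`day`, `cum_frac`), one row per distinct onset day.
#' @export
cumulative_incidence <- function(records) {
  tto <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  if (!length(tto)) stop("no time-to-onset records")
  days <- sort(unique(tto))
  data.frame(day = days, cum_frac = ecdf(tto)(days))
}
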