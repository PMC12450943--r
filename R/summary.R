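# Table-1-style cohort description.

#' Demographic and clinical summary of a case set
#'
#' Counts and percentages (against the total case count) by sex, age group,
#' report year, reporter type and outcome code, plus onset-time bins when
#' TTO records are supplied. Categories with zero cases are retained so the
#' row schema is fixed. Numeric summaries (age, weight, onset days) are in
#' the `numeric_summaries` attribute.
#'
#' @param cases a `faers_cases` object (deduplicated).
#' @param tto_records optional output of [compute_tto()]; adds the onset
#'   bins (percentages against all cases) and the missing-or-outlier row.
#' @return data.frame (`characteristic`, `level`, `n`, `pct`).
#' @export
demographic_summary <- function(cases, tto_records = NULL) {
  demo <- cases$demo
  n_total <- nrow(demo)
  count_levels <- function(x, levels) {
    n <- vapply(levels, function(l) sum(x == l, na.rm = TRUE), integer(1))
    n
  }
  rows <- list()
  add <- function(characteristic, levels, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, level = levels, n = as.integer(n),
      pct = if (n_total) 100 * n / n_total else 0,
      stringsAsFactors = FALSE)
  }

  sex <- demo$sex
  add("sex", c("Female", "Male", "Not specified"),
      c(sum(sex == "F"), sum(sex == "M"), sum(!sex %in% c("F", "M"))))

  ag <- cut(demo$age_years, c(-Inf, 18, 45, 65, Inf), right = FALSE,
            labels = c("<18", "18-44", "45-64", ">=65"))
  add("age_group", c("<18", "18-44", "45-64", ">=65", "Not specified"),
      c(count_levels(as.character(ag), c("<18", "18-44", "45-64", ">=65")),
        sum(is.na(ag))))

  yr <- format(demo$fda_date, "%Y")
  yr_levels <- sort(unique(yr[!is.na(yr)]))
  add("report_year", yr_levels, count_levels(yr, yr_levels))

  rep_levels <- c("consumer", "lawyer", "other health-professional",
                  "pharmacist", "physician", "unknown")
  add("reporter", rep_levels, count_levels(demo$reporter, rep_levels))

  oc_levels <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  oc <- unique(cases$outc[c("primaryid", "outc_cod")])
  add("outcome", oc_levels, count_levels(oc$outc_cod, oc_levels))

  if (!is.null(tto_records)) {
    bins <- bin_tto(tto_records, n_total = n_total)
    add("tto_days", bins$bin, bins$n)
    excl <- attr(tto_records, "exclusions")
    add("tto_days", "Missing or outlier",
        if (!is.null(excl)) excl$n_missing_or_outlier
        else n_total - nrow(tto_records))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  num <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(n = 0L, missing = n_total, mean = NA_real_,
                        sd = NA_real_, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, min = NA_real_, max = NA_real_))
    }
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(x), missing = n_total - length(x),
               mean = mean(x), sd = sd(x), median = q[2], q1 = q[1],
               q3 = q[3], min = min(x), max = max(x))
  }
  ns <- list(age_years = num(demo$age_years), weight_kg = num(demo$wt_kg))
  if (!is.null(tto_records)) ns$tto_days <- num(tto_records$tto_days)
  attr(out, "numeric_summaries") <- ns
  out
}
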