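# shared helpers: FAERS date handling, small utilities

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse FAERS-style date fields
#'
#' FAERS dates are digit strings: `YYYYMMDD` (day precision), `YYYYMM`
#' (month precision) or `YYYY` (year precision). Partial dates can either be
#' completed to the first day of their period (useful only for *ordering*,
#' e.g. deduplication by FDA receipt date) or treated as missing (required
#' for day-resolution arithmetic such as time-to-onset).
#'
#' @param x character vector of raw date fields.
#' @param partial `"complete"` to fill partial dates to the first of the
#'   month/year, `"na"` to drop anything below day precision.
#' @return a `Date` vector; unparseable entries are `NA`.
#' @export
parse_faers_date <- function(x, partial = c("complete", "na")) {
  partial <- match.arg(partial)
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)] <- NA_character_
  n <- nchar(x)
  if (partial == "complete") {
    x[!is.na(n) & n == 4L] <- paste0(x[!is.na(n) & n == 4L], "0101")
    x[!is.na(n) & n == 6L] <- paste0(x[!is.na(n) & n == 6L], "01")
  } else {
    x[!is.na(n) & n < 8L] <- NA_character_
  }
  out <- as.Date(x, format = "%Y%m%d")
  out
}

# strict non-negative integer-like string (PRIMARYID etc.)
.is_idlike <- function(x) grepl("^[0-9]+$", trimws(as.character(x)))

.assert_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# stable alphabetical tie-break ordering used by rank_signals()
.order_desc_then_name <- function(key, name) order(-key, name, method = "radix")
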