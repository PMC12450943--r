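# FAERS quarterly ASCII dialect: first line is a header of column names,
# fields are "$"-delimited, one record per line, no quoting.

.faers_required_cols <- list(
  demo    = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
              "age_cod", "wt", "occp_cod", "reporter_country"),
  drug    = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac    = c("primaryid", "caseid", "pt"),
  ther    = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  indi    = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  outc    = c("primaryid", "caseid", "outc_cod"),
  deleted = "caseid"
)

#' Read a set of FAERS-shaped quarterly ASCII tables
#'
#' Reads the dollar-delimited FAERS tables named by `paths`. Table roles are
#' selected by explicit path configuration, never guessed from filenames.
#' All fields are kept as character so that a write/read round trip
#' preserves records exactly; typed columns (dates, numeric age) are derived
#' later by [deduplicate()].
#'
#' Rows of DEMO whose mandatory keys (`primaryid`, `caseid`) are empty or
#' non-numeric are rejected, counted, and kept in the `rejected` attribute —
#' never silently dropped.
#'
#' @param paths named list or character vector of file paths; names must be
#'   among `demo`, `drug`, `reac`, `ther`, `indi`, `outc`, `deleted`.
#'   `demo`, `drug` and `reac` are mandatory.
#' @return an object of class `faers_tables`: a list with one data.frame per
#'   role supplied (absent optional roles become empty tables), plus
#'   attributes `rejected` (data.frame of rejected DEMO rows) and
#'   `n_rejected`.
#' @export
read_faers_tables <- function(paths) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("'paths' must be a named list of table-role = file entries")
  }
  bad <- setdiff(names(paths), names(.faers_required_cols))
  if (length(bad)) {
    stop("unknown table role(s): ", paste(bad, collapse = ", "))
  }
  for (role in c("demo", "drug", "reac")) {
    if (is.null(paths[[role]])) stop("missing mandatory table: ", role)
  }
  tables <- list()
  for (role in names(.faers_required_cols)) {
    p <- paths[[role]]
    if (is.null(p)) {
      tables[[role]] <- .empty_faers_table(role)
      next
    }
    if (!file.exists(p)) stop(sprintf("file for table '%s' not found: %s", role, p))
    header <- readLines(p, n = 1L)
    cols <- strsplit(tolower(header), "$", fixed = TRUE)[[1]]
    need <- .faers_required_cols[[role]]
    if (!all(need %in% cols)) {
      stop(sprintf("malformed header for table '%s' (missing %s): \"%s\"",
                   role, paste(setdiff(need, cols), collapse = ", "), header))
    }
    dt <- data.table::fread(p, sep = "$", colClasses = "character",
                            quote = "", header = TRUE, data.table = FALSE,
                            na.strings = NULL)
    names(dt) <- tolower(names(dt))
    tables[[role]] <- dt
  }

  demo <- tables$demo
  ok <- .is_idlike(demo$primaryid) & .is_idlike(demo$caseid)
  rejected <- demo[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    message(sprintf("read_faers_tables: rejected %d DEMO row(s) with unparseable primaryid/caseid",
                    nrow(rejected)))
  }
  tables$demo <- demo[ok, , drop = FALSE]

  structure(tables,
            class = "faers_tables",
            rejected = rejected,
            n_rejected = nrow(rejected))
}

.empty_faers_table <- function(role) {
  cols <- .faers_required_cols[[role]]
  as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}

#' Write FAERS-shaped tables in the quarterly ASCII dialect
#'
#' Emits one dollar-delimited file per table role (`<role>.txt`) with a
#' header line. The dialect has no quoting mechanism, so any field value
#' containing the `$` delimiter is a hard error.
#'
#' @param tables a `faers_tables` object or plain named list of data.frames
#'   keyed by role.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_faers_ascii <- function(tables, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  roles <- intersect(names(.faers_required_cols), names(tables))
  files <- character(0)
  for (role in roles) {
    df <- as.data.frame(tables[[role]])
    has_dollar <- vapply(df, function(col) any(grepl("$", col, fixed = TRUE)),
                         logical(1))
    if (any(has_dollar) || any(grepl("$", names(df), fixed = TRUE))) {
      stop(sprintf("table '%s' contains the '$' delimiter in column(s): %s; the FAERS ASCII dialect has no quoting",
                   role, paste(names(df)[has_dollar], collapse = ", ")))
    }
    path <- file.path(dir, paste0(role, ".txt"))
    data.table::fwrite(df, path, sep = "$", quote = FALSE, col.names = TRUE)
    files[[role]] <- path
  }
  invisible(files)
}
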