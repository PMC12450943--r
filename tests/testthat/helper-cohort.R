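# Builders for small in-code fixtures.

# demo table with FAERS-dialect columns; any field overridable
make_demo <- function(n, caseid = sprintf("c%04d", seq_len(n)),
                      primaryid = paste0(caseid, "09"),
                      fda_dt = "20240101", event_dt = "", sex = "F",
                      age = "", age_cod = "", wt = "", occp_cod = "MD",
                      reporter_country = "US") {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, sex = sex, age = age, age_cod = age_cod,
             wt = wt, occp_cod = occp_cod,
             reporter_country = reporter_country, stringsAsFactors = FALSE)
}

# faers_cases from compact per-case drug/reaction specs:
# drugs: list of character vectors "NAME:ROLE"; pts: list of PT vectors
toy_cases <- function(drugs, pts, demo = NULL, start_dt = NULL) {
  n <- length(drugs)
  stopifnot(length(pts) == n)
  if (is.null(demo)) demo <- make_demo(n)
  drug_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    parts <- strsplit(drugs[[i]], ":", fixed = TRUE)
    data.frame(primaryid = demo$primaryid[i], caseid = demo$caseid[i],
               drug_seq = as.character(seq_along(parts)),
               role_cod = vapply(parts, `[`, "", 2),
               drugname = vapply(parts, `[`, "", 1),
               stringsAsFactors = FALSE)
  }))
  reac_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(primaryid = demo$primaryid[i], caseid = demo$caseid[i],
               pt = pts[[i]], stringsAsFactors = FALSE)
  }))
  ther_rows <- if (!is.null(start_dt)) {
    data.frame(primaryid = demo$primaryid, caseid = demo$caseid,
               dsg_drug_seq = "1", start_dt = start_dt,
               stringsAsFactors = FALSE)
  } else NULL
  tabs <- list(demo = demo, drug = drug_rows, reac = reac_rows,
               ther = ther_rows, indi = NULL, outc = NULL)
  deduplicate(tabs)
}

# independent scalar formula oracle for the four statistics (direct
# textbook evaluation, no shared code with the package internals)
oracle_stats <- function(a, b, c, d) {
  N <- a + b + c + d
  ror <- (a / b) / (c / d)
  se_r <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_p <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  exp_cells <- outer(c(a + b, c + d), c(a + c, b + d)) / N
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  chi2 <- sum((obs - exp_cells)^2 / exp_cells)
  chi2_yates <- sum((pmax(0, abs(obs - exp_cells) - 0.5))^2 / exp_cells)
  E <- (a + b) * (a + c) / N
  ic <- log(a / E, base = 2)
  ebgm <- a / E
  list(ror = ror, ror_lo = exp(log(ror) - 1.96 * se_r),
       ror_hi = exp(log(ror) + 1.96 * se_r),
       prr = prr, prr_lo = exp(log(prr) - 1.96 * se_p),
       prr_hi = exp(log(prr) + 1.96 * se_p),
       chi2 = chi2, chi2_yates = chi2_yates,
       ic = ic, ic025 = ic - 1.96 * se_p / log(2),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.645 * se_r))
}
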