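test_that("the same seed and config give byte-identical output files", {
  cfg <- cohort_config(n_cases = 300, seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_faers_ascii(generate_cohort(cfg)$tables, d1)
  f2 <- write_faers_ascii(generate_cohort(cfg)$tables, d2)
  for (role in names(f1)) {
    expect_identical(readLines(f1[[role]]), readLines(f2[[role]]),
                     label = role)
  }
  # and a different seed does not
  f3 <- write_faers_ascii(
    generate_cohort(cohort_config(n_cases = 300, seed = 124))$tables,
    withr::local_tempdir())
  expect_false(identical(readLines(f1[["demo"]]), readLines(f3[["demo"]])))
})

test_that("manifest counts equal counts recomputed from the emitted files", {
  cfg <- cohort_config(n_cases = 1500, seed = 456,
                       ddi_injections = data.frame(
                         drug_a = "SARILUMAB", drug_b = "TOCILIZUMAB",
                         event = "Malaise", multiplier = 5))
  coh <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  files <- write_faers_ascii(coh$tables, d)
  cases <- deduplicate(read_faers_tables(as.list(files)))
  expect_equal(nrow(cases$demo), coh$manifest$n_expected_after_dedup)

  # spot-check drug-event counts
  truth <- coh$manifest$drug_event_counts
  for (i in c(1L, 25L, 60L, nrow(truth))) {
    dg <- truth$drug[i]; evn <- truth$event[i]
    with_dg <- unique(cases$drug$primaryid[cases$drug$drug_norm == dg])
    with_ev <- unique(cases$reac$primaryid[cases$reac$pt == evn])
    n_got <- length(intersect(with_dg, with_ev))
    # manifest counts predate deletions; recount allowing for deleted cases
    expect_lte(abs(n_got - truth$n_reports[i]),
               length(coh$manifest$deletion_caseids))
  }

  # with deletions off, the equality is exact
  cfg0 <- cohort_config(n_cases = 1500, seed = 456, deletion_rate = 0)
  coh0 <- generate_cohort(cfg0)
  cases0 <- deduplicate(coh0$tables)
  truth0 <- coh0$manifest$drug_event_counts
  for (i in c(1L, 25L, 60L, nrow(truth0))) {
    dg <- truth0$drug[i]; evn <- truth0$event[i]
    with_dg <- unique(cases0$drug$primaryid[cases0$drug$drug_norm == dg])
    with_ev <- unique(cases0$reac$primaryid[cases0$reac$pt == evn])
    expect_equal(length(intersect(with_dg, with_ev)), truth0$n_reports[i])
  }
})

test_that("duplicate versions never displace the true report version", {
  cfg <- cohort_config(n_cases = 600, seed = 88, duplicate_rate = 0.3,
                       deletion_rate = 0)
  coh <- generate_cohort(cfg)
  cases <- deduplicate(coh$tables)
  expect_equal(nrow(cases$demo), 600L)
  # the retained version is always the original (suffix 09), including for
  # tie-dated duplicates where the largest-primaryid rule decides
  expect_true(all(substr(cases$demo$primaryid, 8, 9) == "09"))
  expect_gt(coh$manifest$n_duplicate_versions, 0)
})

test_that("a null cohort has relative reporting ratios near one", {
  cfg <- cohort_config(n_cases = 50000, seed = 314, duplicate_rate = 0,
                       deletion_rate = 0)
  cases <- deduplicate(generate_cohort(cfg)$tables)
  scan <- signal_scan(cases, "SARILUMAB", min_n = 5L)
  # every event's EBGM (relative reporting ratio) within binomial error of 1
  expect_true(all(abs(scan$ebgm - 1) < 4 / sqrt(scan$a)))
})

test_that("an injected multiplier of 4 is recovered by the pipeline ROR", {
  # a rare event, so the odds ratio tracks the injected rate ratio
  cfg <- cohort_config(
    n_cases = 50000, seed = 2718, duplicate_rate = 0, deletion_rate = 0,
    signal_injections = data.frame(drug = "SARILUMAB",
                                   event = "Hepatic enzyme increased",
                                   multiplier = 4))
  cases <- deduplicate(generate_cohort(cfg)$tables)
  scan <- signal_scan(cases, "SARILUMAB")
  got <- scan[scan$term == "Hepatic enzyme increased", ]
  expect_gt(got$ror, 3.5)
  expect_lt(got$ror, 4.5)
  expect_true(got$positive)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(cohort_config(n_cases = 100),
               "'seed' is mandatory")
  expect_error(cohort_config(
    n_cases = 100, seed = 1,
    signal_injections = data.frame(drug = "SARILUMAB", event = "Pain",
                                   multiplier = 20)),
    "infeasible")
  expect_error(cohort_config(
    n_cases = 100, seed = 1,
    signal_injections = data.frame(drug = "SARILUMAB", event = "Zzz",
                                   multiplier = 2)),
    "absent from the catalog")
})

test_that("the null false-positive rate of the any-method rule stays under 10%", {
  rates <- numeric(100)
  for (s in 1:100) {
    cfg <- cohort_config(n_cases = 1200, seed = 40000 + s,
                         duplicate_rate = 0, deletion_rate = 0)
    cases <- deduplicate(generate_cohort(cfg)$tables)
    scan <- signal_scan(cases, "SARILUMAB")
    rates[s] <- mean(scan$positive)
  }
  expect_lte(mean(rates), 0.10)
})
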