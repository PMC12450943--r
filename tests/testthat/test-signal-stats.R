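test_that("contingency cells count reports, not reaction rows", {
  cases <- toy_cases(
    drugs = list(c("DRUGX:PS"), c("DRUGX:PS"), c("DRUGY:PS"), c("DRUGY:PS")),
    pts = list("EvE", "EvF", "EvE", "EvF"))
  t <- build_contingency(cases, "DRUGX", "EvE", level = "pt")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1L, 1L, 1L, 1L))

  # a PT repeated on one report still counts once
  cases2 <- toy_cases(
    drugs = list(c("DRUGX:PS"), c("DRUGY:PS")),
    pts = list(c("EvE", "EvE"), "EvF"))
  t2 <- build_contingency(cases2, "DRUGX", "EvE", level = "pt")
  expect_equal(t2$a, 1L)

  expect_error(build_contingency(subset_cases(cases, character(0)),
                                 "DRUGX", "EvE"), "empty stratum")
})

test_that("the injected-pair cell count matches the generator's bookkeeping", {
  cfg <- cohort_config(
    n_cases = 3000, seed = 21, duplicate_rate = 0, deletion_rate = 0,
    signal_injections = data.frame(drug = "SARILUMAB",
                                   event = "Injection site rash",
                                   multiplier = 6))
  coh <- generate_cohort(cfg)
  cases <- deduplicate(coh$tables)
  t <- build_contingency(cases, "SARILUMAB", "Injection site rash")
  truth <- coh$manifest$drug_event_counts
  expect_equal(t$a, truth$n_reports[truth$drug == "SARILUMAB" &
                                      truth$event == "Injection site rash"])
})

test_that("the four statistics reproduce their closed-form values", {
  t <- list(a = 10, b = 90, c = 100, d = 9900)
  expect_equal(unname(ror_stat(t)), c(11, 5.559515, 21.76449), tolerance = 1e-6)
  p <- prr_chi2(t)
  expect_equal(unname(p[["prr"]]), 10)
  expect_equal(unname(p[["chi2"]]), 74.44717, tolerance = 1e-6)
  expect_equal(unname(p[["chi2_yates"]]), 66.32694, tolerance = 1e-6)
  expect_equal(unname(mgps_ebgm(t)[["ebgm"]]), 9.181818, tolerance = 1e-6)
  expect_equal(unname(bcpnn_ic(t)[["ic"]]), log2(9.181818), tolerance = 1e-6)

  # observed equals expected: information component is exactly zero
  expect_equal(unname(bcpnn_ic(list(a = 10, b = 90, c = 990, d = 8910))[["ic"]]),
               0)

  # independence: every measure at its null value
  ind <- list(a = 10, b = 90, c = 100, d = 900)
  expect_equal(unname(ror_stat(ind)[["ror"]]), 1)
  pi_ <- prr_chi2(ind)
  expect_equal(unname(pi_[["prr"]]), 1)
  expect_equal(unname(pi_[["chi2"]]), 0)
  expect_equal(unname(mgps_ebgm(ind)[["ebgm"]]), 1)
})

test_that("chi-squared values agree with the stats::chisq.test oracle", {
  set.seed(33)
  for (i in 1:25) {
    cells <- as.list(setNames(rpois(4, c(20, 200, 300, 5000)) + 1,
                              c("a", "b", "c", "d")))
    m <- matrix(unlist(cells), 2, byrow = TRUE)
    p <- prr_chi2(cells)
    expect_equal(unname(p[["chi2"]]),
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(p[["chi2_yates"]]),
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("all four statistics agree with a brute-force oracle on 1000 random tables", {
  set.seed(99)
  for (i in 1:1000) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    c_ <- sample(1:500, 1); d <- sample(100:20000, 1)
    got <- evaluate_signal(list(a = a, b = b, c = c_, d = d))
    want <- oracle_stats(a, b, c_, d)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("signal ordering and symmetry invariants hold on random tables", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(1:40, 1); b <- sample(1:400, 1)
    c_ <- sample(1:400, 1); d <- sample(100:10000, 1)
    s <- evaluate_signal(list(a = a, b = b, c = c_, d = d))
    # ic is exactly log2(ebgm): the two share one expected count
    expect_identical(s$ic, log2(s$ebgm))
    if (s$ror > 1) {
      expect_true(s$ror >= s$prr && s$prr >= s$ebgm)
    } else if (s$ror < 1) {
      expect_true(s$ror <= s$prr && s$prr <= s$ebgm)
    }
    # swapping the rows of the table inverts the odds ratio
    swapped <- evaluate_signal(list(a = c_, b = d, c = a, d = b))
    expect_equal(swapped$ror, 1 / s$ror, tolerance = 1e-12)
  }
})

test_that("positivity rules gate on the minimum case count", {
  s <- evaluate_signal(list(a = 10, b = 90, c = 100, d = 9900))
  expect_true(s$flag_prr_mhra)
  expect_true(s$positive)

  # two cases with an enormous ROR still cannot fire ROR/PRR/MGPS
  s2 <- evaluate_signal(list(a = 2, b = 1, c = 5, d = 10000))
  expect_false(s2$flag_ror)
  expect_false(s2$flag_prr_mhra)
  expect_false(s2$flag_mgps)

  ind <- evaluate_signal(list(a = 10, b = 90, c = 100, d = 900))
  expect_false(ind$positive)

  set.seed(12)
  for (i in 1:100) {
    s3 <- evaluate_signal(list(a = sample(0:2, 1), b = sample(1:50, 1),
                               c = sample(1:50, 1), d = sample(50:5000, 1)))
    expect_false(s3$flag_ror || s3$flag_prr_mhra || s3$flag_mgps)
  }
})

test_that("zero cells trigger the continuity correction for intervals only", {
  expect_message(r <- ror_stat(list(a = 5, b = 20, c = 0, d = 100)),
                 "Haldane")
  expect_true(all(is.finite(r)))
  expect_error(ror_stat(list(a = 5, b = 20, c = 0, d = 100),
                        zero_cell = "error"), "zero cell")
  p <- prr_chi2(list(a = 5, b = 20, c = 0, d = 100))
  expect_equal(unname(p[["prr"]]), Inf)
  expect_true(is.na(p[["lo"]]) && is.na(p[["hi"]]))
})

test_that("ranking is a stable descending sort with an alphabetical tie-break", {
  res <- data.frame(term = c("Bpt", "Apt", "Cpt"), a = c(5L, 9L, 7L),
                    ror = c(3, 1.2, 2))
  by_freq <- rank_signals(res, "frequency")
  expect_equal(by_freq$a, c(9L, 7L, 5L))
  tie <- data.frame(term = c("Zpt", "Apt"), a = c(7L, 7L), ror = c(1, 1))
  expect_equal(rank_signals(tie, "frequency")$term, c("Apt", "Zpt"))
  expect_equal(rank_signals(res, "ror", k = 2)$term, c("Bpt", "Cpt"))
})

test_that("an injected pair ranks first by ROR among positive signals", {
  cfg <- cohort_config(
    n_cases = 8000, seed = 31, duplicate_rate = 0, deletion_rate = 0,
    signal_injections = data.frame(drug = "SARILUMAB",
                                   event = "Anaphylactic reaction",
                                   multiplier = 12))
  coh <- generate_cohort(cfg)
  cases <- deduplicate(coh$tables)
  scan <- signal_scan(cases, "SARILUMAB")
  pos <- rank_signals(scan[scan$positive, ], by = "ror")
  expect_equal(pos$term[1], "Anaphylactic reaction")
})
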