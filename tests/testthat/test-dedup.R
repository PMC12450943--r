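test_that("deduplication keeps the latest FDA_DT, then the largest PRIMARYID", {
  demo <- make_demo(2, caseid = c("100", "100"),
                    primaryid = c("1009", "1001"),
                    fda_dt = c("20240101", "20240301"))
  cases <- deduplicate(list(demo = demo, drug = NULL, reac = NULL))
  expect_equal(cases$demo$primaryid, "1001")

  demo_tie <- make_demo(2, caseid = c("100", "100"),
                        primaryid = c("1001", "1008"),
                        fda_dt = "20240301")
  cases_tie <- deduplicate(list(demo = demo_tie, drug = NULL, reac = NULL))
  expect_equal(cases_tie$demo$primaryid, "1008")
})

test_that("deletion lists remove whole cases", {
  demo <- make_demo(5, caseid = as.character(1:5))
  cases <- deduplicate(list(demo = demo, drug = NULL, reac = NULL),
                       deletion_caseids = "3")
  expect_equal(nrow(cases$demo), 4L)
  expect_false("3" %in% cases$demo$caseid)
  expect_equal(attr(cases, "log")$n_deleted, 1L)
})

test_that("deduplication is idempotent and recovers the true case count", {
  cfg <- cohort_config(n_cases = 400, seed = 5)
  coh <- generate_cohort(cfg)
  expect_gt(nrow(coh$tables$demo), 400)  # duplicates really were injected
  once <- deduplicate(coh$tables)
  expect_equal(nrow(once$demo), coh$manifest$n_expected_after_dedup)
  expect_false(anyDuplicated(once$demo$caseid) > 0)
  expect_true(all(once$demo$caseid %in%
                    setdiff(coh$tables$demo$caseid,
                            coh$manifest$deletion_caseids)))
  twice <- deduplicate(once)
  expect_equal(twice$demo, once$demo, ignore_attr = TRUE)
  # tie-dated duplicates resolve to the maximum primaryid of each version set
  pid_by_case <- tapply(as.numeric(coh$tables$demo$primaryid),
                        coh$tables$demo$caseid, max)
  expect_equal(as.numeric(once$demo$primaryid),
               as.numeric(pid_by_case[once$demo$caseid]))
})

test_that("age normalization converts every FAERS unit to years", {
  expect_equal(normalize_age(6, "DEC"), 60)
  expect_equal(normalize_age(24, "MON"), 2)
  expect_equal(normalize_age(58.4, "DY"), 0.16, tolerance = 1e-3)
  expect_equal(normalize_age(52.1429, "WK"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_warning(res <- normalize_age(-5, "YR"), "negative")
  expect_true(is.na(res))
  expect_true(is.na(normalize_age(200, "XX")))   # implausible, unknown unit
  expect_equal(normalize_age(70, "XX"), 70)      # plausible, assume years
})

test_that("drug-name normalization strips dosage text, maps synonyms, and is idempotent", {
  expect_equal(normalize_drug_name("  kevzara 200 MG "), "SARILUMAB")
  expect_equal(normalize_drug_name("SARILUMAB INJECTION"), "SARILUMAB")
  expect_equal(normalize_drug_name("RINVOQ (UPADACITINIB)"), "UPADACITINIB")
  x <- c("Kevzara", "methotrexate 2.5 mg", "IBUPROFEN")
  expect_equal(normalize_drug_name(normalize_drug_name(x)),
               normalize_drug_name(x))
})

test_that("PT-to-SOC mapping annotates known PTs and reports unmapped ones", {
  map <- load_pt_soc_map()
  reac <- data.frame(primaryid = c("1", "1", "2", "3"),
                     pt = c("Arthralgia", "Zzztest", "Pain", "Fatigue"))
  ann <- map_pt_to_soc(reac, map)
  expect_equal(ann$soc_name[1], "Musculoskeletal and connective tissue disorders")
  expect_true(is.na(ann$soc_name[2]))
  expect_equal(nrow(ann), 4L)  # unmapped PT retained at PT level
  expect_equal(attr(ann, "unmapped"), "Zzztest")
  tally <- table(ann$soc_name)
  expect_equal(sort(as.integer(tally)), c(1L, 2L))  # 3 mapped PTs in 2 SOCs
  expect_error(map_pt_to_soc(reac, map[0, ]), "empty")
})

test_that("target-report selection honours role codes and synonyms", {
  cases <- toy_cases(
    drugs = list(c("SARILUMAB:PS"), c("SARILUMAB:C", "IBUPROFEN:PS"),
                 c("KEVZARA:PS"), c("IBUPROFEN:PS")),
    pts = list("Pain", "Pain", "Nausea", "Pain"))
  sel <- select_target_reports(cases, "SARILUMAB")
  expect_equal(sort(sel$demo$caseid), c("c0001", "c0003"))  # C-role excluded
  sel_any <- select_target_reports(cases, "sarilumab", roles = c("PS", "C"))
  expect_equal(nrow(sel_any$demo), 3L)
  expect_warning(sel0 <- select_target_reports(cases, "NOSUCHDRUG"), "no case")
  expect_equal(nrow(sel0$demo), 0L)
})

test_that("partial dates complete for ordering but vanish for day arithmetic", {
  expect_equal(parse_faers_date("202403", "complete"), as.Date("2024-03-01"))
  expect_equal(parse_faers_date("2024", "complete"), as.Date("2024-01-01"))
  expect_true(is.na(parse_faers_date("202403", "na")))
  expect_true(is.na(parse_faers_date("garbage", "complete")))
  expect_equal(parse_faers_date("20240315", "na"), as.Date("2024-03-15"))
})
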