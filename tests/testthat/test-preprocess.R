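test_that("dedup keeps the latest receipt date, breaking ties by primaryid", {
  demo <- make_demo(caseid = c(7, 7, 8, 8, 9),
                    primaryid = c(71, 72, 83, 81, 91),
                    fda_dt = c("20230101", "20230301",
                               "20230501", "20230501", "20230601"))
  kept <- deduplicate_cases(demo)
  expect_equal(sort(kept$primaryid), c("72", "83", "91"))
  # idempotent
  expect_equal(deduplicate_cases(kept), kept)
})

test_that("dedup is permutation-invariant and handles dateless cases", {
  demo <- make_demo(caseid = rep(1:10, each = 3),
                    primaryid = 100 + 1:30,
                    fda_dt = sprintf("202301%02d", rep(1:10, 3)))
  ref <- deduplicate_cases(demo)
  expect_equal(nrow(ref), 10L)
  set.seed(1)
  for (i in 1:5) {
    perm <- demo[sample.int(nrow(demo)), , drop = FALSE]
    expect_equal(deduplicate_cases(perm), ref, ignore_attr = TRUE)
  }
  nodate <- make_demo(caseid = c(5, 5), primaryid = c(51, 52),
                      fda_dt = c(NA, NA))
  expect_warning(kept <- deduplicate_cases(nodate), "no parseable fda_dt")
  expect_equal(kept$primaryid, "52")
})

test_that("deleted-case removal", {
  demo <- make_demo(caseid = 1:100, primaryid = 1:100 * 10,
                    fda_dt = "20230301")
  expect_equal(remove_deleted(demo, character()), demo)  # identity
  expect_equal(nrow(remove_deleted(demo, as.character(c(3, 14, 15, 92, 65)))),
               95L)
  expect_false("7" %in% remove_deleted(demo, "7")$caseid)
})

test_that("brand-name matching is whole-word, case-insensitive, first-wins", {
  dict <- default_drug_dictionary()
  expect_equal(match_target_drug("OZURDEX", dict), "Ozurdex")
  expect_equal(match_target_drug("ozurdex  0.7 mg implant", dict), "Ozurdex")
  expect_equal(match_target_drug("LOTEMAX 0.5% GEL", dict), "Lotemax")
  expect_equal(match_target_drug("PRED MILD  0.12%", dict), "Pred Mild")
  expect_equal(match_target_drug("KAPIMOX-P DROPS", dict), "Kapimox-P")
  # generic substance names deliberately unmatched
  expect_true(is.na(match_target_drug("DEXAMETHASONE", dict)))
  # no partial-word hits
  expect_true(is.na(match_target_drug("FMLX", dict)))
  expect_equal(match_target_drug("FML FORTE", dict), "FML")
  # first pattern in dictionary order wins
  d2 <- drug_dictionary(c("ALPHA", "ALPHA BETA"), c("first", "second"))
  expect_equal(match_target_drug("ALPHA BETA", d2), "first")
})

test_that("report assembly applies PS-role filter, joins and unit conversions", {
  demo <- make_demo(caseid = 1:4, primaryid = c(11, 21, 31, 41),
                    fda_dt = "20230301", event_dt = "20230210",
                    age = c("64", "730", NA, "60"),
                    age_cod = c("YR", "DY", NA, NA),
                    wt = c("154.324", NA, NA, "70"),
                    wt_cod = c("LBS", NA, NA, NA))
  drug <- data.frame(
    primaryid = c("11", "21", "21", "31", "41"),
    drug_seq = c("1", "1", "2", "1", "1"),
    role_cod = c("PS", "PS", "PS", "C", "PS"),
    drugname = c("DUREZOL", "OZURDEX", "MAXIDEX", "OZURDEX", "ASPIRIN"),
    route = NA, dose_form = NA, stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("11", "21", "31", "41", "99"),
                     pt = c("Eye pain", "Cataract", "Uveitis", "Headache",
                            "Orphan"), stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c("11", "21", "21"),
                     dsg_drug_seq = c("1", "1", "2"),
                     start_dt = c("20230201", "202302", "20230205"),
                     end_dt = NA, stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("11", "11"), outc_cod = c("HO", "OT"),
                     stringsAsFactors = FALSE)
  rep <- assemble_reports(demo, drug, reac, ther, outc)

  r1 <- rep[rep$caseid == "1", ]
  expect_equal(r1$target_drug, "Durezol")
  expect_equal(unlist(r1$pts), "Eye pain")
  expect_equal(sort(unlist(r1$outcomes)), c("HO", "OT"))
  expect_equal(r1$age_years, 64)
  expect_equal(r1$weight_kg, 154.324 * 0.453592, tolerance = 1e-8)
  expect_equal(r1$therapy_start, as.Date("2023-02-01"))

  # two target brands as PS -> assigned to both, each with its own start;
  # partial start date for Ozurdex is excluded -> NA therapy_start
  r2 <- rep[rep$caseid == "2", ]
  expect_setequal(r2$target_drug, c("Ozurdex", "Maxidex"))
  expect_equal(r2$age_years, rep(2.0, 2), tolerance = 1e-2)
  expect_true(is.na(r2$therapy_start[r2$target_drug == "Ozurdex"]))
  expect_equal(r2$therapy_start[r2$target_drug == "Maxidex"],
               as.Date("2023-02-05"))

  # the only Ozurdex row has role C -> comparator arm, not a target report
  r3 <- rep[rep$caseid == "3", ]
  expect_true(is.na(r3$target_drug))
  # non-dictionary PS drug -> comparator arm
  expect_true(is.na(rep$target_drug[rep$caseid == "4"]))
  # REAC row with unknown primaryid lands in the rejects report
  expect_true(any(attr(rep, "rejects")$primaryid == "99"))
})

test_that("injected duplicates reduce to the ground-truth unique count", {
  sim <- simulate_faers(sim_config(seed = 7, n_reports = 150,
                                   duplicate_rate = 0.2,
                                   deleted_rate = 0.04))
  man <- sim$manifest
  truth <- as.integer(man$value[man$key == "n_retained_expected"])
  demo <- remove_deleted(deduplicate_cases(sim$tables$demo), sim$deleted)
  expect_equal(nrow(demo), truth)
  # each caseid exactly once
  expect_false(any(duplicated(demo$caseid)))
  # zero duplicate rate is the identity on counts
  sim0 <- simulate_faers(sim_config(seed = 8, n_reports = 100,
                                    duplicate_rate = 0, deleted_rate = 0))
  expect_equal(nrow(deduplicate_cases(sim0$tables$demo)), 100L)
})
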