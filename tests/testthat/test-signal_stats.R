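# Frozen oracle values below were computed by independent hand
# arithmetic on the closed forms: for (a,b,c,d) = (10,90,100,9900),
# ROR = 10*9900/(90*100) = 11, SE(lnROR) = sqrt(1/10+1/90+1/100+1/9900)
# = sqrt(0.12121212...), lower CI = exp(ln 11 - 1.96*0.348156...) =
# 5.559515; PRR = (10/100)/(100/10000) = 10; EBGM = 10*10100/(100*110)
# = 9.181818...

test_that("ROR matches hand-computed values, thresholds gate on a >= 3", {
  r <- ror(c(10, 90, 100, 9900))
  expect_equal(r$ror, 11)
  expect_equal(r$ror_lo95, exp(log(11) - 1.96 * sqrt(0.12121212121212122)),
               tolerance = 1e-9)
  expect_equal(r$ror_lo95, 5.559515, tolerance = 1e-6)
  expect_true(r$signal)
  expect_false(r$corrected)

  balanced <- ror(c(5, 5, 5, 5))
  expect_equal(balanced$ror, 1)
  expect_false(balanced$signal)

  # strong association but a < 3: never a signal
  small <- ror(c(2, 1, 1, 1000))
  expect_gt(small$ror_lo95, 1)
  expect_false(small$signal)
})

test_that("PRR matches hand-computed values", {
  p <- prr(c(10, 90, 100, 9900))
  expect_equal(p$prr, 10)
  expect_equal(p$prr_lo95,
               exp(log(10) - 1.96 * sqrt(1 / 10 - 1 / 100 + 1 / 100 - 1 / 10000)),
               tolerance = 1e-9)
  expect_true(p$signal)
  expect_equal(prr(c(5, 5, 5, 5))$prr, 1)
})

test_that("EBGM is the relative reporting ratio with log-normal bounds", {
  e <- ebgm(c(10, 90, 100, 9900))
  expect_equal(e$ebgm, 10 * 10100 / (100 * 110), tolerance = 1e-12)
  expect_equal(e$ebgm, 9.181818, tolerance = 1e-6)
  expect_equal(ebgm(c(10, 90, 90, 810))$ebgm, 1)
  expect_false(ebgm(c(10, 90, 90, 810))$signal)
})

test_that("BCPNN agrees with an independently coded oracle to 1e-9", {
  tables <- list(c(10, 90, 100, 9900), c(10, 90, 90, 810),
                 c(3, 7, 11, 400), c(150, 600, 85, 4165),
                 c(1, 1, 1, 1))
  for (tt in tables) {
    got <- bcpnn(tt)
    want <- oracle_bcpnn(tt[1], tt[2], tt[3], tt[4])
    expect_equal(got$ic, want$ic, tolerance = 1e-9)
    expect_equal(got$e_ic, want$e_ic, tolerance = 1e-9)
    expect_equal(got$v_ic, want$v_ic, tolerance = 1e-9)
    expect_equal(got$ic025, want$ic025, tolerance = 1e-9)
  }
  # raw IC is exactly zero at independence
  expect_equal(bcpnn(c(10, 90, 90, 810))$ic, 0)
  # the prior construction makes E(IC) exactly zero on balanced tables
  for (k in c(1, 5, 50)) {
    expect_equal(bcpnn(c(k, k, k, k))$e_ic, 0, tolerance = 1e-12)
  }
  # undefined margins: no signal
  expect_error(disproportionality(0, 0, 5, 5), NA)
  z <- disproportionality(0, 0, 5, 5, correct = FALSE)
  expect_false(z$bcpnn_signal)
})

test_that("shrinkage vanishes as counts scale: IC025 rises toward raw IC", {
  base <- c(10, 90, 90, 810)
  ic_raw <- bcpnn(base)$ic
  ic025 <- vapply(c(1, 10, 100), function(k) bcpnn(base * k)$ic025,
                  numeric(1))
  expect_true(all(diff(ic025) > 0))
  expect_true(all(ic025 < ic_raw))
  expect_lt(ic_raw - ic025[3], 0.2)
})

test_that("cross-method consistency over random positive-cell tables", {
  set.seed(42)
  n <- 2000
  a <- sample(1:60, n, TRUE); b <- sample(1:400, n, TRUE)
  c_ <- sample(1:400, n, TRUE); d <- sample(50:8000, n, TRUE)
  res <- disproportionality(a, b, c_, d)
  # direction agreement
  expect_equal(sign(res$ror - 1), sign(res$prr - 1))
  expect_equal(sign(res$prr - 1), sign(res$ic))
  expect_equal(sign(res$ic), sign(res$ebgm - 1))
  # the odds ratio is at least as far from 1 as the proportional ratio
  expect_true(all(abs(log(res$ror)) >= abs(log(res$prr)) - 1e-12))
  # identical closed forms for raw IC and EBGM
  expect_equal(2^res$ic, res$ebgm, tolerance = 1e-9)
})

test_that("estimates are monotone non-decreasing in a with b,c,d fixed", {
  a <- 1:40
  res <- disproportionality(a, 50, 30, 2000)
  for (col in c("ror", "prr", "ebgm", "ic025")) {
    expect_true(all(diff(res[[col]]) > -1e-12), info = col)
  }
})

test_that("zero cells trigger the continuity correction, a = 0 yields NA", {
  z <- disproportionality(5, 0, 3, 100)
  expect_true(z$corrected)
  expect_true(is.finite(z$ror) && is.finite(z$ror_hi95))
  # uncorrected a >= 3 gate still applies after correction
  z2 <- disproportionality(2, 0, 3, 100)
  expect_false(z2$ror_signal)
  expect_true(is.na(disproportionality(0, 10, 10, 100)$ror))
})

test_that("2x2 construction counts each report exactly once per cell", {
  rep4 <- make_reports(caseid = 1:4,
                       target_drug = c("drugX", "drugX", "drugY", "drugY"),
                       pts = list("PT1", "PT2", "PT1", "PT2"))
  t1 <- build_2x2(rep4, "drugX", "PT1")
  expect_equal(unlist(t1[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  # multiple PTs on one report count once in a
  rep2 <- make_reports(caseid = 1:2, target_drug = c("drugX", NA),
                       pts = list(c("PT1", "PT2"), "PT3"))
  t2 <- build_2x2(rep2, "drugX", "PT1")
  expect_equal(t2$a, 1)
  expect_equal(t2$n, 2)
})

test_that("2x2 cells equal a brute-force recount on a synthetic corpus", {
  sim <- simulate_faers(sim_config(seed = 5, n_reports = 200))
  rep <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
  n_cases <- length(unique(rep$caseid))
  for (term in c("Cataract", "Eye pain", "Headache")) {
    got <- build_2x2(rep, "Ozurdex", term)
    want <- brute_force_2x2(rep, "Ozurdex", term)
    expect_equal(unlist(got[c("a", "b", "c", "d")]), want)
    expect_equal(got$n, n_cases)
  }
  # SOC level against the same brute force
  got_soc <- build_2x2(rep, "Lotemax", "Eye disorders", level = "SOC",
                       map = sim$map)
  want_soc <- brute_force_2x2(rep, "Lotemax", "Eye disorders",
                              level = "SOC", map = sim$map)
  expect_equal(unlist(got_soc[c("a", "b", "c", "d")]), want_soc)
  expect_error(build_2x2(rep, "Lotemax", "No such SOC", level = "SOC",
                         map = sim$map), "No such SOC")
})

test_that("screen emits every term with a >= 1 and matches per-term tables", {
  sim <- simulate_faers(sim_config(seed = 5, n_reports = 300))
  rep <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
  s <- screen_drug(rep, "Ozurdex")
  expect_gt(nrow(s), 0)
  expect_true(all(s$a >= 1))
  expect_equal(s$a + s$b + s$c + s$d,
               rep_len(length(unique(rep$caseid)), nrow(s)))
  # spot-check rows against build_2x2
  for (i in c(1L, nrow(s))) {
    tt <- build_2x2(rep, "Ozurdex", s$term[i])
    expect_equal(unname(unlist(s[i, c("a", "b", "c", "d")])),
                 unname(unlist(tt[c("a", "b", "c", "d")])))
  }
  # SOC-level drug x SOC matrix equals per-cell computation
  m <- soc_ror_matrix(rep, drugs = c("Ozurdex", "Lotemax"), map = sim$map)
  for (dr in rownames(m)) for (soc in colnames(m)) {
    if (!is.na(m[dr, soc])) {
      expect_equal(m[dr, soc],
                   ror(build_2x2(rep, dr, soc, "SOC", sim$map))$ror,
                   info = paste(dr, soc))
    }
  }
})

test_that("term overlap intersects per-drug signal sets", {
  expect_equal(common_terms(list(x = c("A", "B"), y = c("B", "C")))$common,
               "B")
  expect_length(common_terms(list(x = "A", y = "B"))$common, 0L)
  ov <- common_terms(list(x = c("A", "B"), y = c("B", "C"),
                          z = c("B", "D")))
  expect_equal(ov$sizes, c(x = 2L, y = 2L, z = 2L))
  expect_equal(ov$pairwise["x", "y"], 1L)
  expect_error(common_terms(list(x = "A")), "at least two")
})

test_that("a PT planted in every drug is recovered as the full intersection", {
  # keep the class share of the corpus small so the common term is not
  # diluted out of the reference set
  targets <- c("Ozurdex", "Lotemax", "Durezol", "Maxidex", "Iluvien",
               "FML", "Triesence")
  drugs <- rbind(
    data.frame(label = targets, p = 0.02, target = TRUE),
    data.frame(label = sprintf("OTHER PRODUCT %02d", 1:20),
               p = (1 - 0.14) / 20, target = FALSE))
  cfg <- sim_config(seed = 31, n_reports = 6000, drugs = drugs,
                    planted = data.frame(drug = targets, pt = "Cataract",
                                         rr = 25),
                    duplicate_rate = 0, deleted_rate = 0)
  rep <- clean_reports(simulate_faers(cfg)$tables,
                       dictionary = default_drug_dictionary())
  screens <- screen_all(rep, level = "PT")
  ov <- common_terms(screens, mode = "all_four")
  expect_equal(ov$common, "Cataract")
})
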