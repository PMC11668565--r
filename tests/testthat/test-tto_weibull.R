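test_that("induction times subtract dates and tally every exclusion", {
  rep <- make_reports(
    caseid = 1:5, target_drug = "Ozurdex", pts = as.list(rep("PT", 5)),
    event_dt = as.Date(c("2023-01-11", "2023-01-01", NA, "2023-02-01",
                         "2023-01-05")),
    therapy_start = as.Date(c("2023-01-01", "2023-01-05", "2023-01-01",
                              NA, "2023-01-05")),
    event_precision = c("day", "day", "month", "day", "day"))
  it <- induction_times(rep)
  expect_equal(it$tto_days, 10)
  excl <- attr(it, "exclusions")
  expect_equal(excl[["negative interval"]], 1L)
  expect_equal(excl[["partial date"]], 1L)
  expect_equal(excl[["missing date"]], 1L)
  expect_equal(excl[["zero interval"]], 1L)
  expect_equal(nrow(it) + sum(excl), 5L)
})

test_that("quartiles use linear interpolation at rank 1+(n-1)p", {
  expect_equal(tto_quartiles(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(tto_quartiles(7), c(median = 7, q1 = 7, q3 = 7))
  expect_error(tto_quartiles(numeric(0)), "no induction times")
  set.seed(99)
  x <- rweibull(1000, shape = 0.55, scale = 32.5)
  med_closed <- 32.5 * log(2)^(1 / 0.55)
  expect_lt(abs(tto_quartiles(x)["median"] - med_closed) / med_closed, 0.15)
})

test_that("Weibull MLE recovers generating parameters and matches an
           independent fitter", {
  set.seed(123)
  x <- rweibull(2000, shape = 0.55, scale = 30)
  fit <- fit_weibull(x)
  expect_gt(30, fit$alpha_ci["lo"]); expect_lt(30, fit$alpha_ci["hi"])
  expect_gt(0.55, fit$beta_ci["lo"]); expect_lt(0.55, fit$beta_ci["hi"])
  expect_equal(fit$failure_type, "early failure")

  # agreement limited by the reference fitter's looser convergence
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(coef(fit)["alpha"]), unname(ref$estimate["scale"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["beta"]), unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_gte(as.numeric(logLik(fit)), ref$loglik - 1e-6)
})

test_that("fit is order-invariant, scale-equivariant, and beats its start", {
  set.seed(7)
  x <- rweibull(400, shape = 1.3, scale = 12)
  f1 <- fit_weibull(x)
  f2 <- fit_weibull(rev(sort(x)))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  fk <- fit_weibull(x * 10)
  expect_equal(fk$alpha, f1$alpha * 10, tolerance = 1e-6)
  expect_equal(fk$beta, f1$beta, tolerance = 1e-6)
  expect_gte(f1$loglik, f1$loglik_start)
})

test_that("exponential data yield a shape interval containing 1", {
  set.seed(11)
  x <- rweibull(2000, shape = 1, scale = 20)
  fit <- fit_weibull(x)
  expect_lt(fit$beta_ci["lo"], 1)
  expect_gt(fit$beta_ci["hi"], 1)
  expect_equal(fit$failure_type, "random failure")
})

test_that("degenerate inputs are refused with clear errors", {
  expect_error(fit_weibull(rep(c(1, 2, 3), 10)), "at least 10 distinct")
  expect_error(fit_weibull(rep(5, 50)), "at least 10 distinct")
  expect_error(fit_weibull(c(-1, seq_len(20))), "positive")
})

test_that("hazard classification follows the shape-interval rule", {
  expect_equal(classify_failure(c(0.5045, 0.6001)), "early failure")
  expect_equal(classify_failure(c(0.90, 1.10)), "random failure")
  expect_equal(classify_failure(c(1.20, 1.50)), "wear-out failure")
  # boundary: an interval touching 1 is not strictly on either side
  expect_equal(classify_failure(c(1.0, 1.2)), "random failure")
  expect_error(classify_failure(c(2, 1)), "ordered")
})

test_that("Wald interval coverage for the shape is near nominal", {
  # 200 replicates of n = 200 at (alpha = 30, beta = 0.55)
  hits <- vapply(seq_len(200), function(r) {
    set.seed(5000 + r)
    x <- rweibull(200, shape = 0.55, scale = 30)
    ci <- fit_weibull(x)$beta_ci
    ci["lo"] <= 0.55 && 0.55 <= ci["hi"]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("per-drug summary mirrors the fit and exclusion columns", {
  sim <- simulate_faers(sim_config(seed = 3, n_reports = 1500))
  rep <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
  tab <- tto_summary(rep, c("Ozurdex", "Lotemax"))
  expect_equal(tab$drug, c("Ozurdex", "Lotemax"))
  expect_true(all(tab$n_used > 10))
  expect_true(all(tab$failure_type == "early failure"))
  it <- induction_times(rep, "Ozurdex")
  f <- fit_weibull(it$tto_days)
  expect_equal(tab$alpha[1], f$alpha)
  expect_equal(tab$median[1], f$median)
})
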