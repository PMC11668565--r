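test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, duplicate_rate = 1.5), "probabilities")
  expect_error(sim_config(seed = 1,
                          planted = data.frame(drug = "Ozurdex",
                                               pt = "Cataract", rr = 500)),
               "infeasible")
  expect_error(sim_config(seed = 1,
                          planted = data.frame(drug = "Ozurdex",
                                               pt = "Nonexistent", rr = 2)),
               "not in the PT table")
})

test_that("identical seeds give byte-identical files, new seeds differ", {
  cfg <- sim_config(seed = 21, n_reports = 120)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_faers(cfg, dir = d1)
  simulate_faers(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(all(c("DEMO.txt", "DRUG.txt", "REAC.txt", "THER.txt",
                    "OUTC.txt", "deleted_cases.txt", "manifest.tsv")
                  %in% files))
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- withr::local_tempdir()
  simulate_faers(sim_config(seed = 22, n_reports = 120), dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "DEMO.txt"))),
                         unname(tools::md5sum(file.path(d3, "DEMO.txt")))))
})

test_that("realized margins track configured probabilities at n = 5000", {
  cfg <- sim_config(seed = 1234, n_reports = 5000, duplicate_rate = 0,
                    deleted_rate = 0)
  sim <- simulate_faers(cfg)
  rep <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
  n <- length(unique(rep$caseid))
  expect_equal(n, 5000L)
  # drug marginals within 4 binomial standard deviations
  for (i in seq_len(nrow(cfg$drugs))) {
    if (!cfg$drugs$target[i]) next
    p <- cfg$drugs$p[i]
    obs <- sum(rep$target_drug == cfg$drugs$label[i], na.rm = TRUE)
    expect_lt(abs(obs - n * p), 4 * sqrt(n * p * (1 - p)),
              label = paste(cfg$drugs$label[i], "margin deviation"))
  }
  # background PT rates among non-planted drugs, against the exact
  # implied marginal (Bernoulli rate plus the forced >=1-reaction mass)
  bg <- rep[is.na(rep$target_drug), ]
  nbg <- nrow(bg)
  p_all <- cfg$pts$p_background
  p0 <- prod(1 - p_all)
  for (pt in c("Headache", "Cataract", "Eye pain")) {
    p <- p_all[cfg$pts$pt == pt]
    p_eff <- p + p0 * p / sum(p_all)
    obs <- sum(vapply(bg$pts, function(x) pt %in% x, logical(1)))
    expect_lt(abs(obs - nbg * p_eff),
              4 * sqrt(nbg * p_eff * (1 - p_eff)) + 3,
              label = paste(pt, "rate deviation"))
  }
})

test_that("every generated reaction term resolves in the emitted map", {
  sim <- simulate_faers(sim_config(seed = 2, n_reports = 300))
  pts <- unique(sim$tables$reac$pt)
  expect_true(all(vapply(pts,
                         function(p) length(meddra_socs(sim$map, p)) > 0,
                         logical(1))))
  expect_equal(meddra_socs(toy_meddra(), "Cataract"), "Eye disorders")
  # the toy hierarchy covers the common ocular terms
  eye <- c("Eye inflammation", "Cataract", "Visual impairment", "Uveitis",
           "Eye pain", "Vision blurred", "Visual acuity reduced",
           "Retinal detachment")
  for (p in eye) expect_equal(meddra_socs(toy_meddra(), p), "Eye disorders")
})

test_that("the manifest alone scores dedup, planted and onset truths", {
  cfg <- sim_config(seed = 9, n_reports = 400, duplicate_rate = 0.1,
                    deleted_rate = 0.05)
  sim <- simulate_faers(cfg)
  man <- sim$manifest
  get1 <- function(section, key) {
    man$value[man$section == section & man$key == key]
  }
  expect_equal(as.integer(get1("counts", "n_cases")), 400L)
  expect_equal(as.integer(get1("counts", "n_duplicate_versions")), 40L)
  expect_equal(as.integer(get1("counts", "n_deleted")), 20L)
  expect_equal(as.integer(get1("counts", "n_retained_expected")), 380L)
  expect_equal(nrow(sim$tables$demo), 440L)
  expect_equal(get1("planted", "Ozurdex | Cataract"), "10")
  expect_equal(as.numeric(get1("tto_beta", "Ozurdex")), 0.55)
  # retained count matches after running the pipeline stages
  rep <- clean_reports(sim$tables, sim$deleted, sim$dictionary)
  expect_equal(length(unique(rep$caseid)),
               as.integer(get1("counts", "n_retained_expected")))
})
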