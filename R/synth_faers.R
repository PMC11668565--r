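# Synthetic FAERS-dialect data with known ground truth.
#
# The generator emits the exact '$'-delimited dialect consumed by the
# reader: one synthetic "quarter" of DEMO/DRUG/REAC/THER/OUTC rows plus
# a deleted-case list and a ground-truth manifest. Every report draws
# one primary-suspect drug, per-PT Bernoulli reactions (background rate
# times the planted relative risk for its drug), a therapy start date
# inside the quarter window, an event date start + Weibull onset delay
# in whole days, demographics from configured distributions, duplicate
# case versions with later receipt dates, and deleted cases.

#' Toy MedDRA-like hierarchy
#'
#' A small synthetic mapping (never licensed MedDRA content) covering
#' the preferred terms the generator can emit: eight ocular PTs under
#' "Eye disorders" plus endocrine, product-issue, nervous-system,
#' gastrointestinal and general-disorder terms.
#'
#' @return a `meddra_map`.
#' @export
toy_meddra <- function() {
  eye <- data.frame(
    pt = c("Eye inflammation", "Cataract", "Visual impairment", "Uveitis",
           "Eye pain", "Vision blurred", "Visual acuity reduced",
           "Retinal detachment"),
    hlt = c("Ocular inflammations", "Cataracts NEC",
            "Visual disorders NEC", "Uveitis and related conditions",
            "Ocular sensation disorders", "Visual disorders NEC",
            "Visual disorders NEC", "Retinal detachments"),
    hlgt = c("Ocular inflammatory disorders", "Lens disorders",
             "Vision disorders", "Ocular inflammatory disorders",
             "Ocular disorders NEC", "Vision disorders",
             "Vision disorders", "Retinal disorders"),
    soc = "Eye disorders", stringsAsFactors = FALSE)
  other <- data.frame(
    pt = c("Adrenal insufficiency", "Cushing's syndrome",
           "Device dislocation", "Device malfunction",
           "Headache", "Nausea", "Fatigue", "Drug ineffective",
           "Intraocular pressure increased"),
    hlt = c("Adrenal cortical hypofunctions", "Glucocorticoid disorders",
            "Device issues NEC", "Device issues NEC",
            "Headaches NEC", "Nausea and vomiting symptoms",
            "Asthenic conditions", "Therapeutic response decreased",
            "Intraocular pressure tests"),
    hlgt = c("Adrenal gland disorders", "Adrenal gland disorders",
             "Device issues", "Device issues",
             "Headaches", "Gastrointestinal signs and symptoms",
             "General system disorders NEC",
             "Therapeutic and nontherapeutic effects",
             "Eye investigations"),
    soc = c("Endocrine disorders", "Endocrine disorders",
            "Product issues", "Product issues",
            "Nervous system disorders", "Gastrointestinal disorders",
            "General disorders and administration site conditions",
            "General disorders and administration site conditions",
            "Investigations"),
    stringsAsFactors = FALSE)
  meddra_map(rbind(eye, other))
}

# default per-PT background reporting probabilities (per report)
default_pt_table <- function() {
  map <- toy_meddra()$table
  p <- c("Eye inflammation" = 0.120, "Cataract" = 0.020,
         "Visual impairment" = 0.100, "Uveitis" = 0.050,
         "Eye pain" = 0.150, "Vision blurred" = 0.180,
         "Visual acuity reduced" = 0.090, "Retinal detachment" = 0.040,
         "Adrenal insufficiency" = 0.015, "Cushing's syndrome" = 0.010,
         "Device dislocation" = 0.020, "Device malfunction" = 0.015,
         "Headache" = 0.250, "Nausea" = 0.200, "Fatigue" = 0.150,
         "Drug ineffective" = 0.300,
         "Intraocular pressure increased" = 0.060)
  data.frame(pt = names(p), p_background = unname(p),
             soc = map$soc[match(names(p), map$pt)],
             stringsAsFactors = FALSE)
}

# default drug table: the seven analyzed target brands plus a
# background product pool
default_drug_table <- function(n_background = 20) {
  targets <- data.frame(
    label = c("Ozurdex", "Lotemax", "Durezol", "Maxidex", "Iluvien",
              "FML", "Triesence"),
    p = c(0.08, 0.10, 0.09, 0.05, 0.03, 0.04, 0.02),
    target = TRUE, stringsAsFactors = FALSE)
  bg <- data.frame(
    label = sprintf("OTHER PRODUCT %02d", seq_len(n_background)),
    p = rep((1 - sum(targets$p)) / n_background, n_background),
    target = FALSE, stringsAsFactors = FALSE)
  rbind(targets, bg)
}

# default per-drug Weibull onset-delay parameters (days); background
# products get an exponential-like onset
default_tto_table <- function() {
  data.frame(
    drug = c("Ozurdex", "Lotemax", "Durezol", "Maxidex", "Iluvien",
             "FML", "Triesence", ".background"),
    alpha = c(32.54, 17.88, 19.57, 72.04, 254.65, 20.17, 7.57, 30),
    beta = c(0.55, 0.48, 0.76, 0.51, 0.73, 0.60, 0.39, 1.0),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for the synthetic-FAERS generator
#'
#' Defaults describe a plausible single-quarter ophthalmic-corticosteroid
#' corpus: seven target brands with marginal reporting probabilities, a
#' background product pool, the toy MedDRA hierarchy with per-PT
#' background rates, one planted drug--event association (Ozurdex /
#' Cataract at relative risk 10), per-drug Weibull onset-delay
#' parameters, FAERS-like demographic mixes, a 5\% duplicate-version
#' rate, 1\% deleted cases and a 5\% partial event-date rate.
#'
#' @param seed mandatory integer seed; the generator is fully
#'   deterministic given the config.
#' @param n_reports number of distinct cases to generate.
#' @param drugs data frame with columns `label`, `p` (marginal
#'   probability of being the report's primary-suspect drug), `target`
#'   (logical: matched by the brand dictionary).
#' @param pts data frame with columns `pt`, `p_background`, `soc`.
#' @param planted data frame with columns `drug`, `pt`, `rr`: within
#'   reports of `drug`, the reporting probability of `pt` is
#'   `p_background * rr`.
#' @param tto data frame with columns `drug`, `alpha`, `beta`
#'   (Weibull onset-delay scale in days and shape); row with drug
#'   `".background"` covers unlisted drugs.
#' @param duplicate_rate fraction of cases emitted additionally as a
#'   later report version.
#' @param deleted_rate fraction of cases listed in the deleted-case
#'   file.
#' @param partial_date_rate fraction of event dates degraded to
#'   year-month precision.
#' @param quarter_start first day of the synthetic quarter.
#' @param sex_p,country_p,occp_p named probability vectors.
#' @param outcome_p named per-code Bernoulli probabilities.
#' @param age_missing_p,weight_missing_p missingness rates.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_reports = 5000,
                       drugs = default_drug_table(),
                       pts = default_pt_table(),
                       planted = data.frame(drug = "Ozurdex",
                                            pt = "Cataract", rr = 10),
                       tto = default_tto_table(),
                       duplicate_rate = 0.05,
                       deleted_rate = 0.01,
                       partial_date_rate = 0.05,
                       quarter_start = as.Date("2023-01-01"),
                       sex_p = c(F = 0.55, M = 0.29, UNK = 0.16),
                       country_p = c(US = 0.60, FR = 0.08, GB = 0.07,
                                     DE = 0.06, JP = 0.05, CA = 0.04,
                                     UNK = 0.10),
                       occp_p = c(MD = 0.30, PH = 0.10, OT = 0.20,
                                  CN = 0.25, LW = 0.02, UNK = 0.13),
                       outcome_p = c(HO = 0.12, OT = 0.35, DE = 0.02,
                                     LT = 0.01, DS = 0.03, CA = 0.001,
                                     RI = 0.002),
                       age_missing_p = 0.5,
                       weight_missing_p = 0.75) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_reports = as.integer(n_reports),
              drugs = drugs, pts = pts, planted = planted, tto = tto,
              duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
              partial_date_rate = partial_date_rate,
              quarter_start = as.Date(quarter_start), sex_p = sex_p,
              country_p = country_p, occp_p = occp_p,
              outcome_p = outcome_p, age_missing_p = age_missing_p,
              weight_missing_p = weight_missing_p)
  rates <- c(duplicate_rate, deleted_rate, partial_date_rate,
             drugs$p, pts$p_background, outcome_p, age_missing_p,
             weight_missing_p)
  if (any(rates < 0 | rates > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(drugs$p) - 1) > 1e-8) stop("drug probabilities must sum to 1")
  if (nrow(planted) > 0) {
    if (any(planted$rr <= 0)) stop("relative risks must be > 0")
    pbg <- pts$p_background[match(planted$pt, pts$pt)]
    if (any(is.na(pbg))) stop("planted PT not in the PT table")
    if (any(pbg * planted$rr > 1)) {
      stop("infeasible config: planted rr pushes a PT probability above 1")
    }
    if (!all(planted$drug %in% drugs$label)) {
      stop("planted drug not in the drug table")
    }
  }
  if (any(cfg$tto$alpha <= 0) || any(cfg$tto$beta <= 0)) {
    stop("Weibull onset parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

sample_p <- function(n, p) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# brand strings as they would appear in DRUG.drugname: sometimes the
# bare brand, sometimes with strength/form suffixes
embellish_drugname <- function(label, target) {
  suffix <- c("", "", "", " 0.05%", " OPHTHALMIC SUSPENSION",
              " 0.7 MG IMPLANT", " EYE DROPS")
  s <- sample(suffix, length(label), replace = TRUE)
  toupper(paste0(label, ifelse(target, s, "")))
}

#' Generate a synthetic FAERS quarter
#'
#' Fully deterministic given `config` (the seed is part of the config).
#' Returns the five tables in reader schema, the deleted-case list, and
#' a ground-truth manifest sufficient to score dedup counts, planted
#' signals and onset-time parameters without re-reading the config.
#' When `dir` is given, also writes `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#' `THER.txt`, `OUTC.txt`, `deleted_cases.txt`, `manifest.tsv`,
#' `meddra_map.tsv` and `drug_dictionary.tsv` there.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return invisibly, a list with `tables` (named list of data frames),
#'   `deleted` (character vector), `manifest` (long-format data frame
#'   with columns `section`, `key`, `value`), `map` (the `meddra_map`),
#'   `dictionary`, and `dir` (if written).
#' @export
simulate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  drug_lab <- sample(config$drugs$label, n, replace = TRUE,
                     prob = config$drugs$p)
  is_target <- config$drugs$target[match(drug_lab, config$drugs$label)]

  # per-report per-PT reporting probabilities (background x planted rr)
  npt <- nrow(config$pts)
  pmat <- matrix(rep(config$pts$p_background, each = n), nrow = n)
  if (nrow(config$planted) > 0) {
    for (i in seq_len(nrow(config$planted))) {
      rows <- drug_lab == config$planted$drug[i]
      col <- match(config$planted$pt[i], config$pts$pt)
      pmat[rows, col] <- pmin(1, pmat[rows, col] * config$planted$rr[i])
    }
  }
  hit <- matrix(stats::runif(n * npt), nrow = n) < pmat
  none <- rowSums(hit) == 0L
  if (any(none)) {
    # guarantee at least one reaction per report; the forced draw is
    # independent of the drug, so it induces no drug-term association,
    # and adds prod(1-p) * p_i/sum(p) to each PT's implied marginal
    forced <- sample.int(npt, sum(none), replace = TRUE,
                         prob = config$pts$p_background)
    hit[cbind(which(none), forced)] <- TRUE
  }

  # therapy start inside the quarter; onset delay Weibull, whole days >= 1
  start_dt <- config$quarter_start + sample.int(90L, n, replace = TRUE) - 1L
  tto_idx <- match(drug_lab, config$tto$drug)
  tto_idx[is.na(tto_idx)] <- match(".background", config$tto$drug)
  alpha <- config$tto$alpha[tto_idx]
  beta <- config$tto$beta[tto_idx]
  delay <- round(stats::rweibull(n, shape = beta, scale = alpha))
  redo <- delay == 0L
  while (any(redo)) {
    delay[redo] <- round(stats::rweibull(sum(redo), shape = beta[redo],
                                         scale = alpha[redo]))
    redo <- delay == 0L
  }
  event_dt <- start_dt + delay
  fda_dt <- event_dt + sample.int(31L, n, replace = TRUE) - 1L
  event_str <- format(event_dt, "%Y%m%d")
  partial <- stats::runif(n) < config$partial_date_rate
  event_str[partial] <- substr(event_str[partial], 1, 6)

  sex <- sample_p(n, config$sex_p)
  sex[sex == "UNK"] <- NA
  age <- round(pmin(pmax(stats::rnorm(n, 60, 20), 1), 95))
  age[stats::runif(n) < config$age_missing_p] <- NA
  age_cod <- ifelse(is.na(age), NA, "YR")
  # a slice of ages expressed in days/months to exercise normalization
  in_days <- !is.na(age) & stats::runif(n) < 0.05
  age[in_days] <- age[in_days] * 365.25
  age_cod[in_days] <- "DY"
  wt <- round(pmin(pmax(stats::rnorm(n, 75, 15), 30), 160), 1)
  wt[stats::runif(n) < config$weight_missing_p] <- NA
  wt_cod <- ifelse(is.na(wt), NA, "KG")
  occp <- sample_p(n, config$occp_p)
  occp[occp == "UNK"] <- NA
  ctry <- sample_p(n, config$country_p)
  ctry[ctry == "UNK"] <- NA

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_dt, "%Y%m%d"), event_dt = event_str,
    sex = sex, age = as.character(age), age_cod = age_cod,
    wt = as.character(wt), wt_cod = wt_cod, occp_cod = occp,
    occr_country = ctry, stringsAsFactors = FALSE)

  # DRUG: primary suspect plus 0-2 concomitant background products
  ncon <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  bg_pool <- config$drugs$label[!config$drugs$target]
  if (length(bg_pool) == 0L) bg_pool <- "OTHER PRODUCT 01"
  con_pid <- rep(primaryid, ncon)
  con_seq <- unlist(lapply(ncon[ncon > 0], function(k) seq_len(k) + 1L),
                    use.names = FALSE) %||% integer(0)
  drug <- rbind(
    data.frame(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
               drugname = embellish_drugname(drug_lab, is_target),
               route = ifelse(is_target, "OPHTHALMIC", "ORAL"),
               dose_form = ifelse(is_target, "SOLUTION/DROPS", "TABLET"),
               stringsAsFactors = FALSE),
    data.frame(primaryid = con_pid, drug_seq = as.character(con_seq),
               role_cod = sample(c("C", "SS"), length(con_pid),
                                 replace = TRUE, prob = c(0.8, 0.2)),
               drugname = toupper(sample(bg_pool, length(con_pid),
                                         replace = TRUE)),
               route = "ORAL", dose_form = "TABLET",
               stringsAsFactors = FALSE))

  reac <- data.frame(
    primaryid = rep(primaryid, rowSums(hit)),
    pt = config$pts$pt[unlist(apply(hit, 1L, which), use.names = FALSE)],
    stringsAsFactors = FALSE)

  ther <- data.frame(
    primaryid = primaryid, dsg_drug_seq = "1",
    start_dt = format(start_dt, "%Y%m%d"),
    end_dt = "", stringsAsFactors = FALSE)
  ther$end_dt <- NA_character_

  outc_draw <- lapply(seq_len(n), function(i) {
    names(config$outcome_p)[stats::runif(length(config$outcome_p)) <
                              config$outcome_p]
  })
  outc <- data.frame(
    primaryid = rep(primaryid, lengths(outc_draw)),
    outc_cod = unlist(outc_draw, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)

  # duplicate versions: re-emit a case with a later receipt date and a
  # new primaryid (version digit 2)
  n_dup <- floor(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  if (length(dup_idx)) {
    dpid <- paste0(caseid[dup_idx], "2")
    ddemo <- demo[dup_idx, , drop = FALSE]
    ddemo$primaryid <- dpid
    ddemo$fda_dt <- format(fda_dt[dup_idx] +
                             sample.int(50L, n_dup, replace = TRUE) + 9L,
                           "%Y%m%d")
    demo <- rbind(demo, ddemo)
    redup <- function(tab) {
      e <- tab[tab$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      e$primaryid <- paste0(substr(e$primaryid, 1,
                                   nchar(e$primaryid) - 1L), "2")
      rbind(tab, e)
    }
    drug <- redup(drug); reac <- redup(reac); ther <- redup(ther)
    outc <- redup(outc)
  }

  n_del <- floor(config$deleted_rate * n)
  deleted <- if (n_del > 0) sort(sample(caseid, n_del)) else character(0)

  dict <- default_drug_dictionary()
  toy <- toy_meddra()$table
  hlt <- toy$hlt[match(tolower(config$pts$pt), toy$key)]
  hlgt <- toy$hlgt[match(tolower(config$pts$pt), toy$key)]
  hlt[is.na(hlt)] <- "Synthetic HLT"
  hlgt[is.na(hlgt)] <- "Synthetic HLGT"
  map <- meddra_map(data.frame(
    pt = config$pts$pt, hlt = hlt, hlgt = hlgt,
    soc = config$pts$soc, stringsAsFactors = FALSE))

  truth_rows <- rbind(
    data.frame(section = "counts", key = c(
      "n_cases", "n_duplicate_versions", "n_deleted",
      "n_retained_expected"),
      value = as.character(c(n, n_dup, n_del, n - n_del)),
      stringsAsFactors = FALSE),
    data.frame(section = "seed", key = "seed",
               value = as.character(config$seed), stringsAsFactors = FALSE),
    if (nrow(config$planted) > 0) data.frame(
      section = "planted",
      key = paste(config$planted$drug, config$planted$pt, sep = " | "),
      value = as.character(config$planted$rr), stringsAsFactors = FALSE),
    data.frame(section = "tto_alpha", key = config$tto$drug,
               value = as.character(config$tto$alpha),
               stringsAsFactors = FALSE),
    data.frame(section = "tto_beta", key = config$tto$drug,
               value = as.character(config$tto$beta),
               stringsAsFactors = FALSE),
    data.frame(section = "drug_marginal", key = config$drugs$label,
               value = as.character(config$drugs$p),
               stringsAsFactors = FALSE),
    data.frame(section = "pt_background", key = config$pts$pt,
               value = as.character(config$pts$p_background),
               stringsAsFactors = FALSE))

  fix_na <- function(tab) { tab[] <- lapply(tab, function(col) {
    col[!is.na(col) & col == ""] <- NA; col }); tab }
  tables <- list(demo = fix_na(demo), drug = fix_na(drug),
                 reac = fix_na(reac), ther = fix_na(ther),
                 outc = fix_na(outc))
  out <- list(tables = tables, deleted = deleted, manifest = truth_rows,
              map = map, dictionary = dict)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_faers_table(tables$demo, file.path(dir, "DEMO.txt"), "demo")
    write_faers_table(tables$drug, file.path(dir, "DRUG.txt"), "drug")
    write_faers_table(tables$reac, file.path(dir, "REAC.txt"), "reac")
    write_faers_table(tables$ther, file.path(dir, "THER.txt"), "ther")
    write_faers_table(tables$outc, file.path(dir, "OUTC.txt"), "outc")
    writeLines(deleted, file.path(dir, "deleted_cases.txt"))
    utils::write.table(truth_rows, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_meddra_map(map, file.path(dir, "meddra_map.tsv"))
    write_drug_dictionary(dict, file.path(dir, "drug_dictionary.tsv"))
    out$dir <- dir
  }
  invisible(out)
}

#' Null-simulation configuration for false-positive calibration
#'
#' A corpus with one target drug, many background products, `n_pts`
#' generic preferred terms at a common background rate, and no planted
#' association: every signal flagged on such data is a false positive.
#'
#' @param seed integer seed.
#' @param n_reports cases per replicate.
#' @param n_pts number of preferred terms.
#' @param p_drug marginal probability of the target drug.
#' @param p_pt per-report background probability of each PT.
#' @return a `sim_config`.
#' @export
null_sim_config <- function(seed, n_reports = 500, n_pts = 50,
                            p_drug = 0.3, p_pt = 0.04) {
  socs <- paste("Synthetic SOC", rep(LETTERS[1:5], length.out = n_pts))
  pts <- data.frame(pt = sprintf("Synthetic PT %02d", seq_len(n_pts)),
                    p_background = p_pt, soc = socs,
                    stringsAsFactors = FALSE)
  drugs <- rbind(
    data.frame(label = "Ozurdex", p = p_drug, target = TRUE,
               stringsAsFactors = FALSE),
    data.frame(label = sprintf("OTHER PRODUCT %02d", 1:10),
               p = (1 - p_drug) / 10, target = FALSE,
               stringsAsFactors = FALSE))
  sim_config(seed = seed, n_reports = n_reports, drugs = drugs, pts = pts,
             planted = data.frame(drug = character(), pt = character(),
                                  rr = numeric()),
             tto = data.frame(drug = ".background", alpha = 30, beta = 1),
             duplicate_rate = 0, deleted_rate = 0, partial_date_rate = 0)
}
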