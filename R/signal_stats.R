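# Disproportionality statistics on 2x2 report-level contingency tables.
#
# The counting unit is the de-duplicated report: for a (drug, term) pair,
#   a = reports with the target drug (as primary suspect) AND the term,
#   b = reports with the target drug, other terms only,
#   c = reports with the term but not the target drug,
#   d = all remaining reports,
# so a+b+c+d always equals the number of retained reports and the table
# margins are the drug and term report totals.

#' Default BCPNN prior hyperparameters
#'
#' The standard information-component priors: `gamma11 = alpha1 =
#' beta1 = 1`, `alpha = beta = 2`. The joint prior weight `gamma` is
#' derived per table as
#' `gamma11 * (N+alpha) * (N+beta) / ((a+b+alpha1) * (a+c+beta1))`,
#' which calibrates the posterior expectation of the IC to zero on an
#' empty database and (asymptotically) under independence.
#'
#' @param gamma11,alpha1,beta1,alpha,beta positive hyperparameters.
#' @return a named list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                         alpha = 2, beta = 2) {
  p <- list(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  if (any(unlist(p) <= 0)) stop("BCPNN hyperparameters must be > 0")
  structure(p, class = "bcpnn_priors")
}

#' Build the 2x2 contingency table for a (drug, term) pair
#'
#' Each retained report contributes to exactly one cell. At `level =
#' "SOC"` a report "has the term" iff at least one of its preferred
#' terms maps to that system organ class under `map`.
#'
#' @param reports a `faers_reports` data frame (see
#'   [assemble_reports()]); the reference set is all retained reports.
#' @param drug target-drug label.
#' @param term preferred term (PT level) or system organ class (SOC
#'   level); matching is case-insensitive after whitespace
#'   normalization.
#' @param level `"PT"` or `"SOC"`.
#' @param map a `meddra_map`, required at SOC level.
#' @return an object of class `contingency_2x2` with elements `a`, `b`,
#'   `c`, `d`, `n`, `drug`, `term`, `level`.
#' @export
build_2x2 <- function(reports, drug, term, level = c("PT", "SOC"),
                      map = NULL) {
  level <- match.arg(level)
  cs <- case_sets(reports, level = level, map = map)
  key <- tolower(norm_term(term, "keep"))
  if (level == "SOC") {
    if (is.null(map)) stop("a MedDRA-like map is required at SOC level")
    if (!(key %in% tolower(map$table$soc))) {
      stop("term not present in the mapping at SOC level: ", term)
    }
  }
  has_drug <- cs$case %in% cs$drug_cases[[drug]]
  has_term <- vapply(cs$terms, function(tt) key %in% tt, logical(1))
  a <- sum(has_drug & has_term)
  b <- sum(has_drug & !has_term)
  cc <- sum(!has_drug & has_term)
  d <- sum(!has_drug & !has_term)
  structure(list(a = a, b = b, c = cc, d = d, n = a + b + cc + d,
                 drug = drug, term = term, level = level),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table for (%s, %s) at %s level\n", x$drug, x$term,
              x$level))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target term", "other terms")))
  print(m)
  cat("N =", x$n, "\n")
  invisible(x)
}

# internal: per-case membership structures reused by build_2x2 and
# screen_drug; terms are normalized lowercase keys
case_sets <- function(reports, level = c("PT", "SOC"), map = NULL) {
  level <- match.arg(level)
  case <- unique(reports$caseid)
  first <- match(case, reports$caseid)
  pts <- lapply(reports$pts[first], function(p) unique(tolower(p)))
  terms <- if (level == "PT") {
    pts
  } else {
    if (is.null(map)) stop("a MedDRA-like map is required at SOC level")
    soc_of <- split(tolower(map$table$soc), map$table$key)
    lapply(pts, function(p) {
      unique(unlist(soc_of[p], use.names = FALSE)) %||% character(0)
    })
  }
  tg <- reports[!is.na(reports$target_drug), c("caseid", "target_drug")]
  drug_cases <- split(tg$caseid, tg$target_drug)
  list(case = case, terms = terms, drug_cases = drug_cases)
}

as_cells <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    unlist(table[c("a", "b", "c", "d")])
  } else {
    x <- unlist(table)[1:4]
    stats::setNames(x, c("a", "b", "c", "d"))
  }
}

#' Disproportionality estimates for vectors of 2x2 cells
#'
#' Vectorized core computing all four statistics. Zero-cell policy
#' (Haldane--Anscombe): when any of `b`, `c`, `d` is zero, 0.5 is added
#' to all four cells before estimation and the row is marked
#' `corrected`; the `a >= 3` signal gate always uses the uncorrected
#' `a`. Rows with `a == 0` are not meaningful signal candidates and
#' yield `NA` estimates.
#'
#' Closed forms (N = a+b+c+d):
#' \itemize{
#'   \item ROR = ad/bc, `SE(lnROR) = sqrt(1/a+1/b+1/c+1/d)`, 95\% CI
#'     `exp(lnROR +- 1.96 SE)`; signal iff `a >= 3` and lower CI > 1.
#'   \item PRR = (a/(a+b))/(c/(c+d)),
#'     `SE(lnPRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; signal iff
#'     `a >= 3` and lower CI > 1.
#'   \item BCPNN: raw `IC = log2(aN/((a+b)(a+c)))`; posterior
#'     expectation `E(IC)` and variance `V(IC)` under the Dirichlet
#'     priors of [bcpnn_priors()]; `IC025 = E(IC) - 2 sqrt(V(IC))`;
#'     signal iff IC025 > 0.
#'   \item EBGM: the simplified relative-reporting-ratio form
#'     `aN/((a+b)(a+c))` (not a full gamma-Poisson shrinkage fit), with
#'     log-normal bounds `exp(lnEBGM +- 1.96 sqrt(1/a+1/b+1/c+1/d))`;
#'     signal iff EBGM05 > 2.
#' }
#'
#' @param a,b,c,d integer vectors of cell counts (recycled to a common
#'   length).
#' @param priors BCPNN prior hyperparameters.
#' @param correct apply the zero-cell correction (default `TRUE`).
#' @return a data frame with one row per table: cells, `corrected`, all
#'   point estimates, interval bounds, and per-method signal flags plus
#'   the conjunction `all_four`.
#' @export
disproportionality <- function(a, b, c, d, priors = bcpnn_priors(),
                               correct = TRUE) {
  n <- max(length(a), length(b), length(c), length(d))
  a0 <- rep_len(as.numeric(a), n); b0 <- rep_len(as.numeric(b), n)
  c0 <- rep_len(as.numeric(c), n); d0 <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a0, b0, c0, d0))) || any(c(a0, b0, c0, d0) < 0)) {
    stop("cell counts must be non-negative and non-missing")
  }
  corrected <- correct & (b0 == 0 | c0 == 0 | d0 == 0)
  h <- ifelse(corrected, 0.5, 0)
  a1 <- a0 + h; b1 <- b0 + h; c1 <- c0 + h; d1 <- d0 + h
  N <- a1 + b1 + c1 + d1
  defined <- a0 > 0 & a1 > 0 & b1 > 0 & c1 > 0 & d1 > 0
  nab <- function(x) ifelse(defined, x, NA_real_)

  ror <- nab(a1 * d1 / (b1 * c1))
  se_ror <- nab(sqrt(1 / a1 + 1 / b1 + 1 / c1 + 1 / d1))
  ror_lo95 <- exp(log(ror) - 1.96 * se_ror)
  ror_hi95 <- exp(log(ror) + 1.96 * se_ror)

  prr <- nab((a1 / (a1 + b1)) / (c1 / (c1 + d1)))
  se_prr <- nab(sqrt(pmax(1 / a1 - 1 / (a1 + b1) + 1 / c1 - 1 / (c1 + d1), 0)))
  prr_lo95 <- exp(log(prr) - 1.96 * se_prr)
  prr_hi95 <- exp(log(prr) + 1.96 * se_prr)

  ic <- nab(log2(a1 * N / ((a1 + b1) * (a1 + c1))))
  g11 <- priors$gamma11; a1p <- priors$alpha1; b1p <- priors$beta1
  alp <- priors$alpha; bet <- priors$beta
  gam <- g11 * (N + alp) * (N + bet) / ((a1 + b1 + a1p) * (a1 + c1 + b1p))
  e_ic <- nab(log2((a1 + g11) * (N + alp) * (N + bet) /
                     ((N + gam) * (a1 + b1 + a1p) * (a1 + c1 + b1p))))
  v_ic <- nab((1 / log(2)^2) *
    ((N - a1 + gam - g11) / ((a1 + g11) * (1 + N + gam)) +
     (N - (a1 + b1) + alp - a1p) / ((a1 + b1 + a1p) * (1 + N + alp)) +
     (N - (a1 + c1) + bet - b1p) / ((a1 + c1 + b1p) * (1 + N + bet))))
  ic025 <- e_ic - 2 * sqrt(v_ic)

  ebgm <- nab(a1 * N / ((a1 + b1) * (a1 + c1)))
  se_ebgm <- se_ror
  ebgm05 <- exp(log(ebgm) - 1.96 * se_ebgm)
  ebgm95 <- exp(log(ebgm) + 1.96 * se_ebgm)

  flag <- function(x) !is.na(x) & x
  ror_signal <- flag(a0 >= 3 & ror_lo95 > 1)
  prr_signal <- flag(a0 >= 3 & prr_lo95 > 1)
  bcpnn_signal <- flag(ic025 > 0)
  ebgm_signal <- flag(ebgm05 > 2)

  data.frame(
    a = a0, b = b0, c = c0, d = d0, corrected = corrected,
    ror = ror, ror_lo95 = ror_lo95, ror_hi95 = ror_hi95,
    prr = prr, prr_lo95 = prr_lo95, prr_hi95 = prr_hi95,
    ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
    ebgm = ebgm, ebgm05 = ebgm05, ebgm95 = ebgm95,
    ror_signal = ror_signal, prr_signal = prr_signal,
    bcpnn_signal = bcpnn_signal, ebgm_signal = ebgm_signal,
    all_four = ror_signal & prr_signal & bcpnn_signal & ebgm_signal)
}

one_stat <- function(table, cols, priors = bcpnn_priors(), correct = TRUE) {
  cells <- as_cells(table)
  res <- disproportionality(cells["a"], cells["b"], cells["c"], cells["d"],
                            priors = priors, correct = correct)
  as.list(res[1, cols])
}

#' Reporting odds ratio with confidence interval and signal flag
#'
#' @param table a `contingency_2x2` or a numeric vector `c(a, b, c, d)`.
#' @param correct apply the zero-cell correction.
#' @return list with `ror`, `ror_lo95`, `ror_hi95`, `corrected`,
#'   `signal` (`a >= 3` and lower CI > 1).
#' @export
#' @examples
#' ror(c(10, 90, 100, 9900)) # ROR = 11
ror <- function(table, correct = TRUE) {
  out <- one_stat(table, c("ror", "ror_lo95", "ror_hi95", "corrected",
                           "ror_signal"), correct = correct)
  names(out)[names(out) == "ror_signal"] <- "signal"
  out
}

#' Proportional reporting ratio with confidence interval and signal flag
#' @inheritParams ror
#' @return list with `prr`, `prr_lo95`, `prr_hi95`, `corrected`,
#'   `signal`.
#' @export
prr <- function(table, correct = TRUE) {
  out <- one_stat(table, c("prr", "prr_lo95", "prr_hi95", "corrected",
                           "prr_signal"), correct = correct)
  names(out)[names(out) == "prr_signal"] <- "signal"
  out
}

#' BCPNN information component with shrinkage interval
#'
#' @inheritParams ror
#' @param priors prior hyperparameters (see [bcpnn_priors()]).
#' @return list with raw `ic`, posterior `e_ic` and `v_ic`, `ic025 =
#'   e_ic - 2*sqrt(v_ic)`, `corrected`, `signal` (IC025 > 0).
#' @export
bcpnn <- function(table, priors = bcpnn_priors(), correct = TRUE) {
  out <- one_stat(table, c("ic", "e_ic", "v_ic", "ic025", "corrected",
                           "bcpnn_signal"), priors = priors,
                  correct = correct)
  names(out)[names(out) == "bcpnn_signal"] <- "signal"
  out
}

#' Simplified empirical-Bayes geometric mean with interval bounds
#'
#' Uses the closed relative-reporting-ratio form `aN/((a+b)(a+c))`, not
#' a full gamma-Poisson mixture fit; see [disproportionality()].
#'
#' @inheritParams ror
#' @return list with `ebgm`, `ebgm05`, `ebgm95`, `corrected`, `signal`
#'   (EBGM05 > 2).
#' @export
ebgm <- function(table, correct = TRUE) {
  out <- one_stat(table, c("ebgm", "ebgm05", "ebgm95", "corrected",
                           "ebgm_signal"), correct = correct)
  names(out)[names(out) == "ebgm_signal"] <- "signal"
  out
}

#' Screen every term observed with a target drug
#'
#' Builds the 2x2 table of each term reported at least once with the
#' target drug (reference set: all retained reports, i.e. the target
#' drug versus all other drugs in the corpus) and computes all four
#' statistics with their flags. Terms never reported with the drug
#' (`a == 0`) are not emitted.
#'
#' @inheritParams build_2x2
#' @param priors BCPNN priors.
#' @param correct zero-cell policy toggle.
#' @return a `signal_screen` data frame (one row per term, sorted by
#'   decreasing ROR) with columns `term`, `level`, cells, estimates,
#'   bounds and flags; attributes `drug`, `level`, `n_reports`.
#' @export
screen_drug <- function(reports, drug, level = c("PT", "SOC"), map = NULL,
                        priors = bcpnn_priors(), correct = TRUE) {
  level <- match.arg(level)
  cs <- case_sets(reports, level = level, map = map)
  N <- length(cs$case)
  has_drug <- cs$case %in% cs$drug_cases[[drug]]
  n_drug <- sum(has_drug)
  term_case <- data.frame(
    term = unlist(cs$terms, use.names = FALSE) %||% character(0),
    drug = rep(has_drug, lengths(cs$terms)))
  if (nrow(term_case) == 0L || n_drug == 0L) {
    empty <- disproportionality(1, 1, 1, 1)[0, ]
    out <- cbind(data.frame(term = character(), level = character()), empty)
  } else {
    a_term <- tapply(term_case$drug, term_case$term, sum)
    n_term <- tapply(rep(1L, nrow(term_case)), term_case$term, sum)
    keep <- a_term >= 1
    a <- as.integer(a_term[keep])
    nt <- as.integer(n_term[keep])
    b <- n_drug - a
    cc <- nt - a
    d <- N - a - b - cc
    stats <- disproportionality(a, b, cc, d, priors = priors,
                                correct = correct)
    # report terms with their display casing (first occurrence wins)
    all_terms <- if (level == "PT") {
      unlist(lapply(reports$pts[match(cs$case, reports$caseid)], unique))
    } else NULL
    term_key <- names(a_term)[keep]
    display <- if (level == "PT" && length(all_terms)) {
      disp <- all_terms[match(term_key, tolower(all_terms))]
      ifelse(is.na(disp), term_key, disp)
    } else {
      # SOC display casing from the map
      if (!is.null(map)) {
        disp <- map$table$soc[match(term_key, tolower(map$table$soc))]
        ifelse(is.na(disp), term_key, disp)
      } else term_key
    }
    out <- cbind(data.frame(term = display, level = level,
                            stringsAsFactors = FALSE), stats)
    out <- out[order(-out$ror, out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "drug") <- drug
  attr(out, "level") <- level
  attr(out, "n_reports") <- N
  class(out) <- c("signal_screen", "data.frame")
  out
}

#' @export
print.signal_screen <- function(x, n = 10, ...) {
  cat(sprintf("Signal screen: %s at %s level (%d reports, %d terms)\n",
              attr(x, "drug"), attr(x, "level"), attr(x, "n_reports"),
              nrow(x)))
  cols <- intersect(c("term", "a", "ror", "ror_lo95", "ic025", "ebgm05",
                      "all_four"), names(x))
  print(format(utils::head(as.data.frame(x)[, cols, drop = FALSE], n),
               digits = 3), row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more terms\n")
  invisible(x)
}

#' Screen several drugs and tabulate a drug-by-SOC ROR matrix
#'
#' @inheritParams screen_drug
#' @param drugs character vector of target-drug labels; defaults to all
#'   labels present in `reports`.
#' @return named list of `signal_screen` objects.
#' @export
screen_all <- function(reports, drugs = NULL, level = c("PT", "SOC"),
                       map = NULL, priors = bcpnn_priors(), correct = TRUE) {
  level <- match.arg(level)
  drugs <- drugs %||% sort(unique(reports$target_drug[
    !is.na(reports$target_drug)]))
  stats::setNames(lapply(drugs, function(dr) {
    screen_drug(reports, dr, level = level, map = map, priors = priors,
                correct = correct)
  }), drugs)
}

#' Drug-by-SOC matrix of RORs (heatmap input)
#'
#' @inheritParams screen_all
#' @return numeric matrix, drugs in rows, SOCs in columns; `NA` where a
#'   SOC was never reported with the drug.
#' @export
soc_ror_matrix <- function(reports, drugs = NULL, map, priors = bcpnn_priors(),
                           correct = TRUE) {
  screens <- screen_all(reports, drugs = drugs, level = "SOC", map = map,
                        priors = priors, correct = correct)
  socs <- sort(unique(map$table$soc))
  m <- matrix(NA_real_, nrow = length(screens), ncol = length(socs),
              dimnames = list(names(screens), socs))
  for (dr in names(screens)) {
    s <- screens[[dr]]
    m[dr, s$term] <- s$ror
  }
  m
}

#' Terms common to every screened drug, with overlap counts
#'
#' Intersects per-drug signal sets (Venn-style reporting). Input is
#' either a named list of `signal_screen` objects (flagged terms are
#' extracted according to `mode`) or a named list of character vectors.
#'
#' @param screens named list of screens or term sets (>= 2).
#' @param mode which flag selects a term from a screen: `"all_four"`
#'   (conjunction of the four methods) or `"ror_only"`.
#' @return object of class `term_overlap`: `sets` (the per-drug term
#'   sets), `common` (terms flagged for every drug), `sizes`, `pairwise`
#'   (intersection-count matrix), and `region_counts` (exclusive Venn
#'   region counts keyed by drug combination).
#' @export
common_terms <- function(screens, mode = c("all_four", "ror_only")) {
  mode <- match.arg(mode)
  flag_col <- if (mode == "all_four") "all_four" else "ror_signal"
  sets <- lapply(screens, function(s) {
    if (is.data.frame(s)) unique(s$term[s[[flag_col]]]) else
      unique(as.character(s))
  })
  if (length(sets) < 2L) stop("need at least two screened drugs")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  common <- Reduce(intersect, sets)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  membership <- vapply(sets, function(s) {
    unique(unlist(sets, use.names = FALSE)) %in% s
  }, logical(length(unique(unlist(sets, use.names = FALSE)))))
  if (is.null(dim(membership))) {
    membership <- matrix(membership, ncol = k)
  }
  combo <- apply(membership, 1L, function(r) {
    paste(names(sets)[r], collapse = " & ")
  })
  region_counts <- sort(table(combo), decreasing = TRUE)
  structure(list(sets = sets, common = common,
                 sizes = lengths(sets), pairwise = pairwise,
                 region_counts = region_counts),
            class = "term_overlap")
}

#' @export
print.term_overlap <- function(x, ...) {
  cat("Term overlap across", length(x$sets), "drugs\n")
  cat("Set sizes:\n")
  print(x$sizes)
  cat("Common to all:", length(x$common), "term(s)\n")
  if (length(x$common)) cat(" ", paste(sort(x$common), collapse = ", "), "\n")
  invisible(x)
}
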