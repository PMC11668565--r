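# Independent oracles and fixture builders shared across tests.
# Oracles are deliberately coded from scratch (scalar, long-hand) so
# they never share a code path with the package internals they check.

# long-hand scalar BCPNN closed forms (double implementation)
oracle_bcpnn <- function(a, b, c, d,
                         g11 = 1, a1 = 1, b1 = 1, al = 2, be = 2) {
  N <- a + b + c + d
  ic_raw <- log(a * N / ((a + b) * (a + c))) / log(2)
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  eic <- log((a + g11) * (N + al) * (N + be) /
               ((N + gam) * (a + b + a1) * (a + c + b1))) / log(2)
  vic <- (1 / log(2)^2) * (
    (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
    (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
    (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))
  list(ic = ic_raw, e_ic = eic, v_ic = vic, ic025 = eic - 2 * sqrt(vic))
}

# brute-force recount of one 2x2 cell set from a reports object, using
# plain per-case set membership at PT or SOC level
brute_force_2x2 <- function(reports, drug, term, level = "PT", map = NULL) {
  ids <- unique(reports$caseid)
  a <- b <- cc <- d <- 0L
  for (id in ids) {
    rows <- reports[reports$caseid == id, , drop = FALSE]
    has_drug <- any(!is.na(rows$target_drug) & rows$target_drug == drug)
    pts <- tolower(unlist(rows$pts[1]))
    has_term <- if (level == "PT") {
      tolower(term) %in% pts
    } else {
      socs <- unique(tolower(map$table$soc[map$table$key %in% pts]))
      tolower(term) %in% socs
    }
    if (has_drug && has_term) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_term) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# minimal hand-built reports object for unit tests that do not need the
# full ingestion path
make_reports <- function(caseid, target_drug, pts,
                         event_dt = as.Date(NA),
                         therapy_start = as.Date(NA),
                         event_precision = "day", ...) {
  n <- length(caseid)
  out <- data.frame(
    caseid = as.character(caseid),
    primaryid = paste0(caseid, "1"),
    target_drug = target_drug,
    event_dt = rep_len(as.Date(event_dt), n),
    therapy_start = rep_len(as.Date(therapy_start), n),
    event_precision = rep_len(event_precision, n),
    stringsAsFactors = FALSE, ...)
  out$pts <- if (is.list(pts)) pts else as.list(pts)
  class(out) <- c("faers_reports", "data.frame")
  out
}

# write a small raw DEMO data frame with given (caseid, primaryid,
# fda_dt) triples, other fields defaulted
make_demo <- function(caseid, primaryid, fda_dt, event_dt = NA,
                      sex = "F", age = NA, age_cod = NA, wt = NA,
                      wt_cod = NA, occp_cod = "MD", occr_country = "US") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt),
             event_dt = as.character(event_dt), sex = sex,
             age = as.character(age), age_cod = age_cod,
             wt = as.character(wt), wt_cod = wt_cod,
             occp_cod = occp_cod, occr_country = occr_country,
             stringsAsFactors = FALSE)
}
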