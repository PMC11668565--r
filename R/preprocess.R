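# Case-level cleaning: de-duplication, deleted-case removal, brand-name
# dictionary matching, and assembly of analysis-ready report records.

#' De-duplicate case versions
#'
#' A spontaneous-reporting case accrues several report versions over
#' time; for each `caseid` the version with the latest FDA receipt date
#' (`fda_dt`) is retained, ties broken by the greatest `primaryid`
#' (numerically when ids are numeric, lexicographically otherwise). The
#' rule is deterministic and permutation-invariant. Cases whose versions
#' all lack `fda_dt` keep the greatest `primaryid`, with a warning.
#'
#' @param demo a DEMO data frame (see [read_faers_table()]).
#' @return the retained subset of `demo`, one row per `caseid`, ordered
#'   by `caseid` rank.
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  fda <- demo$fda_dt
  # partial receipt dates still order correctly when right-padded with 0
  padded <- ifelse(!is.na(fda) & grepl("^[0-9]{4,8}$", fda),
                   sprintf("%-8s", fda), NA)
  fda_num <- suppressWarnings(as.numeric(gsub(" ", "0", padded)))
  no_date <- tapply(is.na(fda_num), demo$caseid, all)
  if (any(no_date)) {
    warning("caseid(s) with no parseable fda_dt, keeping greatest primaryid: ",
            paste(utils::head(names(no_date)[no_date], 5), collapse = ", "))
  }
  fda_key <- ifelse(is.na(fda_num), -Inf, fda_num)
  o <- order(xtfrm(demo$caseid), -fda_key, -id_rank(demo$primaryid))
  sorted <- demo[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$caseid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- attr(demo, "rejects")
  out
}

#' Remove deleted cases
#'
#' @param x a data frame with a `caseid` column.
#' @param deleted character vector of deleted case ids (possibly empty).
#' @return `x` without the deleted cases.
#' @export
remove_deleted <- function(x, deleted) {
  if (length(deleted) == 0L) return(x)
  out <- x[!(x$caseid %in% as.character(deleted)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- attr(x, "rejects")
  out
}

#' Match a product string against the brand-name dictionary
#'
#' Matching is case-insensitive after trimming and collapsing internal
#' whitespace, and requires the pattern to occur as a whole word
#' (delimited by non-alphanumerics or string edges) inside the product
#' string, so `"LOTEMAX 0.5% GEL"` matches `Lotemax` but
#' `"DEXAMETHASONE"` matches nothing. The first matching pattern in
#' dictionary order wins.
#'
#' @param drugname character vector of product strings.
#' @param dictionary a drug dictionary (see [drug_dictionary()]).
#' @return character vector of target-drug labels, `NA` where no pattern
#'   matches.
#' @export
#' @examples
#' match_target_drug(c("OZURDEX", "LOTEMAX 0.5% GEL", "DEXAMETHASONE"),
#'                   default_drug_dictionary())
match_target_drug <- function(drugname, dictionary) {
  name <- norm_term(drugname, "upper")
  out <- rep(NA_character_, length(name))
  for (i in seq_len(nrow(dictionary))) {
    pat <- dictionary$pattern[i]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pat)
    rx <- paste0("(^|[^A-Z0-9])", esc, "($|[^A-Z0-9])")
    hit <- is.na(out) & !is.na(name) & grepl(rx, name, perl = TRUE)
    out[hit] <- dictionary$label[i]
  }
  out
}

# reporter occupation -> reporter class (standard FAERS convention)
reporter_class_of <- function(occp_cod) {
  ifelse(occp_cod %in% c("MD", "PH", "OT"), "healthcare professional",
  ifelse(occp_cod %in% c("CN", "LW"), "non-healthcare professional",
         "missing"))
}

.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                 DY = 1 / 365.25, HR = 1 / 8766)
.wt_factor <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)

age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  f <- .age_factor[ifelse(is.na(age_cod), "YR", age_cod)]
  unname(a * ifelse(is.na(f), NA_real_, f))
}

weight_in_kg <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt))
  f <- .wt_factor[ifelse(is.na(wt_cod), "KG", wt_cod)]
  unname(w * ifelse(is.na(f), NA_real_, f))
}

#' Assemble analysis-ready reports from the five cleaned tables
#'
#' Links the de-duplicated DEMO table with DRUG, REAC, THER and OUTC on
#' `primaryid` and emits one record per retained case, plus one record
#' per (case, matched target drug) for cases where a primary-suspect
#' (`role_cod == "PS"`) drug row matches the brand dictionary. A case
#' naming two different target brands as PS contributes to each drug's
#' analysis independently. Cases with no matching PS row are kept with
#' `target_drug = NA`: they form the comparator ("all other drugs") arm
#' of the disproportionality contingency tables.
#'
#' Normalizations applied: age to years (DEC x10, YR x1, MON /12,
#' WK /52.1775, DY /365.25, HR /8766; a missing unit is taken as years),
#' weight to kg (LBS x0.453592, GMS /1000), country upper-cased, reporter
#' occupation collapsed to healthcare / non-healthcare professional.
#' `therapy_start` is the earliest full-precision (8-digit) start date
#' among THER rows pointing at a matched PS drug row; partial start dates
#' are excluded from time-to-onset but the report still participates in
#' signal counting.
#'
#' Cases with no reaction rows are dropped (tallied in
#' `attr(x, "exclusions")`); REAC/THER/OUTC rows referencing unknown
#' primaryids are tallied in `attr(x, "rejects")`.
#'
#' @param demo de-duplicated, deletion-filtered DEMO table.
#' @param drug,reac,ther,outc the remaining raw tables.
#' @param dictionary brand-name dictionary (see [drug_dictionary()]).
#' @return a `faers_reports` data frame, one row per case per matched
#'   target drug (or a single `target_drug = NA` row), with list columns
#'   `pts` and `outcomes`.
#' @export
assemble_reports <- function(demo, drug, reac, ther, outc,
                             dictionary = default_drug_dictionary()) {
  pid <- demo$primaryid
  known <- function(tab, nm) {
    unknown <- !(tab$primaryid %in% pid)
    list(tab = tab[!unknown, , drop = FALSE],
         rejects = if (any(unknown)) data.frame(
           table = nm, primaryid = tab$primaryid[unknown],
           reason = "unknown primaryid", stringsAsFactors = FALSE))
  }
  r <- known(reac, "reac"); t <- known(ther, "ther"); o <- known(outc, "outc")
  d <- known(drug, "drug")
  rejects <- do.call(rbind, Filter(Negate(is.null),
                                   list(r$rejects, t$rejects, o$rejects,
                                        d$rejects)))

  # per-case reaction sets (preserve original PT casing, unique per case)
  pts_by_pid <- lapply(split(r$tab$pt, factor(r$tab$primaryid, levels = pid)),
                       function(p) unique(norm_term(p, "keep")))
  outc_by_pid <- lapply(split(o$tab$outc_cod,
                              factor(o$tab$primaryid, levels = pid)), unique)

  # PS drug rows matched against the dictionary
  drows <- d$tab
  ps <- drows[drows$role_cod == "PS", , drop = FALSE]
  ps$label <- match_target_drug(ps$drugname, dictionary)
  ps <- ps[!is.na(ps$label), , drop = FALSE]

  # earliest full-precision therapy start per (primaryid, label)
  start <- parse_faers_date(t$tab$start_dt)
  tmatch <- merge(
    data.frame(primaryid = t$tab$primaryid, dsg_drug_seq = t$tab$dsg_drug_seq,
               start_date = start$date, full = start$precision == "day",
               stringsAsFactors = FALSE),
    data.frame(primaryid = ps$primaryid, dsg_drug_seq = ps$drug_seq,
               label = ps$label, stringsAsFactors = FALSE),
    by = c("primaryid", "dsg_drug_seq"))
  tmatch <- tmatch[tmatch$full & !is.na(tmatch$start_date), , drop = FALSE]
  start_key <- paste(tmatch$primaryid, tmatch$label, sep = "\r")
  therapy_start <- if (nrow(tmatch)) {
    tapply(tmatch$start_date, start_key, min)
  } else {
    stats::setNames(numeric(0), character(0))
  }

  event <- parse_faers_date(demo$event_dt)
  fda <- parse_faers_date(demo$fda_dt)
  base <- data.frame(
    caseid = demo$caseid,
    primaryid = pid,
    fda_dt = fda$date,
    fda_year = ifelse(fda$precision %in% c("day", "month", "year"),
                      as.integer(substr(demo$fda_dt, 1, 4)), NA_integer_),
    event_dt = event$date,
    event_precision = event$precision,
    sex = ifelse(demo$sex %in% c("F", "M"), demo$sex, NA_character_),
    age_years = age_in_years(demo$age, demo$age_cod),
    weight_kg = weight_in_kg(demo$wt, demo$wt_cod),
    country = ifelse(is.na(demo$occr_country), NA_character_,
                     norm_term(demo$occr_country, "upper")),
    reporter_class = reporter_class_of(demo$occp_cod),
    stringsAsFactors = FALSE)
  base$pts <- unname(pts_by_pid)
  base$outcomes <- unname(outc_by_pid)

  # drop cases with no coded reaction (tallied, never silent)
  no_pt <- lengths(base$pts) == 0L
  exclusions <- c(`no reaction rows` = sum(no_pt))
  base <- base[!no_pt, , drop = FALSE]

  # one row per (case, matched target drug); unmatched cases keep NA
  match_tab <- unique(data.frame(primaryid = ps$primaryid, label = ps$label,
                                 stringsAsFactors = FALSE))
  match_tab <- match_tab[match_tab$primaryid %in% base$primaryid, , drop = FALSE]
  idx_bg <- !(base$primaryid %in% match_tab$primaryid)
  bg <- base[idx_bg, , drop = FALSE]
  bg$target_drug <- NA_character_
  bg$therapy_start <- as.Date(rep(NA_integer_, nrow(bg)), origin = "1970-01-01")
  tg <- base[match(match_tab$primaryid, base$primaryid), , drop = FALSE]
  tg$target_drug <- match_tab$label
  ts_raw <- therapy_start[paste(tg$primaryid, tg$target_drug, sep = "\r")]
  tg$therapy_start <- as.Date(as.numeric(ts_raw), origin = "1970-01-01")

  out <- rbind(tg, bg)
  out <- out[order(xtfrm(out$caseid), xtfrm(out$target_drug)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  attr(out, "exclusions") <- exclusions
  class(out) <- c("faers_reports", "data.frame")
  out
}

#' @export
print.faers_reports <- function(x, ...) {
  n_cases <- length(unique(x$caseid))
  tgt <- x$target_drug[!is.na(x$target_drug)]
  cat("faers_reports:", n_cases, "retained cases;",
      length(unique(x$caseid[!is.na(x$target_drug)])),
      "with a primary-suspect target drug\n")
  if (length(tgt)) {
    print(sort(table(tgt), decreasing = TRUE))
  }
  invisible(x)
}

#' Run the standard cleaning sequence on raw tables
#'
#' Convenience wrapper: de-duplicate DEMO, remove deleted cases,
#' restrict the remaining tables to retained primaryids, and assemble
#' reports.
#'
#' @param tables named list with elements `demo`, `drug`, `reac`,
#'   `ther`, `outc` (as returned by [read_faers_table()] or
#'   [simulate_faers()]).
#' @param deleted character vector of deleted case ids.
#' @param dictionary brand-name dictionary.
#' @return a `faers_reports` data frame (see [assemble_reports()]).
#' @export
clean_reports <- function(tables, deleted = character(),
                          dictionary = default_drug_dictionary()) {
  demo <- remove_deleted(deduplicate_cases(tables$demo), deleted)
  assemble_reports(demo, tables$drug, tables$reac, tables$ther,
                   tables$outc, dictionary)
}
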