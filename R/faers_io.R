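# Reading and writing FAERS-dialect quarterly ASCII tables.
#
# The quarterly files are '$'-delimited with a single header line and no
# quoting or escaping; empty fields are missing values. Partial dates
# (YYYY or YYYYMM) are retained at parse time so each downstream stage
# can apply its own precision requirement.

.faers_schemas <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex",
           "age", "age_cod", "wt", "wt_cod", "occp_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "route",
           "dose_form"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "outc_cod")
)

.role_codes <- c("PS", "SS", "C", "I")
.outc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

# split one or more '$'-delimited lines, preserving trailing empties
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

#' Read one FAERS-dialect quarterly ASCII table
#'
#' Parses a `$`-delimited file with a header line into a data frame.
#' Required columns for the declared table kind must be present (extra
#' columns are tolerated and ignored). Empty fields become `NA`. Lines
#' whose field count does not match the header, or whose closed-set codes
#' are invalid, are never silently dropped: they are collected into a
#' rejects report attached as `attr(x, "rejects")` (columns `line`,
#' `reason`).
#'
#' @param path path to the ASCII file.
#' @param table table kind, one of `"demo"`, `"drug"`, `"reac"`,
#'   `"ther"`, `"outc"`.
#' @return a `data.frame` with the schema columns for `table` (character
#'   columns), with attribute `rejects`.
#' @seealso [write_faers_table()], [parse_faers_date()]
#' @export
read_faers_table <- function(path, table = names(.faers_schemas)) {
  table <- match.arg(table)
  schema <- .faers_schemas[[table]]
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- split_dollar(lines[1])[[1]]
  header <- trimws(tolower(header))
  missing_cols <- setdiff(schema, header)
  if (length(missing_cols) > 0L) {
    stop("schema error in ", basename(path), " (", table,
         "): missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1]
  rejects <- data.frame(line = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  if (length(body) == 0L) {
    out <- as.data.frame(setNames(rep(list(character()), length(schema)),
                                  schema), stringsAsFactors = FALSE)
    attr(out, "rejects") <- rejects
    return(out)
  }
  fields <- split_dollar(body)
  nf <- lengths(fields)
  ok <- nf == length(header)
  if (any(!ok)) {
    rejects <- rbind(rejects, data.frame(
      line = which(!ok) + 1L,
      reason = sprintf("expected %d fields, found %d",
                       length(header), nf[!ok]),
      stringsAsFactors = FALSE))
  }
  keep <- fields[ok]
  mat <- matrix(unlist(keep, use.names = FALSE) %||% character(0),
                ncol = length(header), byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- header
  out <- out[, schema, drop = FALSE]
  out[] <- lapply(out, function(col) {
    col <- trimws(col)
    col[col == ""] <- NA_character_
    col
  })
  line_no <- which(ok) + 1L
  bad <- validate_rows(out, table)
  if (any(bad$drop)) {
    rejects <- rbind(rejects, data.frame(
      line = line_no[bad$drop], reason = bad$reason[bad$drop],
      stringsAsFactors = FALSE))
    out <- out[!bad$drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  rejects <- rejects[order(rejects$line), , drop = FALSE]
  rownames(rejects) <- NULL
  attr(out, "rejects") <- rejects
  out
}

# row-level validation against the closed code sets and key invariants
validate_rows <- function(x, table) {
  n <- nrow(x)
  drop <- logical(n)
  reason <- character(n)
  flag <- function(idx, why) {
    idx <- idx & !drop
    drop[idx] <<- TRUE
    reason[idx] <<- why
  }
  if ("primaryid" %in% names(x)) {
    flag(is.na(x$primaryid), "empty primaryid")
  }
  if (table == "demo") {
    flag(duplicated(x$primaryid) & !is.na(x$primaryid),
         "duplicate primaryid within file")
  }
  if (table == "drug") {
    flag(!is.na(x$role_cod) & !(x$role_cod %in% .role_codes),
         "role_cod outside {PS, SS, C, I}")
    flag(is.na(x$role_cod), "empty role_cod")
    flag(!drop & duplicated(paste(x$primaryid, x$drug_seq, sep = "\r")),
         "duplicate (primaryid, drug_seq)")
  }
  if (table == "reac") flag(is.na(x$pt), "empty pt")
  if (table == "outc") {
    flag(!is.na(x$outc_cod) & !(x$outc_cod %in% .outc_codes),
         "outc_cod outside closed set")
    flag(is.na(x$outc_cod), "empty outc_cod")
  }
  list(drop = drop, reason = reason)
}

#' Write a FAERS-dialect quarterly ASCII table
#'
#' Inverse of [read_faers_table()]: writes a header line and `$`-delimited
#' rows, with `NA` rendered as an empty field. The dialect has no quoting,
#' so fields containing `$` or newlines are an error.
#'
#' @param x data frame with (at least) the schema columns of `table`.
#' @param path output path.
#' @param table table kind (see [read_faers_table()]).
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, table = names(.faers_schemas)) {
  table <- match.arg(table)
  schema <- .faers_schemas[[table]]
  miss <- setdiff(schema, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, schema, drop = FALSE]
  cells <- lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  if (any(vapply(cells, function(col) any(grepl("[$\n\r]", col)), logical(1)))) {
    stop("fields may not contain '$' or newlines in the FAERS dialect")
  }
  lines <- c(paste(schema, collapse = "$"),
             if (nrow(x)) do.call(paste, c(cells, sep = "$")))
  writeLines(lines, path)
  invisible(path)
}

#' Parse FAERS date strings, keeping partial-date precision
#'
#' FAERS dates appear as `YYYYMMDD`, `YYYYMM`, or `YYYY`. Full dates are
#' converted to `Date`; shorter forms are retained as partial markers so
#' downstream stages can enforce their own precision requirement;
#' non-digit strings and impossible dates (month 13, day 32) are flagged
#' invalid and treated as missing downstream.
#'
#' @param x character vector of raw date fields (`NA`/empty allowed).
#' @return a `data.frame` with columns `raw`, `date` (`Date`, `NA` unless
#'   full precision and valid) and `precision` (one of `"day"`,
#'   `"month"`, `"year"`, `"missing"`, `"invalid"`).
#' @export
#' @examples
#' parse_faers_date(c("20230105", "202301", "2023", "", "20231301"))
parse_faers_date <- function(x) {
  raw <- as.character(x)
  n <- length(raw)
  precision <- rep("invalid", n)
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  blank <- is.na(raw) | trimws(raw) == ""
  precision[blank] <- "missing"
  digits <- !blank & grepl("^[0-9]+$", raw)
  len <- nchar(raw)
  y4 <- digits & len == 4L
  precision[y4] <- "year"
  y6 <- digits & len == 6L
  if (any(y6)) {
    mon <- as.integer(substr(raw[y6], 5L, 6L))
    okm <- mon >= 1L & mon <= 12L
    precision[y6][okm] <- "month"
  }
  y8 <- digits & len == 8L
  if (any(y8)) {
    d <- as.Date(raw[y8], format = "%Y%m%d")
    okd <- !is.na(d)
    precision[y8][okd] <- "day"
    date[y8][okd] <- d[okd]
  }
  data.frame(raw = raw, date = date, precision = precision,
             stringsAsFactors = FALSE)
}

#' Read a MedDRA-like PT to HLT/HLGT/SOC mapping table
#'
#' The mapping interface is a TSV with columns `pt`, `hlt`, `hlgt`,
#' `soc`. A preferred term may map to more than one system organ class
#' (one row each); lookups are case-insensitive after whitespace
#' normalization; duplicated `(pt, soc)` rows are collapsed. The package
#' never ships licensed MedDRA content: only the interface plus a toy
#' hierarchy used by the synthetic generator ([toy_meddra()]).
#'
#' @param path path to the TSV file.
#' @return an object of class `meddra_map`.
#' @seealso [meddra_socs()], [write_meddra_map()], [toy_meddra()]
#' @export
read_meddra_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(x) <- tolower(names(x))
  need <- c("pt", "hlt", "hlgt", "soc")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("mapping table missing column(s): ",
                         paste(miss, collapse = ", "))
  meddra_map(x[, need])
}

#' Construct a MedDRA-like mapping object from a data frame
#'
#' @param x data frame with columns `pt`, `hlt`, `hlgt`, `soc`.
#' @return object of class `meddra_map`: the normalized mapping table
#'   plus a lowercase lookup key.
#' @export
meddra_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$pt <- norm_term(x$pt, "keep")
  x$soc <- norm_term(x$soc, "keep")
  x$hlt <- norm_term(x$hlt, "keep")
  x$hlgt <- norm_term(x$hlgt, "keep")
  if (any(!nzchar(x$pt))) stop("mapping contains empty PT strings")
  if (any(!nzchar(x$soc))) {
    bad <- unique(x$pt[!nzchar(x$soc)])
    stop("PT mapped to zero SOCs: ", paste(bad, collapse = ", "))
  }
  x$key <- tolower(x$pt)
  x <- x[!duplicated(paste(x$key, tolower(x$soc), sep = "\r")), , drop = FALSE]
  rownames(x) <- NULL
  structure(list(table = x), class = "meddra_map")
}

#' @export
print.meddra_map <- function(x, ...) {
  cat("MedDRA-like mapping:", length(unique(x$table$key)), "PTs,",
      length(unique(x$table$soc)), "SOCs\n")
  invisible(x)
}

#' Look up the system organ class(es) of a preferred term
#'
#' @param map a `meddra_map`.
#' @param pt character vector of preferred terms.
#' @return for length-1 `pt`, a character vector of SOCs (length 0 when
#'   unmapped); otherwise a list of such vectors.
#' @export
meddra_socs <- function(map, pt) {
  stopifnot(inherits(map, "meddra_map"))
  key <- tolower(norm_term(pt, "keep"))
  res <- lapply(key, function(k) unique(map$table$soc[map$table$key == k]))
  if (length(res) == 1L) res[[1]] else res
}

#' Write a MedDRA-like mapping table to TSV
#'
#' @param map a `meddra_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meddra_map <- function(map, path) {
  stopifnot(inherits(map, "meddra_map"))
  utils::write.table(map$table[, c("pt", "hlt", "hlgt", "soc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a brand-name drug dictionary
#'
#' TSV with columns `pattern` (brand-name string searched for as a whole
#' word inside product text) and `label` (target-drug name it maps to).
#' Dictionary order matters: the first matching pattern wins.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with columns `pattern`, `label`.
#' @seealso [default_drug_dictionary()], [match_target_drug()]
#' @export
read_drug_dictionary <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(x) <- tolower(names(x))
  if (!all(c("pattern", "label") %in% names(x))) {
    stop("drug dictionary must have columns 'pattern' and 'label'")
  }
  drug_dictionary(x$pattern, x$label)
}

#' Construct and validate a drug dictionary
#'
#' @param pattern character vector of brand-name patterns.
#' @param label character vector of target-drug labels (recycled if
#'   length 1).
#' @return a validated `data.frame` with columns `pattern`, `label`.
#' @export
drug_dictionary <- function(pattern, label = pattern) {
  pattern <- norm_term(pattern, "upper")
  label <- norm_term(label, "keep")
  if (any(!nzchar(pattern))) stop("empty pattern in drug dictionary")
  dup <- duplicated(pattern)
  if (any(dup)) {
    conflicting <- tapply(label, pattern, function(l) length(unique(l)) > 1)
    if (any(conflicting)) {
      stop("pattern mapped to multiple labels: ",
           paste(names(conflicting)[conflicting], collapse = ", "))
    }
  }
  out <- data.frame(pattern = pattern[!dup], label = label[!dup],
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_dictionary", "data.frame")
  out
}

#' The ophthalmic-corticosteroid brand-name dictionary
#'
#' Brand names of corticosteroids commonly used in ophthalmology, used to
#' retrieve target reports by product-name search (generic substance
#' names are deliberately absent: retrieval by substance pulls in
#' non-ophthalmic use).
#'
#' @return a drug dictionary (see [drug_dictionary()]).
#' @export
default_drug_dictionary <- function() {
  brands <- c("Ozurdex", "Maxidex", "Dexapar", "Dexachlor", "Pred Mild",
              "Orchapred", "Kapimox-P", "Predsol", "Trivaris", "Triesence",
              "Retisert", "Iluvien", "Lotemax", "Flucon", "FML",
              "Visipred", "Diflustero", "Durezol")
  drug_dictionary(pattern = brands, label = brands)
}

#' Write a drug dictionary to TSV
#' @param dict a drug dictionary.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_dictionary <- function(dict, path) {
  utils::write.table(as.data.frame(dict)[, c("pattern", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a deleted-case list
#'
#' Plain text, one case identifier per line; blank lines ignored.
#'
#' @param path path to the file.
#' @return character vector of case ids (possibly empty).
#' @export
read_deleted_cases <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a rejects report
#'
#' @param rejects data frame with columns `line`, `reason` (as attached
#'   by [read_faers_table()]), plus an optional `table` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(rejects, path) {
  utils::write.table(rejects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
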