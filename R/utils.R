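# Small shared helpers.

#' Normalize a free-text term or product string
#'
#' Trims leading/trailing whitespace and collapses internal runs of
#' whitespace to a single space. Used for case-insensitive matching of
#' MedDRA terms and product names.
#'
#' @param x character vector.
#' @param case one of `"lower"`, `"upper"`, `"keep"`.
#' @return character vector of the same length.
#' @keywords internal
norm_term <- function(x, case = c("lower", "upper", "keep")) {
  case <- match.arg(case)
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  switch(case, lower = tolower(x), upper = toupper(x), keep = x)
}

#' Round half away from zero
#'
#' Plain half-up rounding (0.05 -> 0.1 at one decimal), as used when
#' printing percentages in cohort tables. Base `round()` rounds half to
#' even, which does not reproduce conventionally printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 645 / 1784, 1) # 36.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against 28.349999... representations of x.x5
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rank helper: numeric ordering when every id is purely numeric,
# lexicographic otherwise (FAERS primaryids are numeric in practice)
id_rank <- function(x) {
  x <- as.character(x)
  if (all(grepl("^[0-9]+$", x[!is.na(x)]))) {
    # avoid integer overflow on long ids
    suppressWarnings(as.numeric(x))
  } else {
    xtfrm(x)
  }
}
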