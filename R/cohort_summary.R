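# Cohort characteristic tables: counts and half-up percentages per drug.

.age_band_levels <- c("<=17", "18-64", "65-85", ">=86", "missing")
.weight_band_levels <- c("<50 kg", "50-100 kg", ">100 kg", "missing")
.outcome_levels <- c(DE = "Death", LT = "Life-threatening",
                     HO = "Hospitalization", DS = "Disability",
                     CA = "Congenital anomaly",
                     RI = "Required intervention", OT = "Others")

# banding uses completed years; boundary ages land in the band whose
# label contains them (17 -> <=17, 65 -> 65-85)
age_band <- function(age_years) {
  a <- floor(age_years)
  ifelse(is.na(a), "missing",
  ifelse(a <= 17, "<=17",
  ifelse(a <= 64, "18-64",
  ifelse(a <= 85, "65-85", ">=86"))))
}

weight_band <- function(weight_kg) {
  w <- weight_kg
  ifelse(is.na(w), "missing",
  ifelse(w < 50, "<50 kg",
  ifelse(w <= 100, "50-100 kg", ">100 kg")))
}

#' Summarize one cohort characteristic per target drug
#'
#' Produces the count and percentage of each level of a report
#' characteristic, per target drug. All categories except `outcome`
#' partition reports, so within a drug their counts sum to the drug's
#' report total and the percentage denominator is that total. A report
#' may carry several outcome codes, so `outcome` counts outcome
#' occurrences (reports with no code contribute one `Missing`
#' occurrence) and percentages use the occurrence total as denominator.
#' Percentages are rounded half-up to one decimal.
#'
#' @param reports a `faers_reports` data frame.
#' @param category one of `"sex"`, `"age_band"`, `"weight_band"`,
#'   `"outcome"`, `"reporter"`, `"year"`, `"country"`.
#' @param drugs target-drug labels; defaults to all present.
#' @return a data frame with columns `drug`, `level`, `count`,
#'   `percentage`.
#' @export
summarize_cohort <- function(reports,
                             category = c("sex", "age_band", "weight_band",
                                          "outcome", "reporter", "year",
                                          "country"),
                             drugs = NULL) {
  category <- match.arg(category)
  drugs <- drugs %||% sort(unique(
    reports$target_drug[!is.na(reports$target_drug)]))
  rows <- lapply(drugs, function(dr) {
    x <- reports[!is.na(reports$target_drug) & reports$target_drug == dr, ,
                 drop = FALSE]
    if (category == "outcome") {
      occ <- unlist(lapply(x$outcomes, function(o) {
        if (length(o) == 0L) "Missing" else
          unname(.outcome_levels[o])
      }), use.names = FALSE)
      levels_all <- c(unname(.outcome_levels), "Missing")
      counts <- table(factor(occ, levels = levels_all))
      denom <- length(occ)
    } else {
      vals <- switch(category,
        sex = ifelse(is.na(x$sex), "Unknown",
                     ifelse(x$sex == "F", "Female", "Male")),
        age_band = age_band(x$age_years),
        weight_band = weight_band(x$weight_kg),
        reporter = x$reporter_class,
        year = ifelse(is.na(x$fda_year), "missing",
                      as.character(x$fda_year)),
        country = ifelse(is.na(x$country), "Unknown", x$country))
      levels_all <- switch(category,
        sex = c("Female", "Male", "Unknown"),
        age_band = .age_band_levels,
        weight_band = .weight_band_levels,
        reporter = c("healthcare professional",
                     "non-healthcare professional", "missing"),
        sort(unique(vals)))
      counts <- table(factor(vals, levels = levels_all))
      denom <- nrow(x)
    }
    pct <- if (denom > 0) round_half_up(100 * as.integer(counts) / denom, 1)
           else rep(0, length(counts))
    data.frame(drug = dr, level = names(counts),
               count = as.integer(counts), percentage = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Country distribution of a drug's reports
#'
#' Counts per (normalized, upper-cased) country string; missing country
#' grouped as `"Unknown"`. Counts sum to the drug's report total.
#'
#' @param reports a `faers_reports` data frame.
#' @param drug target-drug label.
#' @return named integer vector of counts, decreasing.
#' @export
country_distribution <- function(reports, drug) {
  x <- reports[!is.na(reports$target_drug) & reports$target_drug == drug, ,
               drop = FALSE]
  ctry <- ifelse(is.na(x$country), "Unknown", x$country)
  sort(table(ctry), decreasing = TRUE)
}
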