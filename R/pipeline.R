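# End-to-end orchestration: ingest -> dedup/filter -> signals (PT, SOC)
# -> time-to-onset -> demographics -> overlap, with every artifact
# emitted as a TSV so that figures are views of files, never of
# in-memory state. Reruns on identical inputs are byte-identical (no
# timestamps in any output).

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full signal-mining pipeline on a FAERS-dialect directory
#'
#' Expects `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`
#' in `input` (as written by [simulate_faers()] or converted from a real
#' quarter), plus optional `deleted_cases.txt`, a drug dictionary and a
#' MedDRA-like map. Without a map, SOC-level outputs are skipped with a
#' warning and PT-level outputs are still produced.
#'
#' @param input directory containing the ASCII tables.
#' @param out output directory for the TSV artifacts (created).
#' @param drug_dict path to a drug-dictionary TSV, or a dictionary
#'   object; defaults to `drug_dictionary.tsv` in `input` if present,
#'   else [default_drug_dictionary()].
#' @param meddra_map path to a mapping TSV or a `meddra_map`; defaults
#'   to `meddra_map.tsv` in `input` if present, else `NULL` (PT level
#'   only).
#' @param deleted path to a deleted-case list; defaults to
#'   `deleted_cases.txt` in `input` if present.
#' @param mode screening mode used for the overlap artifact:
#'   `"all_four"` or `"ror_only"`.
#' @param priors BCPNN priors.
#' @param correct zero-cell policy toggle.
#' @param verbose log stage progress to stderr.
#' @return invisibly, a named character vector of artifact paths
#'   (class `pipeline_manifest`).
#' @export
run_pipeline <- function(input, out,
                         drug_dict = NULL, meddra_map = NULL,
                         deleted = NULL,
                         mode = c("all_four", "ror_only"),
                         priors = bcpnn_priors(), correct = TRUE,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message("[faersig] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  pick <- function(given, default_file, reader, fallback = NULL) {
    if (!is.null(given) && !is.character(given)) return(given)
    path <- if (is.character(given)) given else {
      p <- file.path(input, default_file)
      if (file.exists(p)) p else NA
    }
    if (is.na(path)) fallback else reader(path)
  }
  dict <- pick(drug_dict, "drug_dictionary.tsv", read_drug_dictionary,
               default_drug_dictionary())
  map <- pick(meddra_map, "meddra_map.tsv", read_meddra_map, NULL)
  del <- pick(deleted, "deleted_cases.txt", read_deleted_cases, character())

  say("ingest")
  tables <- stage("ingest", {
    stats::setNames(lapply(c("demo", "drug", "reac", "ther", "outc"),
      function(k) {
        read_faers_table(file.path(input, paste0(toupper(k), ".txt")), k)
      }), c("demo", "drug", "reac", "ther", "outc"))
  })

  say("dedup/filter/assemble")
  reports <- stage("preprocess", clean_reports(tables, del, dict))
  drugs <- sort(unique(reports$target_drug[!is.na(reports$target_drug)]))

  artifacts <- c()
  add <- function(name, path) {
    artifacts[[name]] <<- path
  }

  rej <- do.call(rbind, Filter(Negate(is.null), lapply(
    names(tables), function(k) {
      r <- attr(tables[[k]], "rejects")
      if (!is.null(r) && nrow(r)) cbind(table = k, r)
    })))
  add("rejects", write_tsv(
    rej %||% data.frame(table = character(), line = integer(),
                        reason = character()),
    file.path(out, "rejects.tsv")))

  say("signals at PT level")
  pt_screens <- stage("signals_pt", screen_all(
    reports, drugs = drugs, level = "PT", priors = priors,
    correct = correct))
  pt_tab <- do.call(rbind, lapply(names(pt_screens), function(dr) {
    cbind(drug = dr, as.data.frame(pt_screens[[dr]]))
  }))
  add("signals_pt", write_tsv(pt_tab, file.path(out, "signals_pt.tsv")))

  if (!is.null(map)) {
    say("signals at SOC level")
    soc_screens <- stage("signals_soc", screen_all(
      reports, drugs = drugs, level = "SOC", map = map, priors = priors,
      correct = correct))
    soc_tab <- do.call(rbind, lapply(names(soc_screens), function(dr) {
      cbind(drug = dr, as.data.frame(soc_screens[[dr]]))
    }))
    add("signals_soc", write_tsv(soc_tab, file.path(out, "signals_soc.tsv")))
    m <- stage("soc_matrix", soc_ror_matrix(reports, drugs = drugs,
                                            map = map, priors = priors,
                                            correct = correct))
    add("soc_ror_matrix", write_tsv(
      data.frame(drug = rownames(m), m, check.names = FALSE),
      file.path(out, "soc_ror_matrix.tsv")))
  } else {
    warning("no MedDRA-like map supplied: SOC-level outputs skipped")
  }

  say("time to onset")
  add("tto_summary", write_tsv(stage("tto", tto_summary(reports, drugs)),
                               file.path(out, "tto_summary.tsv")))

  say("demographics")
  for (cat in c("sex", "age_band", "weight_band", "outcome", "reporter",
                "year")) {
    add(paste0("demographics_", cat), write_tsv(
      stage("demographics", summarize_cohort(reports, cat, drugs)),
      file.path(out, paste0("demographics_", cat, ".tsv"))))
  }
  ctry <- do.call(rbind, lapply(drugs, function(dr) {
    tab <- country_distribution(reports, dr)
    data.frame(drug = dr, country = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  add("country_distribution", write_tsv(
    ctry %||% data.frame(drug = character(), country = character(),
                         count = integer()),
    file.path(out, "country_distribution.tsv")))

  if (length(drugs) >= 2) {
    say("overlap")
    ov <- stage("overlap", common_terms(pt_screens, mode = mode))
    add("overlap_counts", write_tsv(data.frame(
      combination = names(ov$region_counts),
      count = as.integer(ov$region_counts), stringsAsFactors = FALSE),
      file.path(out, "overlap_counts.tsv")))
    add("common_terms", write_tsv(data.frame(
      term = sort(ov$common), stringsAsFactors = FALSE),
      file.path(out, "common_terms.tsv")))
  }

  # run metadata: stable across reruns of identical inputs (no clock)
  meta <- data.frame(
    key = c("package", "version", "r_version", "mode", "zero_cell_correct",
            "input", "n_retained_cases", "n_target_drugs",
            paste0("md5_", c("demo", "drug", "reac", "ther", "outc"))),
    value = c("faersig", as.character(utils::packageVersion("faersig")),
              paste(R.version$major, R.version$minor, sep = "."), mode,
              as.character(correct), normalizePath(input),
              as.character(length(unique(reports$caseid))),
              as.character(length(drugs)),
              unname(tools::md5sum(file.path(input, paste0(
                c("DEMO", "DRUG", "REAC", "THER", "OUTC"), ".txt"))))),
    stringsAsFactors = FALSE)
  add("run_info", write_tsv(meta, file.path(out, "run_info.tsv")))

  say("done: ", length(artifacts), " artifacts in ", out)
  invisible(structure(unlist(artifacts), class = "pipeline_manifest"))
}

#' Render figures from pipeline TSV artifacts
#'
#' Figures are re-derived from the emitted TSVs only (no in-memory
#' state): a drug-by-SOC ROR heatmap on a log2 color scale and an
#' overlap figure (per-combination bar chart of the Venn regions).
#' Empty tables yield a placeholder figure with a warning.
#'
#' @param out the pipeline output directory (holding the TSVs); figures
#'   are written there as PNG.
#' @param width,height device size in pixels.
#' @return invisibly, character vector of figure paths.
#' @export
plot_outputs <- function(out, width = 900, height = 600) {
  figs <- character()
  placeholder <- function(path, msg) {
    grDevices::png(path, width, height)
    on.exit(grDevices::dev.off())
    graphics::plot.new()
    graphics::text(0.5, 0.5, msg)
    warning(msg)
    path
  }

  mat_path <- file.path(out, "soc_ror_matrix.tsv")
  fig1 <- file.path(out, "soc_ror_heatmap.png")
  if (file.exists(mat_path)) {
    tab <- utils::read.delim(mat_path, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$drug
    if (nrow(m) && ncol(m) && any(is.finite(m))) {
      grDevices::png(fig1, width, height)
      lm <- log2(m)
      lm[!is.finite(lm)] <- NA
      graphics::par(mar = c(10, 8, 3, 6))
      pal <- grDevices::hcl.colors(25, "Blue-Red 2")
      rng <- max(abs(lm), na.rm = TRUE)
      graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(lm),
                      col = pal, zlim = c(-rng, rng), axes = FALSE,
                      xlab = "", ylab = "",
                      main = "Reporting odds ratio by system organ class (log2)")
      graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2,
                     cex.axis = 0.8)
      graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1)
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        if (is.finite(m[i, j])) {
          graphics::text(j, i, sprintf("%.2f", m[i, j]), cex = 0.7)
        }
      }
      grDevices::dev.off()
    } else {
      placeholder(fig1, "SOC ROR matrix is empty")
    }
    figs <- c(figs, fig1)
  }

  ov_path <- file.path(out, "overlap_counts.tsv")
  fig2 <- file.path(out, "term_overlap.png")
  if (file.exists(ov_path)) {
    ov <- utils::read.delim(ov_path)
    if (nrow(ov)) {
      grDevices::png(fig2, width, height)
      graphics::par(mar = c(4, 18, 3, 2))
      top <- utils::head(ov[order(-ov$count), , drop = FALSE], 20)
      graphics::barplot(rev(top$count), names.arg = rev(top$combination),
                        horiz = TRUE, las = 1, cex.names = 0.6,
                        xlab = "flagged terms in region",
                        main = "Common signal terms across drugs")
      grDevices::dev.off()
    } else {
      placeholder(fig2, "overlap table is empty")
    }
    figs <- c(figs, fig2)
  }
  invisible(figs)
}
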