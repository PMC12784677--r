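#' Run the full hybrid-expression analysis pipeline
#'
#' Orchestrates counts -> median-of-ratios normalization -> three pairwise
#' NB differential-expression comparisons (hybrid over parent1, hybrid
#' over parent2, parent2 over parent1; `log2fc` of the second-named group
#' over the first) -> Venn intersection -> mid-parent-value inheritance
#' classification -> over-representation of the non-additive genes against
#' each supplied GMT collection. The run is deterministic given its
#' inputs; size factors are computed once on the full matrix and reused in
#' every comparison.
#'
#' @param counts Count matrix or path to a counts TSV.
#' @param design Design data.frame or path to a design CSV; exactly one
#'   group per role parent1/parent2/hybrid.
#' @param gmt Optional: a collection from [read_gmt()], a path, or a named
#'   list of either (e.g. `list(go = "go.gmt", kegg = "kegg.gmt")`); each
#'   collection is tested and BH-corrected separately.
#' @param lfc_threshold,q_threshold DEG thresholds (strict).
#' @param conserved_threshold Conserved band, log2 units.
#' @param mpv_alpha Significance level of the MPV deviation test.
#' @param min_set_size,max_set_size Term-size filters for enrichment.
#' @param pseudocount Fold-change pseudocount for [de_test()].
#' @param outdir Optional directory: when given, [write_report()] is
#'   called on the result.
#' @param quiet Suppress stage messages.
#' @return A `RunReport` list: `comparisons` (per-comparison DEG counts
#'   and orientations), `venn` (three-way intersection count),
#'   `classification` (summary from [summarize_patterns()], or NULL with
#'   a warning when no gene is classifiable), `calls`, `de` (the three DE
#'   tables), `enrichment` (named list of tables), `thresholds`,
#'   `provenance`.
#' @export
run_pipeline <- function(counts, design, gmt = NULL,
                         lfc_threshold = 1, q_threshold = 0.05,
                         conserved_threshold = 1.25, mpv_alpha = 0.05,
                         min_set_size = 5, max_set_size = 2000,
                         pseudocount = 1, outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[midparent] ", ...)
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design)) design <- read_sample_design(design)
  validate_counts(counts)
  validate_design(design, counts)
  roles <- role_groups(design)
  design <- design[design$sample %in% colnames(counts), , drop = FALSE]

  say("size factors (", ncol(counts), " samples)")
  sf <- size_factors(counts)

  run_de <- function(ga, gb) {
    say("DE: ", gb, " vs ", ga)
    de_test(counts, design, group_a = ga, group_b = gb,
            pseudocount = pseudocount, sf = sf,
            lfc_threshold = lfc_threshold, q_threshold = q_threshold)
  }
  de_h_p1 <- run_de(roles[["parent1"]], roles[["hybrid"]])
  de_h_p2 <- run_de(roles[["parent2"]], roles[["hybrid"]])
  de_p1_p2 <- run_de(roles[["parent1"]], roles[["parent2"]])
  de <- list(hybrid_vs_parent1 = de_h_p1,
             hybrid_vs_parent2 = de_h_p2,
             parent2_vs_parent1 = de_p1_p2)

  deg_sets <- lapply(de, call_degs, lfc_threshold = lfc_threshold,
                     q_threshold = q_threshold)
  venn <- length(Reduce(intersect, deg_sets))
  stopifnot(venn <= min(lengths(deg_sets)))

  say("classification (universe: union of DEGs)")
  calls <- classify_all(counts, design, de_h_p1, de_h_p2, de_p1_p2,
                        alpha = mpv_alpha,
                        conserved_threshold = conserved_threshold)
  classification <- NULL
  if (nrow(calls) == 0L) {
    warning("no DEG in any comparison; classification summary is empty")
  } else {
    classification <- summarize_patterns(calls)
  }

  enrichment <- NULL
  if (!is.null(gmt)) {
    collections <- if (is.list(gmt) && is.null(attr(gmt, "term_names")))
      gmt else list(sets = gmt)
    collections <- lapply(collections, function(g)
      if (is.character(g)) read_gmt(g) else g)
    universe <- rownames(counts)[rowSums(counts > 0) >= 1L]
    query <- intersect(calls$gene_id[calls$additivity == "non-additive"],
                       universe)
    if (length(query) == 0L) {
      warning("no non-additive gene in the expressed universe; ",
              "enrichment skipped")
    } else {
      say("enrichment of ", length(query), " non-additive genes against ",
          length(collections), " collection(s)")
      enrichment <- lapply(collections, function(g)
        enrich(query, universe, g, min_size = min_set_size,
               max_size = max_set_size, q_threshold = q_threshold))
    }
  }

  report <- list(
    comparisons = lapply(names(de), function(nm)
      list(comparison = nm, n_deg = length(deg_sets[[nm]]))),
    venn = list(intersection = venn),
    classification = classification,
    calls = calls,
    de = de,
    enrichment = enrichment,
    thresholds = list(lfc = lfc_threshold, q = q_threshold,
                      conserved = conserved_threshold,
                      mpv_alpha = mpv_alpha,
                      min_set_size = min_set_size,
                      max_set_size = max_set_size,
                      pseudocount = pseudocount),
    provenance = list(package = "midparent",
                      version = as.character(utils::packageVersion("midparent")),
                      roles = as.list(roles)))
  names(report$comparisons) <- names(de)
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# summary portion of a report: everything serialized to report.json
.report_summary <- function(report) {
  report[c("comparisons", "venn", "classification", "enrichment",
           "thresholds", "provenance")]
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (counts, classification summary, enrichment tables,
#' thresholds, provenance) plus one TSV per table: the three DE tables and
#' the inheritance calls. Files are written to a temporary name and
#' renamed, so re-running overwrites atomically.
#'
#' @param report List from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    if (!file.rename(tmp, path)) stop("cannot write ", path)
    path
  }
  files <- atomically(file.path(outdir, "report.json"), function(tmp)
    jsonlite::write_json(.report_summary(report), tmp,
                         auto_unbox = TRUE, digits = NA, null = "null"))
  for (nm in names(report$de))
    files <- c(files, atomically(file.path(outdir, paste0("de_", nm, ".tsv")),
                                 function(tmp) write_de_table(report$de[[nm]], tmp)))
  if (!is.null(report$calls) && nrow(report$calls))
    files <- c(files, atomically(file.path(outdir, "inheritance_calls.tsv"),
                                 function(tmp) write_inheritance_calls(report$calls, tmp)))
  for (nm in names(report$enrichment))
    files <- c(files,
               atomically(file.path(outdir, paste0("enrichment_", nm, ".tsv")),
                          function(tmp) write_enrichment(report$enrichment[[nm]], tmp)))
  invisible(files)
}

#' Read back a pipeline report JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return List mirroring the summary portion of the report.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
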