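## End-to-end orchestration: QC -> background rate -> binomial detection ->
## filter cascade -> A-to-I annotation -> cohort analytics.

#' Run the detection pipeline on a cohort
#'
#' Deterministic given inputs and config. Cells failing the
#' uniquely-mapped-bases gate are dropped up front; the remaining cells go
#' through background-rate estimation, per-site binomial detection,
#' the eight-filter cascade, the A-to-I retention rule and annotation, and
#' the cohort-level summaries. Every filtered site records which filter
#' removed it; the summary reports per-stage attrition (sites in -> out).
#'
#' @param pileup pooled pileup columns for all cells.
#' @param meta cell metadata: `cell_id`, `embryo_id`, `stage`,
#'   `mapped_bases` (and optionally `aligned_bases` for the background-rate
#'   denominator).
#' @param ann annotation bundle: `reference`, `alu`, `simple_repeats`,
#'   `splice_sites`, `snps`, `catalogue`, `genes`, `mirna_targets`.
#' @param config a [pipeline_config()].
#' @param realign optional realignment inputs (see [run_filter_cascade()]).
#' @param out_dir if given, per-stage TSV artifacts are written there.
#' @return list: `meta` (QC-passing cells), `rates`, `candidates`
#'   (verdict-augmented), `attrition`, `editome`, `coding`, `cells`
#'   (per-cell summaries with editing level), `matrix`, `stage_summary`.
#' @export
run_pipeline <- function(pileup, meta, ann, config = pipeline_config(),
                         realign = NULL, out_dir = NULL) {
  meta <- as.data.table(meta)
  assert_that(all(c("cell_id", "embryo_id", "stage", "mapped_bases") %in%
                    names(meta)), "incomplete cell metadata")
  keep <- qc_cell(meta$mapped_bases, config$min_uniquely_mapped_bases)
  if (!any(keep)) stopf("no cell passes the mapped-bases QC gate")
  meta <- meta[keep]
  pileup <- as.data.table(pileup)[cell_id %in% meta$cell_id]

  rates <- background_rates(pileup, meta,
                            exclude_high_freq = config$exclude_high_freq)
  candidates <- call_candidates(pileup, rates, config)
  casc <- run_filter_cascade(candidates, meta, ann, config, realign = realign)
  retained <- casc$candidates[retained == TRUE]
  annres <- annotate_editome(retained, ann, config)
  editome <- annres$editome

  cells <- cell_editomes(editome, meta, candidates = candidates)
  mat <- NULL
  if (nrow(editome) > 0)
    mat <- build_editing_matrix(editome, pileup, meta$cell_id,
                                min_depth = config$min_depth)
  stage_summary <- stage_summaries(cells)

  attrition <- rbind(
    data.table(stage = "candidate_mismatch_sites",
               sites_out = nrow(candidates)),
    casc$attrition,
    data.table(stage = "a2i_retention", sites_out = nrow(editome)))

  out <- list(meta = meta, rates = rates, candidates = casc$candidates,
              attrition = attrition, editome = editome,
              coding = annres$coding, cells = cells, matrix = mat,
              stage_summary = stage_summary, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  fwrite(res$candidates, p("candidates.tsv"), sep = "\t")
  write_candidates_vcf(res$candidates[detected == TRUE], p("candidates.vcf"))
  fwrite(res$attrition, p("attrition.tsv"), sep = "\t")
  fwrite(res$editome, p("editome.tsv"), sep = "\t")
  if (nrow(res$coding)) fwrite(res$coding, p("coding_effects.tsv"), sep = "\t")
  fwrite(res$cells, p("cell_summary.tsv"), sep = "\t")
  fwrite(res$stage_summary$summary, p("stage_summary.tsv"), sep = "\t")
  fwrite(res$stage_summary$tests, p("stage_tests.tsv"), sep = "\t")
  if (!is.null(res$matrix)) {
    mdt <- data.table(cell_id = rownames(res$matrix))
    mdt <- cbind(mdt, as.data.table(res$matrix))
    fwrite(mdt, p("editing_matrix.tsv"), sep = "\t")
    if (nrow(res$matrix) >= 2) {
      cl <- cluster_cells(res$matrix, linkage = res$config$linkage)
      write_dendrogram_newick(cl$hclust, p("cells.nwk"))
    }
  }
  invisible(out_dir)
}

#' Pipeline configuration matched to a simulated cohort
#'
#' The real-data QC gate (0.5 Gb uniquely mapped bases) presumes a
#' full-size transcriptome; for a simulated genome the gate scales to a
#' quarter of the nominal per-cell coverage, keeping its role (drop
#' poorly covered cells) without dropping the whole toy cohort.
#'
#' @param sim a [sim_config()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
sim_pipeline_config <- function(sim, ...) {
  gate <- 0.25 * sim$genome_length * sim$mean_depth
  pipeline_config(min_uniquely_mapped_bases = gate, ...)
}
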