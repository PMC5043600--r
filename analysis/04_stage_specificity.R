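#!/usr/bin/env Rscript
# Stage-specificity of miRNA-target editing and expression-frequency
# associations: per-gene Fisher tests of edited vs unedited cells inside
# one stage (or two sequential stages) against the rest of the cohort, and
# Spearman correlations between editing frequency and host-gene expression
# for exonic-edited genes with BH control.

suppressMessages({
  library(editomics)
  library(data.table)
  library(optparse)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--sim", type = "character", default = "results/sim"),
  make_option("--pipeline", type = "character", default = "results/pipeline"),
  make_option("--out", type = "character", default = "results/stages"))))
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

editome <- fread(file.path(opts$pipeline, "editome.tsv"))
meta <- fread(file.path(opts$sim, "meta.tsv"))
truth <- fread(file.path(opts$sim, "truth_sites.tsv"))
mat_dt <- fread(file.path(opts$pipeline, "editing_matrix.tsv"))
mat <- as.matrix(mat_dt[, -1]); rownames(mat) <- mat_dt$cell_id
rpkm_dt <- fread(file.path(opts$sim, "expression_rpkm.tsv"))
rpkm <- as.matrix(rpkm_dt[, -1]); rownames(rpkm) <- rpkm_dt$gene_id

# Fisher stage tests on miRNA-target editing
gce <- gene_cell_edited(editome)
st1 <- stage_specific_editing(gce, meta, "single_stage")
st2 <- stage_specific_editing(gce, meta, "two_sequential")
fwrite(st1, file.path(opts$out, "stage_flags_single.tsv"), sep = "\t")
fwrite(st2, file.path(opts$out, "stage_flags_pairs.tsv"), sep = "\t")
cat(sprintf("%d genes tested; %d gene-stage flags (single), %d (sequential pairs)\n",
            length(unique(gce$gene_id)), sum(st1$flagged), sum(st2$flagged)))
cat("flagged single-stage genes:\n")
print(st1[flagged == TRUE, .(gene_id, stage, edited_in, edited_out,
                             fet_p = signif(fet_p, 3))])
planted <- unique(truth[active_stages != "all" & active_stages != "",
                        .(gene_id, active_stages)])
if (nrow(planted)) {
  cat("planted stage-restricted genes for comparison:\n")
  print(planted)
}

# expression vs editing frequency on exonic-edited genes
exonic <- unique(editome[feature %in% c("CDS", "3UTR", "5UTR", "ncRNA") &
                           !is.na(gene_id) & gene_id != "",
                         .(chrom, pos, gene_id)])
sg <- data.table(site = paste(exonic$chrom, exonic$pos, sep = ":"),
                 gene_id = exonic$gene_id)
assoc <- expression_vs_frequency(mat, sg, rpkm)
fwrite(assoc, file.path(opts$out, "expression_frequency.tsv"), sep = "\t")
cat(sprintf("\n%d site-gene associations tested; %d flagged at BH-adjusted P < 0.1\n",
            nrow(assoc), sum(assoc$flagged)))
print(assoc[flagged == TRUE][order(p_adjusted)][
  , .(gene_id, site, rho = round(rho, 2), p_adjusted = signif(p_adjusted, 2))])

# non-synonymous recoding events
coding_f <- file.path(opts$pipeline, "coding_effects.tsv")
if (file.exists(coding_f)) {
  coding <- fread(coding_f)
  ns <- coding[effect == "nonsynonymous"]
  cat(sprintf("\nnon-synonymous editing: %d sites on %d genes\n",
              nrow(unique(ns[, .(chrom, pos)])), length(unique(ns$gene_id))))
}
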