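#!/usr/bin/env Rscript
# Editome-level analytics on the pipeline outputs: mismatch spectrum and
# neighbour preference, per-stage editome sizes and editing levels with
# sequential rank-sum tests, correlation of the editing level with the
# simulated ADAR expression, hierarchical clustering of the editing
# matrix, and a separate 30-cell depth-titration cohort showing the level
# statistic is insensitive to sequencing depth.

suppressMessages({
  library(editomics)
  library(data.table)
  library(optparse)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--sim", type = "character", default = "results/sim"),
  make_option("--pipeline", type = "character", default = "results/pipeline"),
  make_option("--out", type = "character", default = "results/levels"))))
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

cells <- fread(file.path(opts$pipeline, "cell_summary.tsv"))
truth_cells <- fread(file.path(opts$sim, "truth_cells.tsv"))
editome <- fread(file.path(opts$pipeline, "editome.tsv"))
ref <- Biostrings::readDNAStringSet(file.path(opts$sim, "genome.fa"))
names(ref) <- sub(" .*", "", names(ref))

# motif: G depletion at -1, enrichment at +1 of the edited adenosine
np <- neighbor_preference(unique(editome[, .(chrom, pos, ref, alt)]), ref)
cat(sprintf("neighbour G fraction: %.3f at -1, %.3f at +1 (%d sites)\n",
            np$minus1_g_frac, np$plus1_g_frac, np$n_sites))

# stage trajectory of editome size and editing level
ss <- stage_summaries(cells)
fwrite(ss$summary, file.path(opts$out, "stage_summary.tsv"), sep = "\t")
fwrite(ss$tests, file.path(opts$out, "stage_ranksum.tsv"), sep = "\t")
cat("\nper-stage editome (mean +/- sd sites; mean level):\n")
print(ss$summary[, .(stage, n_cells, mean_sites = round(mean_sites),
                     sd_sites = round(sd_sites),
                     mean_level = round(mean_level, 1))])
m4 <- ss$summary[stage == "4cell", mean_level]
m8 <- ss$summary[stage == "8cell", mean_level]
cat(sprintf("editing level drops %.0f%% from 4-cell to 8-cell (rank-sum P = %.2g)\n",
            100 * (1 - m8 / m4),
            ss$tests[stage_a == "4cell" & stage_b == "8cell", p]))

# ADAR coupling
tc <- truth_cells[match(cells$cell_id, cell_id)]
ct <- correlate(cells$editing_level, tc$adar_rpkm, "pearson")
cat(sprintf("editing level vs simulated ADAR RPKM: r = %.2f, P = %.2g\n",
            ct$r, ct$p))

# clustering of the editing-frequency matrix
mat_dt <- fread(file.path(opts$pipeline, "editing_matrix.tsv"))
mat <- as.matrix(mat_dt[, -1]); rownames(mat) <- mat_dt$cell_id
cl <- cluster_cells(mat, k = 2)
write_dendrogram_newick(cl$hclust, file.path(opts$out, "cells.nwk"))
grp <- data.table(cell_id = rownames(mat), cluster = cl$labels,
                  stage = cells$stage[match(rownames(mat), cells$cell_id)])
fwrite(grp, file.path(opts$out, "clusters.tsv"), sep = "\t")
cat("\n2-cut cluster composition by stage:\n")
print(dcast(grp, stage ~ cluster, fun.aggregate = length))

# the 4-cells-per-stage default floors the exact rank-sum P at 2/70 = 0.029;
# a 6-cells-per-stage cohort gives the test room below 0.01
cfg_s <- sim_config(seed = opts$seed + 2L, embryos_per_stage = 3L)
sim_s <- simulate_dataset(cfg_s)
res_s <- run_pipeline(sim_s$pileup, sim_s$meta,
                      sim_s[c("reference", "alu", "simple_repeats",
                              "splice_sites", "snps", "catalogue", "genes",
                              "mirna_targets")],
                      sim_pipeline_config(cfg_s))
ss6 <- res_s$stage_summary
cat(sprintf("6-cells-per-stage cohort: 4-cell to 8-cell drop %.0f%%, rank-sum P = %.2g\n",
            100 * (1 - ss6$summary[stage == "8cell", mean_level] /
                     ss6$summary[stage == "4cell", mean_level]),
            ss6$tests[stage_a == "4cell" & stage_b == "8cell", p]))
fwrite(ss6$summary, file.path(opts$out, "stage_summary_6cells.tsv"),
       sep = "\t")

# depth titration: a separate 30-cell cohort varying only sequencing depth
cfg_d <- sim_config(seed = opts$seed + 1L,
                    stages = c("oocyte", "zygote", "2cell"),
                    embryos_per_stage = 5L, cells_per_embryo = 2L,
                    depth_range = c(1, 4), activity_noise_sd = 0)
sim_d <- simulate_dataset(cfg_d)
res_d <- run_pipeline(sim_d$pileup, sim_d$meta,
                      sim_d[c("reference", "alu", "simple_repeats",
                              "splice_sites", "snps", "catalogue", "genes",
                              "mirna_targets")],
                      sim_pipeline_config(cfg_d))
ct_d <- correlate(res_d$cells$editing_level, res_d$cells$mapped_bases,
                  "pearson")
cat(sprintf("\ndepth titration (n = %d, 1-4x depth): level vs mapped bases r = %.2f\n",
            nrow(res_d$cells), ct_d$r))
fwrite(res_d$cells[, .(cell_id, mapped_bases, editing_level)],
       file.path(opts$out, "depth_titration.tsv"), sep = "\t")
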