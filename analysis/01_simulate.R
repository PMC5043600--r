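#!/usr/bin/env Rscript
# Generates the default simulated cohort: a 1 Mb genome with annotation
# tracks, 24 cells (4 per stage, 2 embryos per stage) across six embryonic
# stages, 500 planted A-to-I edits, 200 embryo-private SNPs, 50 + 50
# strand/read-end artifact sites, per-base errors at 1e-3, and a
# stage-dependent editing activity coupled to a simulated ADAR expression
# value. Writes every input the detection pipeline consumes, plus the
# planted truth, under --out.

suppressMessages({
  library(editomics)
  library(data.table)
  library(optparse)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/sim"))))

cfg <- sim_config(seed = opts$seed)
sim <- simulate_dataset(cfg)

write_genome_bundle(sim, opts$out)
write_pileup_tsv(sim$pileup, file.path(opts$out, "pileup.tsv"))
fwrite(sim$meta, file.path(opts$out, "meta.tsv"), sep = "\t")
fwrite(sim$truth_cells, file.path(opts$out, "truth_cells.tsv"), sep = "\t")
rpkm_dt <- data.table(gene_id = rownames(sim$expression$rpkm),
                      sim$expression$rpkm)
fwrite(rpkm_dt, file.path(opts$out, "expression_rpkm.tsv"), sep = "\t")

cat(sprintf("cohort: %d cells, %d embryos, %d stages\n",
            nrow(sim$meta), length(unique(sim$meta$embryo_id)),
            length(unique(sim$meta$stage))))
cat(sprintf("planted: %d edits (%d in Alu), %d SNPs, %d + %d artifacts\n",
            sum(sim$truth_sites$kind == "edit"),
            sim$truth_sites[kind == "edit" & region == "Alu", .N],
            sum(sim$truth_sites$kind == "snp"),
            sum(sim$truth_sites$kind == "strand_artifact"),
            sum(sim$truth_sites$kind == "end_artifact")))
cat(sprintf("pileup columns: %d; outputs in %s\n", nrow(sim$pileup), opts$out))
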