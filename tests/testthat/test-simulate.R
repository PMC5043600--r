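test_that("the generator is deterministic given config and seed", {
  cfg <- tiny_cfg()
  b1 <- simulate_genome(cfg)
  b2 <- simulate_genome(cfg)
  expect_identical(as.character(b1$reference), as.character(b2$reference))
  expect_identical(b1$truth_sites, b2$truth_sites)
  c1 <- simulate_cells(cfg, b1)
  c2 <- simulate_cells(cfg, b2)
  expect_identical(c1$pileup, c2$pileup)
  expect_identical(c1$truth_cells, c2$truth_cells)
})

test_that("planted annotation geometry matches the config", {
  sim <- tiny_sim()
  cfg <- sim$config
  expect_equal(length(sim$alu), cfg$n_alu)
  expect_equal(sum(sim$truth_sites$kind == "edit"), cfg$n_true_edits)
  expect_equal(sum(sim$truth_sites$kind == "snp"), cfg$n_snps)
  # homopolymer runs really are runs of >= 5 identical reference bases
  # (checked through the mask filter on a known planted run position)
  expect_true(all(Biostrings::width(sim$alu) == cfg$alu_len))
  # edits respect the configured frequency prior
  f <- sim$truth_sites[kind == "edit" & !coupled, f_base]
  expect_true(all(f >= cfg$edit_freq_range[1] & f <= cfg$edit_freq_range[2]))
  # planted edits are A-to-G in transcript sense: genomic T-to-C only
  # within minus-strand gene loci
  ed <- sim$truth_sites[kind == "edit"]
  expect_true(all(ed$ref %in% c("A", "T")))
  expect_true(all(ed[ref == "A", alt] == "G"))
  expect_true(all(ed[ref == "T", alt] == "C"))
  # reference carries the planted base at every site
  rb <- editomics:::reference_base(sim$reference, ed$chrom, ed$pos)
  expect_identical(rb, ed$ref)
})

test_that("a clean configuration yields a mismatch-free pileup", {
  cfg <- tiny_cfg(p_err = 0, n_true_edits = 0, n_snps = 0,
                  n_strand_artifacts = 0, n_end_artifacts = 0,
                  n_stage_genes = 0, n_pair_genes = 0, coupled_gene = FALSE)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$pileup), 0)
})

test_that("observed variant support follows the planted per-cell frequencies", {
  sim <- tiny_sim()
  ts <- sim$truth_sites[kind == "edit" & active_stages == "all" & !coupled]
  pu <- sim$pileup[ts, on = c("chrom", "pos"), nomatch = 0L]
  f <- sim$site_freqs[pu, on = c("cell_id", "chrom", "pos")]
  tot <- pu[, .(G = G_fwd + G_rev, C = C_fwd + C_rev, ref, depth)]
  k <- ifelse(pu$ref == "A", tot$G, tot$C)
  use <- f$f > 0 & pu$depth >= 10
  lo <- qbinom(0.005, pu$depth[use], f$f[use])
  hi <- qbinom(0.995, pu$depth[use], f$f[use])
  inside <- k[use] >= lo & k[use] <= hi
  expect_gte(mean(inside), 0.95)
})

test_that("artifact sites are constructed with pure strand or read-end support", {
  sim <- tiny_sim()
  sa <- sim$truth_sites[kind == "strand_artifact"]
  pu <- sim$pileup[sa, on = c("chrom", "pos"), nomatch = 0L]
  alt_rev <- ifelse(pu$ref == "A", pu$G_rev, pu$C_rev)
  expect_true(all(alt_rev == 0))
  ea <- sim$truth_sites[kind == "end_artifact"]
  pu2 <- sim$pileup[ea, on = c("chrom", "pos"), nomatch = 0L]
  expect_true(all(pu2$alt_mid == 0))
})

test_that("background mismatch rate is recovered within 10 % of the error rate", {
  sim <- tiny_sim()
  r <- background_rates(sim$pileup, sim$meta, exclude_high_freq = TRUE)
  expect_true(all(abs(r$p - sim$config$p_err) / sim$config$p_err < 0.1))
})

test_that("neighbour context of planted edits reflects the configured enrichment", {
  sim <- tiny_sim()
  ed <- sim$truth_sites[kind == "edit"]
  np <- neighbor_preference(ed, sim$reference)
  n <- np$n_sites
  tol <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(np$plus1_g_frac - sim$config$context_g_plus1_prob), tol)
  expect_lt(np$minus1_g_frac, 0.25)
})

test_that("truth scoring reports exact precision/recall on degenerate inputs", {
  sim <- tiny_sim()
  edits <- sim$truth_sites[kind == "edit"]
  full <- data.table::data.table(cell_id = "c", chrom = edits$chrom,
                                 pos = edits$pos)
  sc <- score_against_truth(full, sim$truth_sites, sim$pileup)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  empty <- full[0]
  sc0 <- score_against_truth(empty, sim$truth_sites, sim$pileup)
  expect_true(is.na(sc0$precision))
  expect_equal(sc0$recall, 0)
})

test_that("SAM emission plants variants at the configured frequency", {
  set.seed(2)
  chars <- sample(c("A", "C", "G", "T"), 400, TRUE)
  chars[200] <- "A"
  ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref) <- "chrS"
  sam <- simulate_sam(ref, data.table::data.table(pos = 200L, alt = "G",
                                                  f = 1.0),
                      n_reads = 120, seed = 4)
  pu <- build_pileup(read_sam(sam), ref, cell_id = "s1")
  col <- pu[pos == 200]
  expect_gt(col$depth, 10)
  expect_equal(col$G_fwd + col$G_rev, col$depth)  # every covering read edited
  # frequency 0 plants nothing
  sam0 <- simulate_sam(ref, data.table::data.table(pos = 200L, alt = "G",
                                                   f = 0),
                       n_reads = 60, seed = 5)
  pu0 <- build_pileup(read_sam(sam0), ref, cell_id = "s0")
  expect_equal(pu0[pos == 200, G_fwd + G_rev], 0L)
})
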