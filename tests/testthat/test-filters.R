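test_that("two-tailed Fisher P agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1.0)
  expect_lt(abs(fisher_exact_2x2(matrix(c(12, 0, 0, 12), 2, byrow = TRUE)) -
                  oracle_fet(12, 0, 0, 12)), 1e-12)
  set.seed(3)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    expect_lt(abs(fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE)) -
                    oracle_fet(a, b, c_, d)), 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("strand-bias filter applies the published three-clause rule", {
  # variant 19 sense / 1 antisense: strand frequency 0.95 > 0.9
  v <- strand_bias_filter(19, 1, 50, 50)
  expect_equal(v$decision, "fail")
  expect_equal(v$var_strand_freq, 0.95)
  # balanced variant and reference support
  expect_equal(strand_bias_filter(10, 10, 50, 50)$decision, "pass")
  # all variant reads antisense: frequency 0 < 0.1
  expect_equal(strand_bias_filter(0, 12, 30, 30)$decision, "fail")
  # FET branch: decision follows the enumeration-oracle P and preferences
  p <- oracle_fet(9, 1, 10, 10)
  v <- strand_bias_filter(9, 1, 10, 10)
  expect_equal(v$fet_p, p, tolerance = 1e-12)
  expect_equal(v$decision,
               if ((p < 0.005 && abs(0.9 - 0.5) > 0) || 0.9 > 0.9) "fail"
               else "pass")
  # strongly discordant strands trip the FET clause
  expect_equal(strand_bias_filter(35, 5, 50, 250)$decision, "fail")
  expect_error(strand_bias_filter(0, 0, 5, 5), ">= 1 variant read")
})

test_that("position-bias filter flags read-end concentration", {
  expect_equal(position_bias_filter(10, 0, 20, 80)$decision, "fail")  # e = 1
  expect_equal(position_bias_filter(1, 9, 20, 80)$decision, "pass")
  v <- position_bias_filter(7, 3, 20, 80)
  expect_equal(v$fet_p, oracle_fet(7, 3, 20, 80), tolerance = 1e-12)
  expect_equal(v$decision, if (v$fet_p < 0.05 && 0.7 > 0.3) "fail" else "pass")
  expect_error(position_bias_filter(0, 0, 5, 5), ">= 1 variant base")
})

test_that("realignment filter keeps sites whose variant reads realign to them", {
  set.seed(11)
  locus <- paste(sample(BASES <- c("A", "C", "G", "T"), 300, TRUE),
                 collapse = "")
  # a paralogous contig: same sequence with 12 scattered substitutions
  para <- strsplit(locus, "")[[1]]
  idx <- seq(10, 290, length.out = 12)
  para[idx] <- vapply(para[idx], function(b) setdiff(BASES, b)[1], "")
  combined <- Biostrings::DNAStringSet(c(g = locus,
                                         t = paste(para, collapse = "")))
  site_pos <- 150L
  read_from <- function(src, start, len = 60L) substr(src, start, start + len - 1L)
  locus_reads <- vapply(c(100L, 110L, 120L), function(s)
    read_from(locus, s), "")
  para_reads <- vapply(c(100L, 110L, 120L), function(s)
    read_from(paste(para, collapse = ""), s), "")
  r <- realignment_filter("g", site_pos, locus_reads, combined)
  expect_equal(r$decision, "pass")
  expect_equal(r$realign_frac, 1)
  # reads originating from the paralog place best away from the site
  r2 <- realignment_filter("g", site_pos, para_reads, combined)
  expect_equal(r2$decision, "fail")
  # 9 of 10 supporting reads meets the 90 % rule; 8 of 10 does not
  r3 <- realignment_filter("g", site_pos, c(rep(locus_reads, 3), para_reads[1]),
                           combined)
  expect_equal(r3$realign_frac, 0.9)
  expect_equal(r3$decision, "pass")
  r4 <- realignment_filter("g", site_pos,
                           c(rep(locus_reads[1:2], 4), para_reads[1:2]),
                           combined)
  expect_equal(r4$decision, "fail")
  expect_error(realignment_filter("g", 1, "ACGT",
                                  Biostrings::DNAStringSet()), "empty")
})

test_that("region masks remove repeats, homopolymers, and non-Alu splice-adjacent sites", {
  s <- paste(rep("ACGT", 100), collapse = "")
  substr(s, 201, 205) <- "AAAAA"
  ref <- Biostrings::DNAStringSet(s); names(ref) <- "chr1"
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 340))
  splice <- data.table::data.table(chrom = "chr1", pos = 100L)
  v <- region_mask_filter(rep("chr1", 5), c(203L, 320L, 97L, 97L, 21L),
                          in_alu = c(TRUE, FALSE, FALSE, TRUE, FALSE),
                          ref, reps, splice)
  expect_equal(v$decision, c("fail", "fail", "fail", "pass", "pass"))
  expect_true(v$in_homopolymer[1])
  expect_true(v$in_simple_repeat[2])
  expect_true(v$near_splice_non_alu[3])   # non-Alu, 3 bp from splice
  expect_false(v$near_splice_non_alu[4])  # Alu site exempt from splice mask
  # a site adjacent to (not inside) the run is also masked
  v2 <- region_mask_filter("chr1", 206L, FALSE, ref, reps, splice)
  expect_equal(v2$decision, "fail")
})

test_that("known-SNP filter honours catalogue membership and alt-awareness", {
  snps <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                 alt = c("G", "T"))
  v <- known_snp_filter(c("chr1", "chr1", "chr2"), c(10L, 30L, 10L),
                        c("G", "G", "G"), snps)
  expect_equal(v$decision, c("fail", "pass", "pass"))
  # same position, different alt: passes in alt-aware mode, fails otherwise
  v2 <- known_snp_filter("chr1", 20L, "G", snps, alt_aware = TRUE)
  expect_equal(v2$decision, "pass")
  v3 <- known_snp_filter("chr1", 20L, "G", snps, alt_aware = FALSE)
  expect_equal(v3$decision, "fail")
  expect_equal(known_snp_filter("chr1", 10L, "G", NULL)$decision, "pass")
})

test_that("recurrence filter removes sites confined to a single embryo", {
  meta <- data.table::data.table(cell_id = c("a1", "a2", "b1", "b2"),
                                 embryo_id = c("e1", "e1", "e2", "e2"))
  det <- data.table::data.table(
    cell_id = c("a1", "a2", "a1", "b1", "a1", "a2", "b1", "b2"),
    chrom = "chr1", pos = c(5L, 5L, 9L, 9L, 13L, 13L, 13L, 13L),
    alt = "G")
  v <- recurrence_filter(det, meta)
  expect_equal(v[pos == 5, decision], "fail")   # two cells, one embryo
  expect_equal(v[pos == 9, decision], "pass")   # two embryos
  expect_equal(v[pos == 13, decision], "pass")  # all embryos
  expect_error(recurrence_filter(det, meta[1:2]), "embryo")
})

test_that("frequency cap is a strict inequality at 0.95", {
  v <- frequency_cap_filter(c(0.96, 0.95, 0.10))
  expect_equal(v$decision, c("fail", "pass", "pass"))
})

test_that("cascade verdicts are order-free predicates with monotone attrition", {
  res <- tiny_result()
  att <- res$attrition[stage != "candidate_mismatch_sites"]
  expect_true(all(diff(att$sites_out) <= 0))
  cand <- res$candidates
  # retained equals the conjunction of the per-filter verdicts, so any
  # filter ordering yields the same retained set
  vcols <- c("strand_verdict", "pos_verdict", "realign_verdict",
             "mask_verdict", "snp_verdict", "recurrence_verdict",
             "freqcap_verdict")
  conj <- Reduce(`&`, lapply(sample(vcols), function(cc) cand[[cc]] != "fail"))
  expect_identical(cand$retained, conj)
  # failing rows always carry an explanatory statistic
  expect_true(all(!is.na(cand[strand_verdict == "fail", var_strand_freq])))
  expect_true(all(!is.na(cand[pos_verdict == "fail", end_freq])))
})

test_that("planted artifacts and embryo-private SNPs are caught by their filters", {
  sim <- tiny_sim()
  res <- tiny_result()
  cand <- res$candidates
  by_kind <- function(kd) {
    pl <- sim$truth_sites[kind == kd, .(chrom, pos)]
    cand[pl, on = c("chrom", "pos"), nomatch = 0L]
  }
  sa <- by_kind("strand_artifact")
  expect_gte(nrow(sa), 1)
  expect_gte(mean(sa$strand_verdict == "fail"), 0.95)
  ea <- by_kind("end_artifact")
  expect_gte(mean(ea$pos_verdict == "fail"), 0.95)
  sn <- by_kind("snp")
  expect_true(all(sn$recurrence_verdict == "fail" |
                    sn$snp_verdict == "fail"))
})
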