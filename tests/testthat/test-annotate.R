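# a compact two-gene world used across annotation tests:
# plus-strand coding gene gA with exons [101,160] [201,260] [301,420],
# CDS [121,160]+[201,260]+[301,320] (150 b), 3'UTR [321,420];
# minus-strand coding gene gB mirrored at [501,820]; ncRNA gN at [901,960]
anno_world <- function() {
  ref_chars <- rep(c("A", "C", "G", "T"), 300)
  g <- function(feature, s, e, gid, strand, type = "coding")
    data.table::data.table(chrom = "chr1", start = s, end = e,
                           strand = strand, feature = feature, gene_id = gid,
                           transcript_id = paste0(gid, ".T1"),
                           transcript_type = type)
  genes <- rbind(
    g("exon", 101, 160, "gA", "+"), g("exon", 201, 260, "gA", "+"),
    g("exon", 301, 420, "gA", "+"),
    g("five_prime_utr", 101, 120, "gA", "+"),
    g("CDS", 121, 160, "gA", "+"), g("CDS", 201, 260, "gA", "+"),
    g("CDS", 301, 320, "gA", "+"),
    g("three_prime_utr", 321, 420, "gA", "+"),
    g("exon", 501, 620, "gB", "-"), g("exon", 701, 760, "gB", "-"),
    g("exon", 781, 820, "gB", "-"),
    g("three_prime_utr", 501, 600, "gB", "-"),
    g("CDS", 601, 620, "gB", "-"), g("CDS", 701, 760, "gB", "-"),
    g("CDS", 781, 800, "gB", "-"),
    g("five_prime_utr", 801, 820, "gB", "-"),
    g("exon", 901, 960, "gN", "+", "ncRNA"))
  ref <- Biostrings::DNAStringSet(paste(ref_chars, collapse = ""))
  names(ref) <- "chr1"
  list(genes = genes, reference = ref)
}

test_that("mismatch classification respects closed Alu intervals and the catalogue", {
  alu_bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t50", alu_bed)  # 0-based half-open: bases 11..50
  alu <- read_bed(alu_bed)
  cat_dt <- data.table::data.table(chrom = "chr1", pos = c(70L, 80L),
                                   strand = c("+", "-"))
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(11L, 50L, 51L, 70L, 80L, 80L),
                                  ref = c("A", "A", "A", "A", "T", "A"),
                                  alt = c("G", "G", "G", "G", "C", "G"))
  cl <- classify_mismatch(sites, alu, cat_dt)
  expect_equal(cl$region_class,
               c("Alu", "Alu", "non-Alu", "non-Alu", "non-Alu", "non-Alu"))
  expect_equal(cl$mismatch_type[5], "T-to-C")
  # strand-sense aware: T-to-C at 80 matches the minus-strand entry,
  # A-to-G at the same position does not
  expect_equal(cl$in_catalogue, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("A-to-I retention keeps Alu A-to-G and catalogued non-Alu A-to-G only", {
  w <- anno_world()
  alu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 420))
  cl <- classify_mismatch(
    data.table::data.table(chrom = "chr1",
                           pos = c(305L, 210L, 215L, 310L, 550L, 550L),
                           ref = c("A", "A", "A", "C", "T", "T"),
                           alt = c("G", "G", "G", "T", "C", "C")),
    alu, data.table::data.table(chrom = "chr1", pos = c(210L, 550L)))
  keep <- retain_a2i(cl, w$genes)
  expect_true(keep[1])    # Alu A-to-G
  expect_true(keep[2])    # non-Alu A-to-G in catalogue
  expect_false(keep[3])   # non-Alu A-to-G, not catalogued
  expect_false(keep[4])   # C-to-T stays in the spectrum only
  expect_true(keep[5])    # T-to-C over a minus-strand gene, catalogued
  # strict mode drops every T-to-C
  expect_false(retain_a2i(cl, w$genes, mode = "strict")[5])
  # without a minus-strand gene overlap, T-to-C is not rescued
  expect_false(retain_a2i(cl[c(6, 6)],
                          w$genes[gene_id != "gB"], "transcript_sense")[1])
})

test_that("mismatch spectrum fractions sum to one per cell", {
  cand <- data.table::data.table(cell_id = rep(c("c1", "c2"), c(4, 2)),
                                 ref = c("A", "A", "A", "C", "T", "G"),
                                 alt = c("G", "G", "T", "T", "C", "A"))
  sp <- mismatch_spectrum(cand)
  expect_equal(sp[, sum(fraction), by = cell_id]$V1, c(1, 1))
  expect_equal(sp[cell_id == "c1" & mismatch_type == "A-to-G", fraction], 0.5)
  expect_equal(nrow(sp), 2 * 12)
})

test_that("neighbour preference reads the reference strand, complemented for T-to-C", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "CCAGT"))
  np <- neighbor_preference(
    data.table::data.table(chrom = "chr1", pos = 3L, ref = "A", alt = "G"), ref)
  expect_equal(np$minus1_g_frac, 0)  # C before the edited A
  expect_equal(np$plus1_g_frac, 1)   # G after it
  # genomic "CTG" around a T-to-C site: on the complementary strand the
  # edited A is flanked by C (+1 side reads the complement of genomic -1)
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "ACTGA"))
  np2 <- neighbor_preference(
    data.table::data.table(chrom = "chr1", pos = 3L, ref = "T", alt = "C"), ref2)
  expect_equal(np2$plus1_g_frac, 1)   # complement of genomic C at -1 is G
  expect_equal(np2$minus1_g_frac, 0)  # complement of genomic G at +1 is C
  # uniform random sequence: both fractions near 1/4
  set.seed(5)
  chars <- sample(c("A", "C", "G", "T"), 20000, TRUE)
  refu <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(refu) <- "chr1"
  pos <- which(chars == "A")
  pos <- pos[pos > 1 & pos < 20000]
  pos <- sample(pos, 400)
  npu <- neighbor_preference(
    data.table::data.table(chrom = "chr1", pos = pos, ref = "A", alt = "G"),
    refu)
  sd3 <- 3 * sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(npu$minus1_g_frac - 0.25), sd3)
  expect_lt(abs(npu$plus1_g_frac - 0.25), sd3)
  expect_error(neighbor_preference(
    data.table::data.table(chrom = "chr1", pos = 1L, ref = "A", alt = "G"),
    ref), "edges")
})

test_that("genic features follow the CDS > UTR > ncRNA > intronic precedence", {
  w <- anno_world()
  # overlap a second transcript whose intron covers gA's CDS
  extra <- data.table::data.table(chrom = "chr1", start = c(50, 280),
                                  end = c(60, 290), strand = "+",
                                  feature = "exon", gene_id = "gX",
                                  transcript_id = "gX.T1",
                                  transcript_type = "coding")
  genes2 <- rbind(w$genes, extra)
  fa <- assign_feature(
    data.table::data.table(chrom = "chr1",
                           pos = c(130L, 110L, 350L, 930L, 180L, 990L)),
    genes2)
  expect_equal(fa$feature,
               c("CDS", "5UTR", "3UTR", "ncRNA", "intronic", "intergenic"))
  expect_equal(fa$gene_id[1], "gA")   # CDS wins over gX's intron
  expect_equal(fa$gene_strand[4], "+")
  expect_error(assign_feature(data.table::data.table(chrom = "chr1", pos = 1L),
                              w$genes[, !"strand"]), "malformed")
})

test_that("coding effects translate the edited codon in transcript orientation", {
  # build a reference whose gA CDS starts with AAG (Lys) and has GCA later
  chars <- rep("T", 1200)
  w <- anno_world()
  cds1 <- 121:160; cds2 <- 201:260; cds3 <- 301:320
  cds_pos <- c(cds1, cds2, cds3)
  codons <- c("AAG", "GCA", rep("CTG", 38))  # 40 codons = 120 CDS bases
  chars[cds_pos] <- unlist(strsplit(paste(codons, collapse = ""), ""))
  ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref) <- "chr1"
  # K -> E at codon 1 position 1 (genomic 121)
  e1 <- coding_effect("chr1", 121L, "G", "gA.T1", w$genes, ref)
  expect_equal(e1$effect, "nonsynonymous")
  expect_equal(e1$aa_ref, "K"); expect_equal(e1$aa_alt, "E")
  # GCA -> GCG at codon 2 position 3 (genomic 126) is synonymous
  e2 <- coding_effect("chr1", 126L, "G", "gA.T1", w$genes, ref)
  expect_equal(e2$effect, "synonymous")
  expect_equal(e2$aa_ref, "A")
  # minus-strand gene: genomic T-to-C reads as transcript A-to-G
  chars2 <- rep("C", 1200)
  # gB CDS (genomic): [601,620], [701,760], [781,800]; transcript reads
  # reverse complement from 800 down
  chars2[c(601:620, 701:760, 781:800)] <- "T"   # transcript all A -> Lys runs
  # make CDS length multiple of 3: 20+60+20 = 100... pad via explicit model
  gB <- w$genes[gene_id == "gB" & feature == "CDS"]
  gB[start == 601, start := 599]  # 102 bases -> 34 codons
  genesB <- rbind(w$genes[!(gene_id == "gB" & feature == "CDS")], gB)
  chars2[599:600] <- "T"
  refB <- Biostrings::DNAStringSet(paste(chars2, collapse = ""))
  names(refB) <- "chr1"
  e3 <- coding_effect("chr1", 750L, "C", "gB.T1", genesB, refB)
  expect_equal(e3$aa_ref, "K")              # AAA on the transcript strand
  expect_equal(e3$effect, "nonsynonymous")  # one A -> G turns Lys codon
  expect_error(coding_effect("chr1", 50L, "G", "gA.T1", w$genes, ref),
               "not in CDS")
})

test_that("codon-level predictions match translating the whole edited CDS", {
  set.seed(9)
  for (i in 1:60) {
    n_codon <- sample(4:20, 1)
    cds_len <- 3L * n_codon
    chars <- sample(c("A", "C", "G", "T"), cds_len + 40, TRUE)
    strand <- sample(c("+", "-"), 1)
    genes <- data.table::data.table(
      chrom = "chr1", start = c(21L, 21L), end = c(20L + cds_len, 20L + cds_len),
      strand = strand, feature = c("exon", "CDS"), gene_id = "g",
      transcript_id = "g.T1", transcript_type = "coding")
    ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(ref) <- "chr1"
    gpos <- sample(21:(20L + cds_len), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[gpos]), 1)
    eff <- coding_effect("chr1", gpos, alt, "g.T1", genes, ref)
    # oracle: translate the full edited CDS directly
    edited <- chars; edited[gpos] <- alt
    tx <- function(ch) {
      s <- Biostrings::DNAString(paste(ch[21:(20L + cds_len)], collapse = ""))
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(Biostrings::translate(s))
    }
    aa0 <- tx(chars); aa1 <- tx(edited)
    expect_equal(eff$effect,
                 if (aa0 == aa1) "synonymous" else "nonsynonymous")
  }
})

test_that("miRNA-target overlap requires both the interval and a 3'UTR feature", {
  tg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 110))
  expect_true(mirna_target_overlap("chr1", 105L, "3UTR", tg))
  expect_false(mirna_target_overlap("chr1", 105L, "CDS", tg))
  expect_false(mirna_target_overlap("chr1", 500L, "3UTR", tg))
})
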