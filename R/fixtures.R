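## A fully worked miniature input set for demonstration and validation.

#' Twelve-site demonstration cohort for the filter cascade
#'
#' A hand-built world of four cells from two embryos over a 2 kb contig,
#' with one pileup column per failure mode of the detection cascade plus a
#' single clean Alu A-to-G edit: a depth-3 site, a frequency-0.09 site, a
#' strand-confined site, a read-end-confined site, a homopolymer-run site,
#' a non-Alu splice-adjacent site, a known-SNP site, a single-embryo site,
#' a frequency-0.96 site, a non-Alu A-to-G absent from the editing
#' catalogue, and an Alu C-to-T. Running [run_pipeline()] on it retains
#' exactly the one clean edit, and each removed site fails its intended
#' gate.
#'
#' @return list with `pileup`, `meta`, `ann` (annotation bundle), `config`
#'   (QC gate disabled: the toy cells carry 1 Mb of aligned bases), and
#'   `sites` (named list of the planted site definitions).
#' @export
demo_cascade_cohort <- function() {
  chars <- rep(c("A", "C", "G", "T"), 500)   # 2 kb, run-free tiling
  chars[200:204] <- "A"                       # homopolymer run
  chars[703] <- "A"                           # splice-adjacent site base
  ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref) <- "chrF"

  alu <- GenomicRanges::GRanges("chrF", IRanges::IRanges(100, 400))
  simple_repeats <- GenomicRanges::GRanges("chrF", IRanges::IRanges(1500, 1540))
  g <- function(feature, s, e)
    data.table(chrom = "chrF", start = s, end = e, strand = "+",
               feature = feature, gene_id = "gF", transcript_id = "gF.T1",
               transcript_type = "coding")
  genes <- rbind(g("exon", 600, 700), g("exon", 800, 900),
                 g("five_prime_utr", 600, 619),
                 g("CDS", 620, 700), g("CDS", 800, 850),
                 g("three_prime_utr", 851, 900))
  splice_sites <- data.table(chrom = "chrF", pos = c(700L, 800L))
  snps <- data.table(chrom = "chrF", pos = 181L, alt = "G")
  catalogue <- data.table(chrom = "chrF", pos = 703L, strand = "+")

  sites <- list(
    pass         = list(pos = 121L, ref = "A", alt = "G"),
    depth3       = list(pos = 133L, ref = "A", alt = "G", n = 3L, k = 3L),
    lowfreq      = list(pos = 145L, ref = "A", alt = "G", n = 100L, k = 9L),
    strand       = list(pos = 157L, ref = "A", alt = "G", n = 40L, k = 20L,
                        alt_fwd = 20L),
    readend      = list(pos = 169L, ref = "A", alt = "G", n = 40L, k = 20L,
                        alt_end = 20L),
    homopolymer  = list(pos = 202L, ref = "A", alt = "G"),
    splice       = list(pos = 703L, ref = "A", alt = "G"),
    snplist      = list(pos = 181L, ref = "A", alt = "G"),
    one_embryo   = list(pos = 193L, ref = "A", alt = "G"),
    freqcap      = list(pos = 217L, ref = "A", alt = "G", n = 100L, k = 96L,
                        alt_fwd = 48L, alt_end = 19L),
    nonalu_nocat = list(pos = 901L, ref = "A", alt = "G"),
    alu_ct       = list(pos = 230L, ref = "C", alt = "T"))

  meta <- data.table(cell_id = c("a1", "a2", "b1", "b2"),
                     embryo_id = c("E1", "E1", "E2", "E2"),
                     stage = c("oocyte", "oocyte", "zygote", "zygote"),
                     mapped_bases = 1e6, aligned_bases = 1e6)

  rows <- list()
  for (cell in meta$cell_id) {
    for (nm in names(sites)) {
      s <- sites[[nm]]
      n <- s$n %||% 20L
      k <- s$k %||% 10L
      if (nm == "one_embryo" && cell %in% c("b1", "b2")) k <- 0L
      rows[[length(rows) + 1L]] <- demo_pileup_row(
        cell, "chrF", s$pos, s$ref, s$alt, n, k,
        alt_fwd = if (k == 0L) 0L else s$alt_fwd %||% (k %/% 2L),
        alt_end = if (k == 0L) 0L else s$alt_end %||% round(k * 0.2))
    }
  }
  pileup <- rbindlist(rows)

  ann <- list(reference = ref, alu = alu, simple_repeats = simple_repeats,
              splice_sites = splice_sites, snps = snps,
              catalogue = catalogue, genes = genes,
              mirna_targets = GenomicRanges::GRanges())
  list(pileup = pileup, meta = meta, ann = ann,
       config = pipeline_config(min_uniquely_mapped_bases = 0),
       sites = sites)
}

#' Build one pileup column from explicit counts
#'
#' Convenience constructor for hand-built pileup rows: counts default to
#' balanced strands and an 0.2 end fraction.
#'
#' @param cell_id,chrom,pos,ref,alt the site.
#' @param n,k depth and variant support.
#' @param alt_fwd,alt_end,ref_fwd,ref_end optional count overrides.
#' @return a single-row pileup `data.table`.
#' @export
demo_pileup_row <- function(cell_id, chrom, pos, ref, alt, n, k,
                            alt_fwd = NULL, alt_end = NULL,
                            ref_fwd = NULL, ref_end = NULL) {
  alt_fwd <- alt_fwd %||% (k %/% 2L)
  alt_end <- alt_end %||% round(k * 0.2)
  refn <- n - k
  ref_fwd <- ref_fwd %||% (refn %/% 2L)
  ref_end <- ref_end %||% round(refn * 0.2)
  counts <- setNames(rep(0L, 8),
                     c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                       "A_rev", "C_rev", "G_rev", "T_rev"))
  counts[paste0(ref, "_fwd")] <- ref_fwd
  counts[paste0(ref, "_rev")] <- refn - ref_fwd
  counts[paste0(alt, "_fwd")] <- counts[paste0(alt, "_fwd")] + alt_fwd
  counts[paste0(alt, "_rev")] <- counts[paste0(alt, "_rev")] + (k - alt_fwd)
  data.table(cell_id = cell_id, chrom = chrom, pos = pos, ref = ref,
             depth = n, t(counts), alt_end = alt_end, alt_mid = k - alt_end,
             ref_end = ref_end, ref_mid = refn - ref_end)
}
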