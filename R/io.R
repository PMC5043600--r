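## Readers/writers for the pipeline's external formats. Sites are 1-based
## fully-closed internally and in TSV outputs; BED inputs/outputs are
## 0-based half-open and converted on read/write (rtracklayer handles the
## conversion).

#' Write a genome bundle to a directory of standard-format files
#'
#' FASTA reference, BED interval tracks (Alu, simple repeats, miRNA
#' targets), GTF gene models, and TSV catalogue / SNP / truth tables.
#'
#' @param bundle output of [simulate_genome()] (or a compatible list).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$reference, p("genome.fa"))
  rtracklayer::export(bundle$alu, p("alu.bed"), format = "BED")
  rtracklayer::export(bundle$simple_repeats, p("simple_repeats.bed"),
                      format = "BED")
  rtracklayer::export(bundle$mirna_targets, p("mirna_targets.bed"),
                      format = "BED")
  rtracklayer::export(gene_models_to_granges(bundle$genes), p("genes.gtf"),
                      format = "GTF")
  fwrite(bundle$catalogue, p("catalogue.tsv"), sep = "\t")
  fwrite(bundle$snps, p("snps.tsv"), sep = "\t")
  if (!is.null(bundle$truth_sites))
    fwrite(bundle$truth_sites, p("truth_sites.tsv"), sep = "\t")
  invisible(dir)
}

gene_models_to_granges <- function(genes) {
  genes <- copy(as.data.table(genes))
  # CDS phase: bases of the codon already used when the segment starts
  genes[, phase := NA_integer_]
  cds <- genes[feature == "CDS"]
  if (nrow(cds) > 0) {
    setorder(cds, transcript_id, start)
    cds[, w := end - start + 1L]
    cds[, before := {
      cw <- cumsum(shift(w, fill = 0L))
      if (strand[1] == "-") rev(cumsum(shift(rev(w), fill = 0L))) else cw
    }, by = transcript_id]
    cds[, phase := ((3L - before %% 3L) %% 3L)]
    genes[cds, on = c("transcript_id", "start", "end"), phase := i.phase]
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = genes$feature, gene_id = genes$gene_id,
    transcript_id = genes$transcript_id,
    transcript_type = genes$transcript_type, phase = genes$phase)
  gr
}

#' Read gene models from a GTF-like file
#'
#' Expects exon / CDS / five_prime_utr / three_prime_utr rows carrying
#' `gene_id`, `transcript_id` and `transcript_type` attributes.
#'
#' @param path GTF file.
#' @return gene-model `data.table` as used by [assign_feature()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  mc <- S4Vectors::mcols(gr)
  need <- c("type", "gene_id", "transcript_id")
  miss <- setdiff(need, names(mc))
  assert_that(length(miss) == 0, "gene model lacks attribute(s): %s",
              paste(miss, collapse = ", "))
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   feature = as.character(mc$type),
                   gene_id = mc$gene_id,
                   transcript_id = mc$transcript_id,
                   transcript_type = if ("transcript_type" %in% names(mc))
                     mc$transcript_type else "coding")
  dt[feature %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr")]
}

#' Read a BED interval track as 1-based closed GRanges
#' @param path BED file.
#' @return `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Read/write the TSV pileup dialect
#'
#' One row per (cell, site): `cell_id`, `chrom`, `pos` (1-based), `ref`,
#' `depth`, per-base per-strand counts `A_fwd` ... `T_rev`, and
#' variant/reference end/middle counts.
#'
#' @param path TSV file.
#' @return pileup `data.table`.
#' @export
read_pileup_tsv <- function(path) {
  pu <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  miss <- setdiff(pileup_cols(), names(pu))
  assert_that(length(miss) == 0, "pileup TSV lacks column(s): %s",
              paste(miss, collapse = ", "))
  chk <- pu$A_fwd + pu$C_fwd + pu$G_fwd + pu$T_fwd +
    pu$A_rev + pu$C_rev + pu$G_rev + pu$T_rev
  assert_that(all(chk == pu$depth), "pileup depth != sum of base counts")
  pu
}

#' @rdname read_pileup_tsv
#' @param pileup pileup table.
#' @export
write_pileup_tsv <- function(pileup, path) {
  fwrite(pileup, path, sep = "\t")
  invisible(path)
}

#' Read a SNP site list (TSV: chrom, pos\[, ref, alt\])
#' @param path TSV file.
#' @return `data.table`.
#' @export
read_snp_tsv <- function(path)
  fread(path, sep = "\t", colClasses = list(character = "chrom"))

#' Read a known-editing-site catalogue (TSV: chrom, pos\[, strand\])
#' @param path TSV file.
#' @return `data.table`.
#' @export
read_catalogue_tsv <- function(path)
  fread(path, sep = "\t", colClasses = list(character = "chrom"))

#' Write candidates as minimal VCF-like records
#'
#' Genotype-less per-cell records with counts in INFO (`CELL`, `DP`, `AC`,
#' `AF`, `PADJ`).
#'
#' @param candidates candidate table.
#' @param path output file.
#' @export
write_candidates_vcf <- function(candidates, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CELL,Number=1,Type=String,Description=\"Cell id\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Mapped reads\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Variant reads\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mismatch frequency\">",
           "##INFO=<ID=PADJ,Number=1,Type=Float,Description=\"BH-adjusted binomial P\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  cand <- as.data.table(candidates)
  recs <- cand[, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCELL=%s;DP=%d;AC=%d;AF=%.4g;PADJ=%.4g",
                         chrom, pos, ref, alt, cell_id, n, k, freq, p_adjusted)]
  writeLines(c(hdr, recs), path)
  invisible(path)
}
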