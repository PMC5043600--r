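## Ingest: read trimming, cell QC, pileup construction and the per-cell
## background mismatch rate.

#' Trim the 3' end of a single-end read
#'
#' Single-end reads lose a fixed number of bases from their 3' end (the
#' low-quality tail); paired-end reads are returned unchanged. A single-end
#' read that would be emptied by trimming is dropped with a warning.
#'
#' @param seq character scalar, read sequence (5'->3').
#' @param qual character scalar, phred string of the same length (optional).
#' @param layout `"single_end"` or `"paired_end"`.
#' @param trim bases removed from the 3' end of single-end reads.
#' @return a list with `seq` and `qual`, or `NULL` if the read was dropped.
#' @export
trim_read <- function(seq, qual = NULL, layout = c("single_end", "paired_end"),
                      trim = 15L) {
  layout <- match.arg(layout)
  len <- nchar(seq)
  assert_that(len > 0, "empty read")
  if (layout == "paired_end") return(list(seq = seq, qual = qual))
  if (len <= trim) {
    warning(sprintf("single-end read of length %d <= trim %d dropped", len, trim))
    return(NULL)
  }
  list(seq = substr(seq, 1L, len - trim),
       qual = if (is.null(qual)) NULL else substr(qual, 1L, len - trim))
}

#' Per-cell QC gate on uniquely mapped bases
#'
#' @param uniquely_mapped_bases numeric vector of per-cell totals.
#' @param threshold keep a cell iff it has strictly more uniquely mapped
#'   bases than this (default 0.5 Gb).
#' @return logical vector, `TRUE` = keep.
#' @export
qc_cell <- function(uniquely_mapped_bases, threshold = 5e8) {
  assert_that(all(uniquely_mapped_bases >= 0), "mapped bases must be >= 0")
  uniquely_mapped_bases > threshold
}

#' Read SAM alignment records
#'
#' Parses a SAM file (converted through BAM internally) into a per-record
#' table with coordinates, CIGAR, strand, sequence and qualities. Unmapped
#' and duplicate-flagged records are skipped.
#'
#' @param path SAM file.
#' @return a `data.table` with one row per usable alignment record.
#' @export
read_sam <- function(path) {
  assert_that(file.exists(path), "SAM file not found: %s", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  data.table(
    qname = S4Vectors::mcols(ga)$qname,
    flag = S4Vectors::mcols(ga)$flag,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    seq = as.character(S4Vectors::mcols(ga)$seq),
    qual = as.character(S4Vectors::mcols(ga)$qual))
}

## Expand aligned records to one row per aligned base (M/=/X ops only).
## read-end status is measured on the biological read: last 10 bases (3')
## or first 5 bases (5'), after any upstream trimming.
explode_alignments <- function(aln, end3 = 10L, end5 = 5L) {
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = c("M", "=", "X"))
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    aln$cigar, ops = c("M", "=", "X"))
  nblk <- S4Vectors::elementNROWS(rref)
  fr <- unlist(rref)
  fq <- unlist(rqry)
  widths <- IRanges::width(fr)
  idx <- rep(rep(seq_len(nrow(aln)), nblk), widths)  # alignment row per base
  off <- sequence(widths) - 1L
  refpos <- rep(IRanges::start(fr), widths) + off
  qpos <- rep(IRanges::start(fq), widths) + off
  seqs <- strsplit(aln$seq, "", fixed = TRUE)
  quals <- lapply(aln$qual, function(q) utf8ToInt(q) - 33L)
  len <- nchar(aln$seq)
  gidx <- c(0L, cumsum(len))[idx] + qpos  # flat index into concatenated reads
  dt <- data.table(
    chrom = aln$chrom[idx],
    pos = refpos,
    strand = aln$strand[idx],
    base = unlist(seqs, use.names = FALSE)[gidx],
    qual = unlist(quals, use.names = FALSE)[gidx])
  # biological position within the read: minus-strand SAM records store the
  # reverse complement, so query position 1 is the biological 3' end
  biopos <- ifelse(dt$strand == "-", len[idx] - qpos + 1L, qpos)
  dt[, is_end := biopos <= end5 | biopos > len[idx] - end3]
  dt
}

#' Build pileup columns from aligned reads
#'
#' Tallies quality-passing base calls per genomic site, split by alignment
#' strand, and counts variant/reference bases falling in read ends (last 10
#' bases towards the 3' end, first 5 towards the 5' end of the biological
#' read) versus read middles.
#'
#' @param aln alignment table from [read_sam()].
#' @param reference a named [Biostrings::DNAStringSet] (or object coercible
#'   to one) with the reference contigs.
#' @param min_base_quality minimum phred quality for a base call to count.
#' @param cell_id cell identifier stored in the output.
#' @return a `data.table` of pileup columns, one row per covered site with at
#'   least one quality-passing base: per-base per-strand counts
#'   (`A_fwd` ... `T_rev`), `depth`, and end/middle counts for variant
#'   (non-reference) and reference bases.
#' @export
build_pileup <- function(aln, reference, min_base_quality = 20L,
                         cell_id = "cell") {
  reference <- as(reference, "DNAStringSet")
  bad <- setdiff(unique(aln$chrom), names(reference))
  if (length(bad))
    stopf("chromosome(s) absent from reference: %s", paste(bad, collapse = ", "))
  if (nrow(aln) == 0) return(empty_pileup())
  bt <- explode_alignments(aln)
  bt <- bt[qual >= min_base_quality & base %in% BASES]
  if (nrow(bt) == 0) return(empty_pileup())
  bt[, ref := reference_base(reference, chrom, pos)]
  pu <- bt[, {
    fwd <- strand == "+"
    cnt <- function(b, s) sum(base == b & (fwd == s))
    isref <- base == ref[1]
    list(ref = ref[1], depth = .N,
         A_fwd = cnt("A", TRUE), C_fwd = cnt("C", TRUE),
         G_fwd = cnt("G", TRUE), T_fwd = cnt("T", TRUE),
         A_rev = cnt("A", FALSE), C_rev = cnt("C", FALSE),
         G_rev = cnt("G", FALSE), T_rev = cnt("T", FALSE),
         alt_end = sum(!isref & is_end), alt_mid = sum(!isref & !is_end),
         ref_end = sum(isref & is_end), ref_mid = sum(isref & !is_end))
  }, by = .(chrom, pos)]
  pu[, cell_id := cell_id]
  setcolorder(pu, pileup_cols())
  setkey(pu, chrom, pos)
  pu[]
}

pileup_cols <- function() {
  c("cell_id", "chrom", "pos", "ref", "depth",
    "A_fwd", "C_fwd", "G_fwd", "T_fwd", "A_rev", "C_rev", "G_rev", "T_rev",
    "alt_end", "alt_mid", "ref_end", "ref_mid")
}

empty_pileup <- function() {
  dt <- data.table(cell_id = character(), chrom = character(), pos = integer(),
                   ref = character(), depth = integer())
  for (cc in setdiff(pileup_cols(), names(dt))) dt[, (cc) := integer()]
  setcolorder(dt, pileup_cols())
  dt
}

## reference base lookup (1-based), vectorised over sites
reference_base <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    s <- as.character(reference[[ch]])
    out[i] <- substring(s, pos[i], pos[i])
  }
  out
}

## per-base total and strand count helpers over a pileup table
pileup_base_totals <- function(pu) {
  cbind(A = pu$A_fwd + pu$A_rev, C = pu$C_fwd + pu$C_rev,
        G = pu$G_fwd + pu$G_rev, T = pu$T_fwd + pu$T_rev)
}

#' Per-transcriptome background mismatch rate
#'
#' Estimates the probability that an aligned, quality-passing base disagrees
#' with the reference, for one cell. By default every quality-passing base
#' contributes; the two-pass mode drops sites whose mismatch frequency
#' reaches `freq_threshold` (candidate variants) from both counts.
#'
#' @param pileup pileup columns of a single cell.
#' @param aligned_bases optional total quality-passing aligned bases for the
#'   cell; when the pileup is sparse (mismatch-bearing columns only) this
#'   supplies the true denominator. Defaults to the summed column depths.
#' @param exclude_high_freq drop columns with mismatch frequency >=
#'   `freq_threshold` from numerator and denominator.
#' @param freq_threshold frequency above which a column counts as a
#'   candidate variant in the two-pass mode.
#' @return a list with `cell_id`, `p`, `mismatch_bases`, `aligned_bases`.
#' @export
estimate_background_rate <- function(pileup, aligned_bases = NULL,
                                     exclude_high_freq = FALSE,
                                     freq_threshold = 0.1) {
  assert_that(nrow(pileup) >= 1, "no pileup columns")
  assert_that(length(unique(pileup$cell_id)) == 1,
              "background rate is per-transcriptome: one cell at a time")
  tot <- pileup_base_totals(pileup)
  refn <- tot[cbind(seq_len(nrow(pileup)), match(pileup$ref, BASES))]
  altn <- pileup$depth - refn
  keep <- rep(TRUE, nrow(pileup))
  excluded_bases <- 0
  if (exclude_high_freq) {
    keep <- altn / pileup$depth < freq_threshold
    excluded_bases <- sum(pileup$depth[!keep])
  }
  mismatch <- sum(altn[keep])
  denom <- if (is.null(aligned_bases)) sum(pileup$depth[keep])
           else aligned_bases - excluded_bases
  assert_that(denom > 0, "zero aligned bases for cell %s", pileup$cell_id[1])
  list(cell_id = pileup$cell_id[1], p = mismatch / denom,
       mismatch_bases = mismatch, aligned_bases = denom)
}

#' Background rates for every cell of a cohort
#'
#' @param pileup pooled pileup columns (any number of cells).
#' @param meta optional cell metadata with `cell_id` and `aligned_bases`
#'   columns supplying sparse-pileup denominators.
#' @inheritParams estimate_background_rate
#' @return `data.table` with one row per cell: `cell_id`, `p`,
#'   `mismatch_bases`, `aligned_bases`.
#' @export
background_rates <- function(pileup, meta = NULL, exclude_high_freq = FALSE,
                             freq_threshold = 0.1) {
  rates <- lapply(split(pileup, by = "cell_id"), function(pu) {
    ab <- NULL
    if (!is.null(meta) && "aligned_bases" %in% names(meta)) {
      m <- meta[meta$cell_id == pu$cell_id[1], ]
      if (nrow(m) == 1) ab <- m$aligned_bases
    }
    as.data.table(estimate_background_rate(pu, aligned_bases = ab,
                                           exclude_high_freq = exclude_high_freq,
                                           freq_threshold = freq_threshold))
  })
  rbindlist(rates)
}
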