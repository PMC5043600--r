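## Annotation of retained mismatches: Alu class, A-to-I retention rule,
## mismatch spectrum, neighbour preference, genic features, coding effects,
## miRNA-target overlap.

sites_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
}

#' Classify mismatch sites
#'
#' Assigns each site its substitution type on the reference strand, its
#' Alu / non-Alu region class (closed 1-based intervals), and membership in
#' a known-editing-site catalogue (position + strand sense when the
#' catalogue carries strand, positional otherwise).
#'
#' @param sites `data.table` with `chrom`, `pos`, `ref`, `alt`.
#' @param alu `GRanges` of Alu intervals.
#' @param catalogue `data.table` with `chrom`, `pos` and optionally
#'   `strand`, or `NULL`.
#' @return the input with `region_class`, `mismatch_type`, `in_catalogue`
#'   columns added (copy).
#' @export
classify_mismatch <- function(sites, alu, catalogue = NULL) {
  out <- copy(as.data.table(sites))
  out[, region_class := ifelse(
    IRanges::overlapsAny(sites_granges(chrom, pos), alu), "Alu", "non-Alu")]
  out[, mismatch_type := paste0(ref, "-to-", alt)]
  if (is.null(catalogue) || nrow(catalogue) == 0) {
    out[, in_catalogue := FALSE]
  } else if ("strand" %in% names(catalogue)) {
    # strand-sense aware: an A-to-G site matches a + entry, T-to-C a - entry
    sense <- ifelse(out$ref == "T", "-", "+")
    out[, in_catalogue := site_key(chrom, pos, sense) %in%
          site_key(catalogue$chrom, catalogue$pos, catalogue$strand)]
  } else {
    out[, in_catalogue := site_key(chrom, pos) %in%
          site_key(catalogue$chrom, catalogue$pos)]
  }
  out[]
}

## per-transcript genomic spans derived from exon rows
transcript_spans <- function(genes) {
  ex <- genes[genes$feature == "exon"]
  ex[, .(chrom = chrom[1], start = min(start), end = max(end),
         strand = strand[1], gene_id = gene_id[1],
         transcript_type = transcript_type[1]),
     by = transcript_id]
}

#' A-to-I retention rule
#'
#' Keeps Alu A-to-G mismatches unconditionally and non-Alu A-to-G
#' mismatches only when present in the known-editing catalogue. In the
#' default `transcript_sense` mode a genomic T-to-C mismatch is treated as
#' transcript-sense A-to-G when an overlapping annotated gene lies on the
#' minus strand (libraries are not strand-specific), subject to the same
#' Alu / catalogue rule; `strict` mode drops all T-to-C. Everything else is
#' excluded from the editome but still counted in the mismatch spectrum.
#'
#' @param classified output of [classify_mismatch()].
#' @param genes gene-model table (needed for the minus-strand gene lookup
#'   in `transcript_sense` mode; may be `NULL` under `strict`).
#' @param mode `"transcript_sense"` or `"strict"`.
#' @return logical vector, `TRUE` = retained as a candidate A-to-I site.
#' @export
retain_a2i <- function(classified, genes = NULL,
                       mode = c("transcript_sense", "strict")) {
  mode <- match.arg(mode)
  ag <- classified$ref == "A" & classified$alt == "G"
  keep_rule <- function(is_sense) {
    is_sense & (classified$region_class == "Alu" | classified$in_catalogue)
  }
  retained <- keep_rule(ag)
  if (mode == "transcript_sense" && !is.null(genes)) {
    tc <- classified$ref == "T" & classified$alt == "C"
    if (any(tc)) {
      spans <- transcript_spans(as.data.table(genes))
      minus <- spans[spans$strand == "-"]
      on_minus <- rep(FALSE, nrow(classified))
      if (nrow(minus) > 0) {
        gr <- GenomicRanges::GRanges(minus$chrom,
                                     IRanges::IRanges(minus$start, minus$end))
        on_minus <- IRanges::overlapsAny(
          sites_granges(classified$chrom, classified$pos), gr)
      }
      retained <- retained | keep_rule(tc & on_minus)
    }
  }
  retained
}

#' Per-cell mismatch spectrum
#'
#' Counts and fractions of the 12 substitution types among a cell's
#' mismatch sites.
#'
#' @param candidates `data.table` with `cell_id`, `ref`, `alt`.
#' @return `data.table`: `cell_id`, `mismatch_type`, `count`, `fraction`.
#' @export
mismatch_spectrum <- function(candidates) {
  types <- as.vector(outer(BASES, BASES, function(a, b)
    paste0(a, "-to-", b)))
  types <- types[substr(types, 1, 1) != substr(types, 6, 6)]
  dt <- as.data.table(candidates)[, .(cell_id, type = paste0(ref, "-to-", alt))]
  out <- dt[, .(count = .N), by = .(cell_id, mismatch_type = type)]
  grid <- CJ(cell_id = unique(dt$cell_id), mismatch_type = types)
  out <- out[grid, on = c("cell_id", "mismatch_type")]
  out[is.na(count), count := 0L]
  out[, fraction := count / sum(count), by = cell_id]
  out[]
}

#' Neighbour-base preference around edited sites
#'
#' ADAR-mediated editing under-represents G immediately 5' of the edited
#' adenosine and over-represents G immediately 3' of it. For A-to-G sites
#' the -1/+1 G fractions are read off the reference strand; genomic T-to-C
#' sites are evaluated on the complementary strand (+1 of the edited A is
#' the complement of the base at genomic pos - 1). Sites at contig edges
#' are excluded.
#'
#' @param sites `data.table` with `chrom`, `pos`, `ref`, `alt`; only
#'   A-to-G and T-to-C rows are used.
#' @param reference named `DNAStringSet`.
#' @return list with `minus1_g_frac`, `plus1_g_frac`, `n_sites`.
#' @export
neighbor_preference <- function(sites, reference) {
  s <- as.data.table(sites)
  s <- s[(ref == "A" & alt == "G") | (ref == "T" & alt == "C")]
  assert_that(nrow(s) >= 1, "no A-to-G / T-to-C sites")
  lens <- setNames(Biostrings::width(reference), names(reference))
  inside <- s$pos > 1 & s$pos < lens[s$chrom]
  s <- s[inside]
  assert_that(nrow(s) >= 1, "all sites at contig edges")
  left <- reference_base(reference, s$chrom, s$pos - 1L)
  right <- reference_base(reference, s$chrom, s$pos + 1L)
  is_tc <- s$ref == "T"
  minus1 <- ifelse(is_tc, comp_base(right), left)
  plus1 <- ifelse(is_tc, comp_base(left), right)
  list(minus1_g_frac = mean(minus1 == "G"),
       plus1_g_frac = mean(plus1 == "G"),
       n_sites = nrow(s))
}

#' Assign genic features to sites
#'
#' Feature by precedence CDS > 5'UTR > 3'UTR > ncRNA > intronic >
#' intergenic across all overlapping transcripts; ncRNA means exonic
#' overlap with a transcript lacking a CDS. The reported gene is the one
#' providing the winning feature (first by gene id on ties).
#'
#' @param sites `data.table` with `chrom`, `pos`.
#' @param genes gene-model table: `chrom`, `start`, `end`, `strand`,
#'   `feature` (exon / CDS / five_prime_utr / three_prime_utr), `gene_id`,
#'   `transcript_id`, `transcript_type` (coding / ncRNA).
#' @return `data.table` aligned with `sites`: `feature`, `gene_id`,
#'   `gene_strand`.
#' @export
assign_feature <- function(sites, genes) {
  genes <- as.data.table(genes)
  need <- c("chrom", "start", "end", "strand", "feature", "gene_id",
            "transcript_id", "transcript_type")
  miss <- setdiff(need, names(genes))
  assert_that(length(miss) == 0, "malformed gene model: missing %s",
              paste(miss, collapse = ", "))
  gr <- sites_granges(sites$chrom, sites$pos)
  hit <- function(tab) {
    if (nrow(tab) == 0) return(rep(NA_integer_, length(gr)))
    g <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
    GenomicRanges::findOverlaps(gr, g, select = "first")
  }
  coding <- genes[genes$transcript_type == "coding"]
  nc_ex <- genes[genes$transcript_type == "ncRNA" & genes$feature == "exon"]
  spans <- transcript_spans(genes)
  layers <- list(
    CDS = coding[coding$feature == "CDS"],
    `5UTR` = coding[coding$feature == "five_prime_utr"],
    `3UTR` = coding[coding$feature == "three_prime_utr"],
    ncRNA = nc_ex,
    intronic = spans)
  feature <- rep("intergenic", length(gr))
  gene_id <- rep(NA_character_, length(gr))
  gene_strand <- rep("none", length(gr))
  for (nm in rev(names(layers))) {
    idx <- hit(layers[[nm]])
    sel <- !is.na(idx)
    feature[sel] <- nm
    gene_id[sel] <- layers[[nm]]$gene_id[idx[sel]]
    gene_strand[sel] <- layers[[nm]]$strand[idx[sel]]
  }
  data.table(feature = feature, gene_id = gene_id, gene_strand = gene_strand)
}

## CDS model of one transcript: ordered genomic segments + transcript seq
cds_model <- function(genes, transcript_id, reference) {
  tid <- transcript_id
  cds <- as.data.table(genes)[transcript_id == tid & feature == "CDS"]
  assert_that(nrow(cds) > 0, "transcript %s has no CDS", tid)
  setorder(cds, start)
  strand <- cds$strand[1]
  segs <- lapply(seq_len(nrow(cds)), function(i)
    Biostrings::subseq(reference[[cds$chrom[i]]], cds$start[i], cds$end[i]))
  seq <- do.call(Biostrings::xscat, segs)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  if (Biostrings::nchar(seq) %% 3 != 0)
    stopf("CDS of transcript %s has incomplete terminal codon", tid)
  list(cds = cds, strand = strand, seq = seq)
}

#' Coding effect of an edit within a CDS
#'
#' Locates the edited base inside the transcript's CDS (genomic A-to-G
#' reads as transcript A-to-G on plus-strand genes; on minus-strand genes
#' the genomic T-to-C substitution maps to transcript A-to-G), rebuilds the
#' containing codon, translates with the standard genetic code, and
#' compares amino acids.
#'
#' @param chrom,pos,alt the edited genomic site and alternate allele.
#' @param transcript one transcript id present in `genes`.
#' @param genes gene-model table.
#' @param reference named `DNAStringSet`.
#' @return list: `effect` ("synonymous"/"nonsynonymous"), `aa_ref`,
#'   `aa_alt`, `codon_ref`, `codon_alt`, `cds_pos`.
#' @export
coding_effect <- function(chrom, pos, alt, transcript, genes, reference) {
  m <- cds_model(genes, transcript, reference)
  cds <- m$cds
  row <- which(cds$chrom == chrom & cds$start <= pos & cds$end >= pos)
  assert_that(length(row) == 1, "site %s:%d not in CDS of %s", chrom, pos,
              transcript)
  offs <- c(0, cumsum(cds$end - cds$start + 1L))
  fwd_pos <- offs[row] + (pos - cds$start[row]) + 1L
  L <- Biostrings::nchar(m$seq)
  cds_pos <- if (m$strand == "+") fwd_pos else L - fwd_pos + 1L
  alt_t <- if (m$strand == "+") alt else unname(comp_base(alt))
  codon_i <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon_ref <- as.character(Biostrings::subseq(m$seq, codon_i * 3L + 1L,
                                               codon_i * 3L + 3L))
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_t
  # initiator semantics only apply to the first codon of the CDS
  internal <- codon_i > 0L
  tr1 <- function(cod) as.character(
    Biostrings::translate(Biostrings::DNAString(cod),
                          no.init.codon = internal))
  aa_ref <- tr1(codon_ref)
  aa_alt <- tr1(codon_alt)
  list(effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
       aa_ref = aa_ref, aa_alt = aa_alt, codon_ref = codon_ref,
       codon_alt = codon_alt, cds_pos = cds_pos)
}

#' miRNA-target overlap
#'
#' A site sits in a miRNA-targeted region iff it overlaps a seed-match
#' interval and its genic feature is 3'UTR (targets are defined within
#' 3' untranslated regions).
#'
#' @param chrom,pos,feature site coordinates and assigned feature.
#' @param targets `GRanges` of seed-match intervals.
#' @return logical vector.
#' @export
mirna_target_overlap <- function(chrom, pos, feature, targets) {
  if (is.null(targets) || length(targets) == 0) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(sites_granges(chrom, pos), targets) & feature == "3UTR"
}

#' Annotate the retained editome
#'
#' Applies classification, the A-to-I retention rule, genic features,
#' per-transcript coding effects (CDS sites), and miRNA-target overlap to
#' the filter-cascade survivors.
#'
#' @param retained `data.table` of retained candidates (`cell_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `n`, `k`, `freq`).
#' @param ann annotation bundle (see [run_filter_cascade()]) additionally
#'   holding `genes`, `catalogue`, `mirna_targets`.
#' @param config a [pipeline_config()].
#' @return list with `editome` (per-cell annotated A-to-I sites) and
#'   `coding` (per-transcript coding effects of CDS sites).
#' @export
annotate_editome <- function(retained, ann, config = pipeline_config()) {
  cls <- classify_mismatch(retained, ann$alu, ann$catalogue)
  keep <- retain_a2i(cls, ann$genes, mode = config$t2c_mode)
  ed <- cls[keep]
  if (nrow(ed) == 0) return(list(editome = ed, coding = data.table()))
  fa <- assign_feature(ed, ann$genes)
  ed[, `:=`(feature = fa$feature, gene_id = fa$gene_id,
            gene_strand = fa$gene_strand)]
  ed[, mirna_target := mirna_target_overlap(chrom, pos, feature,
                                            ann$mirna_targets)]
  coding <- data.table()
  cds_sites <- unique(ed[feature == "CDS", .(chrom, pos, ref, alt)])
  if (nrow(cds_sites) > 0) {
    genes <- as.data.table(ann$genes)
    cdsg <- genes[feature == "CDS"]
    rows <- lapply(seq_len(nrow(cds_sites)), function(i) {
      st <- cds_sites[i]
      tids <- unique(cdsg[chrom == st$chrom & start <= st$pos & end >= st$pos,
                          .(transcript_id, gene_id)])
      rbindlist(lapply(seq_len(nrow(tids)), function(j) {
        eff <- coding_effect(st$chrom, st$pos, st$alt,
                             tids$transcript_id[j], genes, ann$reference)
        data.table(chrom = st$chrom, pos = st$pos, ref = st$ref,
                   alt = st$alt, transcript_id = tids$transcript_id[j],
                   gene_id = tids$gene_id[j], effect = eff$effect,
                   aa_ref = eff$aa_ref, aa_alt = eff$aa_alt,
                   cds_pos = eff$cds_pos)
      }))
    })
    coding <- rbindlist(rows)
  }
  ed[, coding_effect := "not_applicable"]
  if (nrow(coding) > 0) {
    eff_site <- coding[, .(effect = if (any(effect == "nonsynonymous"))
      "nonsynonymous" else "synonymous"), by = .(chrom, pos, alt)]
    ed[eff_site, on = c("chrom", "pos", "alt"),
       coding_effect := ifelse(feature == "CDS", i.effect, "not_applicable")]
  }
  list(editome = ed[], coding = coding)
}
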