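## The eight-filter cascade applied to detected variant candidates.

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-tailed P obtained by summing, at fixed margins, the
#' hypergeometric probabilities of every table at most as probable as the
#' observed one. Tables with a zero margin admit a single configuration and
#' return P = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-tailed P value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == 2), "need a 2x2 table")
  assert_that(all(tab >= 0), "counts must be non-negative")
  fet_p_vec(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
}

## vectorised two-tailed FET over rows [[a, b], [c, d]]; duplicate tables
## are computed once
fet_p_vec <- function(a, b, c, d) {
  key <- paste(a, b, c, d)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    m <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m)$p.value
  }, 0)
  unname(pu[match(key, key[uk])])
}

#' Strand-bias filter
#'
#' Variant support concentrated on one alignment strand flags a sequencing
#' artifact. With variant strand frequency v = sense-variant / k and
#' reference strand frequency r defined analogously over reference reads,
#' a site fails iff (two-tailed FET P on the variant/reference x
#' sense/antisense table < `fet_alpha` and |v - 0.5| > |r - 0.5|) or
#' v > 0.9 or v < 0.1. When no reference reads remain, r is taken as 0.5
#' (no measurable reference preference).
#'
#' @param var_fwd,var_rev,ref_fwd,ref_rev per-strand supporting read counts
#'   (vectorised).
#' @param fet_alpha Fisher cutoff.
#' @return `data.table` with `decision` ("pass"/"fail"), `fet_p`,
#'   `var_strand_freq`, `ref_strand_freq`.
#' @export
strand_bias_filter <- function(var_fwd, var_rev, ref_fwd, ref_rev,
                               fet_alpha = 0.005) {
  k <- var_fwd + var_rev
  assert_that(all(k >= 1), "strand-bias filter needs >= 1 variant read")
  v <- var_fwd / k
  nref <- ref_fwd + ref_rev
  r <- ifelse(nref > 0, ref_fwd / nref, 0.5)
  p <- fet_p_vec(var_fwd, var_rev, ref_fwd, ref_rev)
  fail <- (p < fet_alpha & abs(v - 0.5) > abs(r - 0.5)) | v > 0.9 | v < 0.1
  data.table(decision = ifelse(fail, "fail", "pass"), fet_p = p,
             var_strand_freq = v, ref_strand_freq = r)
}

#' Read-position bias filter
#'
#' Variant support concentrated in read ends (last 10 bases towards the 3'
#' end, first 5 towards the 5' end) flags an alignment artifact. With read
#' end frequency e = variant-end / k, a site fails iff (FET P on the
#' variant/reference x end/middle table < `fet_alpha` and e exceeds the
#' read middle frequency 1 - e) or e > 0.9.
#'
#' @param var_end,var_mid,ref_end,ref_mid end/middle supporting base counts.
#' @param fet_alpha Fisher cutoff.
#' @return `data.table` with `decision`, `fet_p`, `end_freq`.
#' @export
position_bias_filter <- function(var_end, var_mid, ref_end, ref_mid,
                                 fet_alpha = 0.05) {
  k <- var_end + var_mid
  assert_that(all(k >= 1), "position-bias filter needs >= 1 variant base")
  e <- var_end / k
  p <- fet_p_vec(var_end, var_mid, ref_end, ref_mid)
  fail <- (p < fet_alpha & e > 1 - e) | e > 0.9
  data.table(decision = ifelse(fail, "fail", "pass"), fet_p = p, end_freq = e)
}

#' Default realigner: local alignment with banded-alignment scoring
#'
#' Aligns one read against every contig of a combined reference
#' (genome + transcripts) with local (Smith-Waterman) alignment, scoring
#' match +1, mismatch -3, gap open -5, gap extend -2, and reports the best
#' placement per contig. The best-scoring placements across contigs (ties
#' included) are the read's candidate placements.
#'
#' @param read character, read sequence.
#' @param combined_ref named `DNAStringSet`.
#' @return `data.table` with `refname`, `start`, `end`, `score` for the
#'   best-scoring placement on each contig.
#' @export
default_realigner <- function(read, combined_ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  res <- lapply(names(combined_ref), function(nm) {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(read),
                                        combined_ref[[nm]],
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    sub <- Biostrings::subject(al)
    data.table(refname = nm, start = Biostrings::start(sub),
               end = Biostrings::end(sub), score = Biostrings::score(al))
  })
  rbindlist(res)
}

#' Realignment-support filter
#'
#' Re-places every variant-supporting read of a site against a combined
#' reference and keeps the site only if at least `min_support_frac` of them
#' realign to it (a best placement on the site's contig covering its
#' position). Guards against mismatches created by misalignment to
#' high-similarity regions.
#'
#' @param chrom,pos the candidate site.
#' @param read_seqs character vector of variant-supporting read sequences.
#' @param combined_ref named `DNAStringSet` (genome + transcript contigs).
#' @param min_support_frac minimum realigning fraction.
#' @param aligner a function `(read, combined_ref) -> data.table(refname,
#'   start, end, score)`; defaults to [default_realigner()].
#' @param strict if `TRUE`, a read with tied best placements on several
#'   locations only counts when every tie covers the site; the default
#'   counts a read if any tied best placement covers it.
#' @return list with `decision`, `realign_frac`, `n_reads`.
#' @export
realignment_filter <- function(chrom, pos, read_seqs, combined_ref,
                               min_support_frac = 0.9,
                               aligner = default_realigner,
                               strict = FALSE) {
  assert_that(length(combined_ref) > 0 && sum(Biostrings::width(combined_ref)) > 0,
              "empty combined reference")
  assert_that(length(read_seqs) >= 1, "no variant-supporting reads")
  hits <- vapply(read_seqs, function(rd) {
    pl <- aligner(rd, combined_ref)
    best <- pl[pl$score == max(pl$score), ]
    covers <- best$refname == chrom & best$start <= pos & best$end >= pos
    if (strict) all(covers) else any(covers)
  }, NA, USE.NAMES = FALSE)
  frac <- mean(hits)
  list(decision = if (frac >= min_support_frac) "pass" else "fail",
       realign_frac = frac, n_reads = length(read_seqs))
}

## does a >=min_run homopolymer run of any base include pos or touch it?
## Runs are measured on the reference strand in a window around the site.
homopolymer_hit <- function(reference, chrom, pos, min_run = 5L) {
  vapply(seq_along(pos), function(i) {
    contig <- reference[[chrom[i]]]
    lo <- max(1L, pos[i] - min_run)
    hi <- min(length(contig), pos[i] + min_run)
    win <- strsplit(as.character(Biostrings::subseq(contig, lo, hi)), "")[[1]]
    r <- rle(win)
    ends <- cumsum(r$lengths) + lo - 1L
    starts <- ends - r$lengths + 1L
    big <- r$lengths >= min_run
    any(big & starts <= pos[i] + 1L & ends >= pos[i] - 1L)
  }, NA)
}

#' Repeat / homopolymer / splice-proximity masks
#'
#' A site fails if it lies inside a simple-repeat interval, if a same-base
#' reference run of length >= `homopolymer_min_run` contains or is adjacent
#' to it, or — for non-Alu sites only — if it lies within `splice_window`
#' bases of an annotated exon-intron boundary.
#'
#' @param chrom,pos candidate sites (vectorised).
#' @param in_alu logical, site lies in an Alu interval.
#' @param reference named `DNAStringSet`.
#' @param simple_repeats `GRanges` of simple-repeat intervals (1-based).
#' @param splice_sites `data.table` with `chrom`, `pos` of splice positions.
#' @param homopolymer_min_run,splice_window mask parameters.
#' @return `data.table` with `decision` and the triggering mask statistics.
#' @export
region_mask_filter <- function(chrom, pos, in_alu, reference,
                               simple_repeats, splice_sites,
                               homopolymer_min_run = 5L, splice_window = 5L) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in_rep <- IRanges::overlapsAny(gr, simple_repeats)
  in_hp <- homopolymer_hit(reference, chrom, pos, homopolymer_min_run)
  near_splice <- rep(FALSE, length(pos))
  if (!is.null(splice_sites) && nrow(splice_sites) > 0) {
    for (ch in unique(chrom)) {
      sp <- splice_sites$pos[splice_sites$chrom == ch]
      if (!length(sp)) next
      i <- which(chrom == ch)
      near_splice[i] <- vapply(pos[i], function(p)
        any(abs(sp - p) <= splice_window), NA)
    }
  }
  splice_fail <- near_splice & !in_alu
  fail <- in_rep | in_hp | splice_fail
  data.table(decision = ifelse(fail, "fail", "pass"),
             in_simple_repeat = in_rep, in_homopolymer = in_hp,
             near_splice_non_alu = splice_fail)
}

#' Known-SNP filter
#'
#' Removes sites present in the union of supplied DNA SNP catalogues
#' (dbSNP-like lists, population panels, optional parental-exome variants).
#' When a catalogue provides an alternate allele and `alt_aware` is set,
#' a site matches only if position and alternate allele both agree.
#'
#' @param chrom,pos,alt candidate sites (vectorised).
#' @param snps `data.table` with `chrom`, `pos` and optionally `alt`
#'   (the union of all catalogues), or `NULL` for no catalogue.
#' @param alt_aware compare the alternate allele when available.
#' @return `data.table` with `decision` and `in_snp_catalogue`.
#' @export
known_snp_filter <- function(chrom, pos, alt, snps, alt_aware = TRUE) {
  if (is.null(snps) || nrow(snps) == 0) {
    return(data.table(decision = rep("pass", length(pos)),
                      in_snp_catalogue = FALSE))
  }
  if (alt_aware && "alt" %in% names(snps) && !all(is.na(snps$alt))) {
    hit <- site_key(chrom, pos, alt) %in%
      site_key(snps$chrom, snps$pos, snps$alt)
  } else {
    hit <- site_key(chrom, pos) %in% site_key(snps$chrom, snps$pos)
  }
  data.table(decision = ifelse(hit, "fail", "pass"), in_snp_catalogue = hit)
}

#' Cross-embryo recurrence filter
#'
#' Rare germline SNPs are private to one individual, whereas true editing
#' recurs across individuals: a site detected in cells of exactly one
#' embryo (over the whole cohort of post-threshold detections) fails.
#'
#' @param detections `data.table` of post-threshold detections with
#'   `cell_id`, `chrom`, `pos`, `alt`.
#' @param meta cell metadata with `cell_id` and `embryo_id`.
#' @return `data.table` keyed by site: `chrom`, `pos`, `alt`, `n_embryos`,
#'   `decision`.
#' @export
recurrence_filter <- function(detections, meta) {
  assert_that(all(c("cell_id", "embryo_id") %in% names(meta)),
              "meta must provide cell_id and embryo_id")
  emb <- meta$embryo_id[match(detections$cell_id, meta$cell_id)]
  assert_that(!anyNA(emb) && all(nzchar(emb)),
              "missing embryo metadata for some detected cell")
  dt <- data.table(chrom = detections$chrom, pos = detections$pos,
                   alt = detections$alt, embryo = emb)
  out <- dt[, .(n_embryos = uniqueN(embryo)), by = .(chrom, pos, alt)]
  out[, decision := ifelse(n_embryos == 1L, "fail", "pass")]
  out[]
}

#' Mismatch-frequency cap
#'
#' Sites with mismatch frequency strictly above the cap look like
#' homozygous genomic variants rather than editing and are removed.
#'
#' @param freq mismatch frequencies (vectorised).
#' @param cap frequency cap (strict inequality).
#' @return `data.table` with `decision` and `freq`.
#' @export
frequency_cap_filter <- function(freq, cap = 0.95) {
  data.table(decision = ifelse(freq > cap, "fail", "pass"), freq = freq)
}

#' Apply the full filter cascade to detected candidates
#'
#' Runs strand bias, position bias, (optional) realignment support,
#' region masks, known-SNP, cross-embryo recurrence and the frequency cap
#' on every post-threshold detection, recording a per-filter verdict.
#' Each filter is a pure predicate, so the final retained set does not
#' depend on filter order; the attrition table reports survivors in the
#' canonical order above.
#'
#' @param candidates output of [call_candidates()]; only rows with
#'   `detected == TRUE` enter the cascade.
#' @param meta cell metadata (`cell_id`, `embryo_id`).
#' @param ann annotation bundle: a list with `reference` (`DNAStringSet`),
#'   `alu` and `simple_repeats` (`GRanges`), `splice_sites`
#'   (`data.table(chrom, pos)`), `snps` (`data.table(chrom, pos[, alt])`).
#' @param config a [pipeline_config()].
#' @param realign optional list with `reads` (a function
#'   `(cell_id, chrom, pos, alt) -> character` returning variant-supporting
#'   read sequences) and `combined_ref`; when absent, the realignment
#'   verdict is `not_applied` (pileup-only inputs carry no read sequences).
#' @return list with `candidates` (verdict-augmented table, logical
#'   `retained` column) and `attrition` (sites surviving after each stage).
#' @export
run_filter_cascade <- function(candidates, meta, ann,
                               config = pipeline_config(), realign = NULL) {
  det <- candidates[candidates$detected == TRUE]
  if (nrow(det) == 0) stopf("no detected candidates to filter")
  sb <- strand_bias_filter(det$alt_fwd, det$alt_rev, det$ref_fwd, det$ref_rev,
                           fet_alpha = config$strand_fet_alpha)
  det[, `:=`(strand_verdict = sb$decision, strand_fet_p = sb$fet_p,
             var_strand_freq = sb$var_strand_freq)]
  pb <- position_bias_filter(det$alt_end, det$alt_mid, det$ref_end, det$ref_mid,
                             fet_alpha = config$pos_fet_alpha)
  det[, `:=`(pos_verdict = pb$decision, pos_fet_p = pb$fet_p,
             end_freq = pb$end_freq)]
  if (is.null(realign)) {
    det[, `:=`(realign_verdict = "not_applied", realign_frac = NA_real_)]
  } else {
    rv <- mapply(function(cid, ch, p, a) {
      reads <- realign$reads(cid, ch, p, a)
      r <- realignment_filter(ch, p, reads, realign$combined_ref,
                              min_support_frac = config$realign_frac)
      c(r$decision, r$realign_frac)
    }, det$cell_id, det$chrom, det$pos, det$alt)
    det[, `:=`(realign_verdict = rv[1, ], realign_frac = as.numeric(rv[2, ]))]
  }
  gr <- GenomicRanges::GRanges(det$chrom, IRanges::IRanges(det$pos, det$pos))
  in_alu <- IRanges::overlapsAny(gr, ann$alu)
  mk <- region_mask_filter(det$chrom, det$pos, in_alu, ann$reference,
                           ann$simple_repeats, ann$splice_sites,
                           homopolymer_min_run = config$homopolymer_min_run,
                           splice_window = config$splice_window)
  det[, `:=`(mask_verdict = mk$decision, in_alu = in_alu)]
  sn <- known_snp_filter(det$chrom, det$pos, det$alt, ann$snps,
                         alt_aware = config$snp_alt_aware)
  det[, snp_verdict := sn$decision]
  rec <- recurrence_filter(det, meta)
  det[rec, on = c("chrom", "pos", "alt"),
      `:=`(recurrence_verdict = i.decision, n_embryos = i.n_embryos)]
  fc <- frequency_cap_filter(det$freq, cap = config$freq_cap)
  det[, freqcap_verdict := fc$decision]
  vcols <- c("strand_verdict", "pos_verdict", "realign_verdict",
             "mask_verdict", "snp_verdict", "recurrence_verdict",
             "freqcap_verdict")
  ok <- Reduce(`&`, lapply(vcols, function(cc) det[[cc]] != "fail"))
  det[, retained := ok]
  surv <- nrow(det)
  attr_dt <- data.table(stage = c("detected", vcols),
                        sites_out = c(surv, vapply(seq_along(vcols), function(i) {
                          keep <- Reduce(`&`, lapply(vcols[seq_len(i)],
                                                     function(cc) det[[cc]] != "fail"))
                          sum(keep)
                        }, 0L)))
  list(candidates = det[], attrition = attr_dt)
}
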