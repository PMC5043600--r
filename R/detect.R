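## Detection: binomial sequencing-error test, BH adjustment, hard thresholds.

#' Upper-tail binomial sequencing-error test
#'
#' Probability that at least `k` of `n` aligned bases disagree with the
#' reference purely through sequencing error, when each base errs
#' independently with the transcriptome's background rate `p`:
#' P(X >= k), X ~ Binomial(n, p). Computed through the regularised
#' incomplete-beta identity underlying [stats::pbinom()], which is
#' numerically stable for the tiny tail probabilities involved.
#'
#' @param k variant-supporting reads (vectorised).
#' @param n mapped reads.
#' @param p background mismatch rate.
#' @return upper-tail P values.
#' @export
binomial_error_test <- function(k, n, p) {
  assert_that(all(k >= 0 & n >= 0 & k <= n), "need 0 <= k <= n")
  assert_in_range(p, 0, 1, "background rate p")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (p(i) * m / i with enforced monotonicity, capped
#' at 1), returned in the input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values.
#' @export
bh_adjust <- function(pvalues) {
  assert_in_range(pvalues, 0, 1, "P values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hard detection thresholds
#'
#' A candidate passes iff its adjusted binomial P is below `alpha`, depth is
#' at least `min_depth`, variant support at least `min_alt`, and mismatch
#' frequency at least `min_freq`.
#'
#' @param n,k,freq,p_adjusted candidate statistics (vectorised).
#' @param alpha,min_depth,min_alt,min_freq thresholds.
#' @return logical vector.
#' @export
apply_detection_thresholds <- function(n, k, freq, p_adjusted,
                                       alpha = 0.01, min_depth = 4L,
                                       min_alt = 3L, min_freq = 0.1) {
  p_adjusted < alpha & n >= min_depth & k >= min_alt & freq >= min_freq
}

## majority alternate allele of each pileup column; the reference base is
## masked out, ties broken by base order A < C < G < T
majority_alt <- function(pu) {
  tot <- pileup_base_totals(pu)
  tot[cbind(seq_len(nrow(pu)), match(pu$ref, BASES))] <- -1L
  BASES[max.col(tot, ties.method = "first")]
}

#' Call variant candidates from pileup columns
#'
#' For every mismatch-bearing column, tests the variant count against the
#' cell's background mismatch rate with the upper-tail binomial test,
#' BH-adjusts within the chosen family, and applies the hard detection
#' thresholds. Multi-allelic columns carry only the majority alternate
#' allele forward.
#'
#' @param pileup pooled pileup columns (multiple cells allowed).
#' @param rates per-cell background rates from [background_rates()].
#' @param config a [pipeline_config()].
#' @return `data.table` of candidates: site, cell, counts (`n`, `k`, and the
#'   majority-alt strand split `alt_fwd`/`alt_rev` plus reference strand and
#'   end/middle counts), `freq`, `p_binomial`, `p_adjusted`, and a logical
#'   `detected` column from the hard thresholds.
#' @export
call_candidates <- function(pileup, rates, config = pipeline_config()) {
  tot <- pileup_base_totals(pileup)
  refn <- tot[cbind(seq_len(nrow(pileup)), match(pileup$ref, BASES))]
  cand <- pileup[pileup$depth - refn > 0]
  if (nrow(cand) == 0) return(cand)
  alt <- majority_alt(cand)
  fwd <- as.matrix(cand[, .(A_fwd, C_fwd, G_fwd, T_fwd)])
  rev <- as.matrix(cand[, .(A_rev, C_rev, G_rev, T_rev)])
  ai <- match(alt, BASES); ri <- match(cand$ref, BASES)
  rows <- seq_len(nrow(cand))
  out <- cand[, .(cell_id, chrom, pos, ref, depth, alt_end, alt_mid,
                  ref_end, ref_mid)]
  set(out, j = "alt", value = alt)
  out[, `:=`(alt_fwd = fwd[cbind(rows, ai)], alt_rev = rev[cbind(rows, ai)],
             ref_fwd = fwd[cbind(rows, ri)], ref_rev = rev[cbind(rows, ri)])]
  out[, n := depth]
  out[, k := alt_fwd + alt_rev]
  out[, freq := k / n]
  out[, multiallelic := (depth - fwd[cbind(rows, ri)] - rev[cbind(rows, ri)]) > k]
  nma <- sum(out$multiallelic)
  if (nma > 0)
    message(sprintf("%d multi-allelic column(s): only the majority alt carried forward", nma))
  p <- rates$p[match(out$cell_id, rates$cell_id)]
  assert_that(!anyNA(p), "missing background rate for some cell")
  out[, p_binomial := binomial_error_test(k, n, p)]
  if (config$bh_family == "per_cell") {
    out[, p_adjusted := bh_adjust(p_binomial), by = cell_id]
  } else {
    out[, p_adjusted := bh_adjust(p_binomial)]
  }
  out[, detected := apply_detection_thresholds(
    n, k, freq, p_adjusted, alpha = config$alpha,
    min_depth = config$min_depth, min_alt = config$min_alt,
    min_freq = config$min_freq)]
  setcolorder(out, c("cell_id", "chrom", "pos", "ref", "alt", "n", "k",
                     "freq", "p_binomial", "p_adjusted", "detected"))
  out[]
}
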