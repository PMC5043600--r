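#' Pipeline configuration
#'
#' Collects every tunable threshold of the detection pipeline, with the
#' published defaults: candidate sites need an adjusted binomial P below
#' `alpha` at depth >= `min_depth` with at least `min_alt` variant reads and a
#' mismatch frequency >= `min_freq`; the filter cascade then applies the
#' strand-bias and position-bias Fisher tests, the realignment-support
#' fraction, the repeat/homopolymer/splice masks, known-SNP removal,
#' cross-embryo recurrence, and the mismatch-frequency cap.
#'
#' @param alpha adjusted-P cutoff for the binomial sequencing-error test.
#' @param min_depth minimum mapped reads at a site.
#' @param min_alt minimum variant-supporting reads.
#' @param min_freq minimum mismatch frequency (k/n).
#' @param strand_fet_alpha Fisher cutoff for the strand-bias filter.
#' @param pos_fet_alpha Fisher cutoff for the position-bias filter.
#' @param realign_frac minimum fraction of variant reads that must realign to
#'   the site.
#' @param homopolymer_min_run reference same-base run length that masks a site.
#' @param splice_window distance (bp) to an annotated splice site that masks a
#'   non-Alu site.
#' @param freq_cap sites with mismatch frequency strictly above this are
#'   removed (germline-homozygote guard).
#' @param min_base_quality minimum base quality used when building pileups.
#' @param trim_3prime_single_end bases trimmed from the 3' end of single-end
#'   reads.
#' @param min_uniquely_mapped_bases per-cell QC gate (bases).
#' @param bh_family `"per_cell"` (default) adjusts binomial P values within
#'   each transcriptome; `"global"` adjusts over the pooled cohort.
#' @param t2c_mode `"transcript_sense"` (default) retains genomic T-to-C
#'   mismatches as A-to-I when an overlapping gene lies on the minus strand;
#'   `"strict"` drops all T-to-C.
#' @param snp_alt_aware whether SNP-catalogue matching also compares the
#'   alternate allele when the catalogue provides one.
#' @param exclude_high_freq two-pass background-rate mode: drop sites with
#'   mismatch frequency >= 0.1 from the numerator.
#' @param linkage agglomeration method for cell clustering.
#' @param spearman_bh_alpha BH cutoff for expression-frequency associations.
#' @param stage_fet_alpha Fisher cutoff for stage-specificity flags.
#' @param min_cells_per_stage stages with fewer cells are excluded from the
#'   stage-specificity tests.
#' @return a named list of class `editomics_config`.
#' @export
pipeline_config <- function(alpha = 0.01,
                            min_depth = 4L,
                            min_alt = 3L,
                            min_freq = 0.1,
                            strand_fet_alpha = 0.005,
                            pos_fet_alpha = 0.05,
                            realign_frac = 0.9,
                            homopolymer_min_run = 5L,
                            splice_window = 5L,
                            freq_cap = 0.95,
                            min_base_quality = 20L,
                            trim_3prime_single_end = 15L,
                            min_uniquely_mapped_bases = 5e8,
                            bh_family = c("per_cell", "global"),
                            t2c_mode = c("transcript_sense", "strict"),
                            snp_alt_aware = TRUE,
                            exclude_high_freq = FALSE,
                            linkage = "complete",
                            spearman_bh_alpha = 0.1,
                            stage_fet_alpha = 0.05,
                            min_cells_per_stage = 4L) {
  cfg <- list(
    alpha = alpha, min_depth = as.integer(min_depth),
    min_alt = as.integer(min_alt), min_freq = min_freq,
    strand_fet_alpha = strand_fet_alpha, pos_fet_alpha = pos_fet_alpha,
    realign_frac = realign_frac,
    homopolymer_min_run = as.integer(homopolymer_min_run),
    splice_window = as.integer(splice_window), freq_cap = freq_cap,
    min_base_quality = as.integer(min_base_quality),
    trim_3prime_single_end = as.integer(trim_3prime_single_end),
    min_uniquely_mapped_bases = min_uniquely_mapped_bases,
    bh_family = match.arg(bh_family), t2c_mode = match.arg(t2c_mode),
    snp_alt_aware = isTRUE(snp_alt_aware),
    exclude_high_freq = isTRUE(exclude_high_freq),
    linkage = linkage, spearman_bh_alpha = spearman_bh_alpha,
    stage_fet_alpha = stage_fet_alpha,
    min_cells_per_stage = as.integer(min_cells_per_stage))
  for (key in c("alpha", "min_freq", "strand_fet_alpha", "pos_fet_alpha",
                "realign_frac", "freq_cap", "spearman_bh_alpha",
                "stage_fet_alpha"))
    assert_in_range(cfg[[key]], 0, 1, key)
  assert_that(cfg$min_depth >= 1 && cfg$min_alt >= 1,
              "min_depth and min_alt must be positive")
  class(cfg) <- "editomics_config"
  cfg
}
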