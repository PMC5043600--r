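# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small cohort: 16 cells, 100 kb genome, fast enough for unit tests
tiny_cfg <- function(...) {
  args <- list(seed = 42L,
               stages = c("oocyte", "zygote", "4cell", "8cell"),
               embryos_per_stage = 2L, cells_per_embryo = 2L,
               genome_length = 180000L, n_genes = 10L, n_alu = 14L,
               n_true_edits = 80L, n_snps = 24L,
               n_strand_artifacts = 10L, n_end_artifacts = 10L,
               n_stage_genes = 2L, n_pair_genes = 1L,
               n_simple_repeats = 8L, n_homopolymers = 10L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_sim <- function() cached("tiny_sim", simulate_dataset(tiny_cfg()))

sim_annotations <- function(sim) {
  sim[c("reference", "alu", "simple_repeats", "splice_sites", "snps",
        "catalogue", "genes", "mirna_targets")]
}

tiny_result <- function() cached("tiny_result", {
  sim <- tiny_sim()
  run_pipeline(sim$pileup, sim$meta, sim_annotations(sim),
               sim_pipeline_config(sim$config))
})

# independent small oracles used across test files ------------------------

# term-by-term upper-tail binomial sum
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# two-tailed Fisher P by enumerating every table with the observed margins
oracle_fet <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  if (m == 0 || nn == 0 || kk == 0 || (a + b + c + d) == kk) {
  }
  lo <- max(0L, kk - nn); hi <- min(kk, m)
  if (lo == hi) return(1)
  probs <- stats::dhyper(lo:hi, m, nn, kk)
  pobs <- stats::dhyper(a, m, nn, kk)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# one pileup row with explicit counts (balanced defaults)
mk_pileup_row <- function(...) demo_pileup_row(...)

`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
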