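## Synthetic-data generator: toy genome + annotations + per-cell pileups
## with known truth, emulating the statistical structure the detection
## pipeline assumes (Alu-concentrated A-to-G edits with +1 G context,
## embryo-private SNPs, strand/read-end artifact sites, a stage-dependent
## editing-activity parameter coupled to a simulated ADAR expression value).

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Defaults give a
#' 1 Mb genome, 24 cells (4 per stage, 2 embryos per stage) across six
#' stages, 500 planted edits with frequencies uniform in \[0.1, 0.95\],
#' 200 embryo-private SNPs, 50 strand-artifact and 50 read-end-artifact
#' sites, a 1e-3 per-base error rate and mean depth 20. Editing activity is
#' flat through the 4-cell stage and drops sharply at the 8-cell stage,
#' with a simulated ADAR expression value coupled to the per-cell activity.
#'
#' @param seed RNG seed.
#' @param stages stage labels used (pronucleus omitted by default: too few
#'   cells at that stage to enter stage-wise tests).
#' @param embryos_per_stage,cells_per_embryo cohort layout.
#' @param genome_length,n_alu,alu_len,n_genes genome geometry.
#' @param p_err per-base sequencing error rate.
#' @param mean_depth mean per-site coverage.
#' @param depth_range per-cell multiplicative depth-factor range (uniform).
#' @param n_true_edits,edit_freq_range,alu_edit_frac planted edits: count,
#'   base-frequency prior, and fraction placed inside Alu intervals.
#' @param catalogue_frac fraction of non-Alu edits present in the
#'   known-editing catalogue.
#' @param context_g_plus1_prob,context_g_minus1_prob G probability at the
#'   +1 / -1 neighbour of each planted edit (transcript sense).
#' @param n_snps,snp_known_frac embryo-private SNPs (half at frequency 0.5,
#'   half at 1.0) and the fraction listed in the SNP catalogue.
#' @param n_strand_artifacts,n_end_artifacts,artifact_freq_range artifact
#'   sites (variant support confined to one strand / to read ends).
#' @param stage_activity named editing-activity multiplier per stage.
#' @param activity_noise_sd lognormal sd of per-cell activity noise.
#' @param adar_coupling,adar_noise_sd simulated ADAR RPKM =
#'   `adar_coupling * activity * exp(noise)`.
#' @param n_stage_genes,n_pair_genes,sites_per_stage_gene,stage_gene_freq
#'   genes whose miRNA-target edits are confined to one stage (or to two
#'   sequential stages).
#' @param coupled_gene plant one gene whose editing frequency decreases
#'   with its expression across stages.
#' @param end_frac fraction of read positions counting as read end
#'   (15 of 90 bases).
#' @param read_len nominal read length (bases).
#' @param n_simple_repeats,n_homopolymers,homopolymer_len masked-region
#'   geometry.
#' @param subthreshold_edit_frac misspecification mode: fraction of edits
#'   planted below the detectable frequency floor, to measure recall loss.
#' @return a list of class `editomics_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       stages = c("oocyte", "zygote", "2cell", "4cell",
                                  "8cell", "morula"),
                       embryos_per_stage = 2L,
                       cells_per_embryo = 2L,
                       genome_length = 1e6L,
                       n_alu = 40L,
                       alu_len = 300L,
                       n_genes = 30L,
                       p_err = 1e-3,
                       mean_depth = 20,
                       depth_range = c(1, 1),
                       n_true_edits = 500L,
                       edit_freq_range = c(0.1, 0.95),
                       alu_edit_frac = 0.8,
                       catalogue_frac = 0.9,
                       context_g_plus1_prob = 0.7,
                       context_g_minus1_prob = 0.1,
                       n_snps = 200L,
                       snp_known_frac = 0.5,
                       n_strand_artifacts = 50L,
                       n_end_artifacts = 50L,
                       artifact_freq_range = c(0.3, 0.6),
                       stage_activity = c(oocyte = 1, pronucleus = 1,
                                          zygote = 1, `2cell` = 1,
                                          `4cell` = 1, `8cell` = 0.3,
                                          morula = 0.18),
                       activity_noise_sd = 0.15,
                       adar_coupling = 30,
                       adar_noise_sd = 0.15,
                       n_stage_genes = 4L,
                       n_pair_genes = 2L,
                       sites_per_stage_gene = 3L,
                       stage_gene_freq = 0.8,
                       coupled_gene = TRUE,
                       end_frac = 15 / 90,
                       read_len = 90L,
                       n_simple_repeats = 20L,
                       n_homopolymers = 30L,
                       homopolymer_len = 8L,
                       subthreshold_edit_frac = 0) {
  cfg <- as.list(environment())
  assert_that(all(stages %in% STAGES), "unknown stage label")
  assert_that(all(stages %in% names(stage_activity)),
              "stage_activity must cover every simulated stage")
  assert_in_range(p_err, 0, 1, "p_err")
  assert_in_range(edit_freq_range, 0, 1, "edit_freq_range")
  assert_that(all(stage_activity > 0), "activity multipliers must be > 0")
  assert_that(genome_length >= n_genes * 17000,
              "genome too short for %d gene loci", n_genes)
  class(cfg) <- "editomics_sim_config"
  cfg
}

## gene-locus geometry, offsets relative to the locus start (0-based)
## plus strand reads left to right: 5'UTR, CDS1, intron, CDS2, intron,
## CDS3, 3'UTR; minus strand is the mirror image.
gene_geometry <- function(strand) {
  if (strand == "+") {
    list(utr5 = c(0L, 199L), cds = list(c(200L, 699L), c(1700L, 2199L),
                                        c(3200L, 3399L)),
         utr3 = c(3400L, 5899L),
         exons = list(c(0L, 699L), c(1700L, 2199L), c(3200L, 5899L)))
  } else {
    list(utr5 = c(5700L, 5899L), cds = list(c(5200L, 5699L),
                                            c(3700L, 4199L),
                                            c(2500L, 2699L)),
         utr3 = c(0L, 2499L),
         exons = list(c(0L, 2699L), c(3700L, 4199L), c(5200L, 5899L)))
  }
}

GENE_SPAN <- 5900L

#' Simulate the toy genome and its annotation bundle
#'
#' Builds a random-base genome with planted gene loci (multi-exon coding
#' genes on both strands plus ncRNA genes), Alu intervals (one inside each
#' coding gene's 3'UTR, the rest intergenic), simple repeats, homopolymer
#' runs, planted edit / SNP / artifact sites with their sequence context,
#' a known-editing-site catalogue covering a configurable fraction of the
#' non-Alu edits, and miRNA-target intervals within 3'UTRs. Deterministic
#' given the config (seeded internally).
#'
#' @param config a [sim_config()].
#' @return a bundle list: `reference` (`DNAStringSet`), `alu`,
#'   `simple_repeats`, `mirna_targets` (`GRanges`), `genes` (gene-model
#'   table), `splice_sites`, `catalogue`, `snps` (the SNP list handed to
#'   the pipeline), `truth_sites`, `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  G <- as.integer(config$genome_length)
  chrom <- "chr1"
  genome <- sample(BASES, G, replace = TRUE)
  stride <- G %/% config$n_genes
  gene_start <- (seq_len(config$n_genes) - 1L) * stride + 1000L
  gene_strand <- rep(c("+", "-"), length.out = config$n_genes)
  is_nc <- seq_len(config$n_genes) %% 5L == 0L
  gene_id <- sprintf("G%02d", seq_len(config$n_genes))

  rows <- list()
  add_row <- function(feature, s, e, gid, tid, strand, type)
    data.table(chrom = chrom, start = s, end = e, strand = strand,
               feature = feature, gene_id = gid, transcript_id = tid,
               transcript_type = type)
  for (i in seq_len(config$n_genes)) {
    s <- gene_start[i]; gid <- gene_id[i]; tid <- paste0(gid, ".T1")
    if (is_nc[i]) {
      for (ex in list(c(0L, 899L), c(1900L, 3399L)))
        rows[[length(rows) + 1L]] <- add_row("exon", s + ex[1], s + ex[2],
                                             gid, tid, "+", "ncRNA")
    } else {
      geo <- gene_geometry(gene_strand[i])
      for (ex in geo$exons)
        rows[[length(rows) + 1L]] <- add_row("exon", s + ex[1], s + ex[2],
                                             gid, tid, gene_strand[i], "coding")
      for (cd in geo$cds)
        rows[[length(rows) + 1L]] <- add_row("CDS", s + cd[1], s + cd[2],
                                             gid, tid, gene_strand[i], "coding")
      rows[[length(rows) + 1L]] <- add_row("five_prime_utr", s + geo$utr5[1],
                                           s + geo$utr5[2], gid, tid,
                                           gene_strand[i], "coding")
      rows[[length(rows) + 1L]] <- add_row("three_prime_utr", s + geo$utr3[1],
                                           s + geo$utr3[2], gid, tid,
                                           gene_strand[i], "coding")
    }
  }
  genes <- rbindlist(rows)
  coding_idx <- which(!is_nc)

  ## splice sites: internal exon boundaries
  ex <- genes[feature == "exon"]
  setorder(ex, transcript_id, start)
  sp <- ex[, if (.N >= 2) .(pos = c(end[-.N], start[-1])) else NULL,
           by = transcript_id]
  splice_sites <- data.table(chrom = chrom, pos = sort(unique(sp$pos)))

  ## Alu intervals: one inside each coding gene's 3'UTR, rest intergenic
  alu_list <- list()
  for (i in coding_idx) {
    s <- gene_start[i]
    geo <- gene_geometry(gene_strand[i])
    a0 <- s + geo$utr3[1] + 600L
    alu_list[[length(alu_list) + 1L]] <-
      c(a0, a0 + config$alu_len - 1L)
  }
  n_intergenic_alu <- max(config$n_alu - length(alu_list), 0L)
  for (j in seq_len(n_intergenic_alu)) {
    i <- ((j - 1L) %% config$n_genes) + 1L
    a0 <- gene_start[i] + GENE_SPAN + 800L + 400L * ((j - 1L) %/% config$n_genes)
    alu_list[[length(alu_list) + 1L]] <- c(a0, a0 + config$alu_len - 1L)
  }
  alu_dt <- as.data.table(do.call(rbind, alu_list))
  setnames(alu_dt, c("start", "end"))
  alu <- GenomicRanges::GRanges(chrom, IRanges::IRanges(alu_dt$start, alu_dt$end))

  ## simple repeats: (AC)n tracts in intergenic slots
  rep_start <- integer(0)
  for (j in seq_len(config$n_simple_repeats)) {
    i <- ((j - 1L) %% config$n_genes) + 1L
    r0 <- gene_start[i] + GENE_SPAN + 3000L + 200L * ((j - 1L) %/% config$n_genes)
    rep_start <- c(rep_start, r0)
    genome[r0:(r0 + 39L)] <- rep(c("A", "C"), 20)
  }
  simple_repeats <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(rep_start, rep_start + 39L))

  ## homopolymer runs in intergenic slots
  hp_start <- integer(0)
  for (j in seq_len(config$n_homopolymers)) {
    i <- ((j - 1L) %% config$n_genes) + 1L
    h0 <- gene_start[i] + GENE_SPAN + 4500L + 100L * ((j - 1L) %/% config$n_genes)
    hp_start <- c(hp_start, h0)
    genome[h0:(h0 + config$homopolymer_len - 1L)] <- sample(BASES, 1)
  }

  occupied <- rep(FALSE, G)
  occupied[unlist(lapply(rep_start, function(r) r:(r + 39L)))] <- TRUE
  occupied[unlist(lapply(hp_start, function(h)
    h:(h + config$homopolymer_len - 1L)))] <- TRUE

  claim <- function(pos, margin = 2L) {
    lo <- pmax(pos - margin, 1L); hi <- pmin(pos + margin, G)
    for (i in seq_along(pos)) occupied[lo[i]:hi[i]] <<- TRUE
  }
  free_at <- function(pos) !occupied[pos]

  ## which strand "hosts" a position: minus iff inside a minus-strand gene
  minus_genes <- coding_idx[gene_strand[coding_idx] == "-"]
  on_minus_gene <- function(pos) {
    i <- findInterval(pos, gene_start)
    i >= 1 & i %in% minus_genes & pos <= gene_start[pmax(i, 1)] + GENE_SPAN
  }

  ## plant one edit site: sets the edited base and its sequence context
  ## (transcript-sense +1 G enrichment, -1 G depletion)
  plant_edit_base <- function(pos, minus) {
    if (!minus) {
      genome[pos] <<- "A"
      genome[pos + 1L] <<- if (runif(1) < config$context_g_plus1_prob) "G"
        else sample(c("A", "C", "T"), 1)
      genome[pos - 1L] <<- if (runif(1) < config$context_g_minus1_prob) "G"
        else sample(c("A", "C", "T"), 1)
      c(ref = "A", alt = "G")
    } else {
      genome[pos] <<- "T"
      genome[pos - 1L] <<- if (runif(1) < config$context_g_plus1_prob) "C"
        else sample(c("T", "G", "A"), 1)
      genome[pos + 1L] <<- if (runif(1) < config$context_g_minus1_prob) "C"
        else sample(c("T", "G", "A"), 1)
      c(ref = "T", alt = "C")
    }
  }

  truth <- list()
  add_site <- function(kind, pos, ref, alt, f_base, gene = NA_character_,
                       region = "non-Alu", in_cat = FALSE,
                       active = "all", embryo = NA_character_,
                       coupled = FALSE) {
    truth[[length(truth) + 1L]] <<- data.table(
      kind = kind, chrom = chrom, pos = pos, ref = ref, alt = alt,
      f_base = f_base, gene_id = gene, region = region,
      in_catalogue = in_cat, active_stages = active, embryo = embryo,
      coupled = coupled)
  }

  draw_freq <- function(n) {
    f <- runif(n, config$edit_freq_range[1], config$edit_freq_range[2])
    sub <- runif(n) < config$subthreshold_edit_frac
    f[sub] <- runif(sum(sub), 0.02, 0.08)  # misspecification mode
    f
  }

  ## --- stage-restricted and coupled genes (miRNA-target machinery) ----
  utr3_alu_of <- function(i) {
    s <- gene_start[i]; geo <- gene_geometry(gene_strand[i])
    a0 <- s + geo$utr3[1] + 600L
    c(a0, a0 + config$alu_len - 1L)
  }
  special_pool <- coding_idx
  stage_genes <- head(special_pool, config$n_stage_genes)
  special_pool <- setdiff(special_pool, stage_genes)
  pair_genes <- head(special_pool, config$n_pair_genes)
  special_pool <- setdiff(special_pool, pair_genes)
  coupled_gid <- NA_character_
  if (isTRUE(config$coupled_gene)) {
    cg <- special_pool[gene_strand[special_pool] == "+"][1]
    special_pool <- setdiff(special_pool, cg)
    coupled_gid <- gene_id[cg]
    aluc <- utr3_alu_of(cg)
    p <- aluc[1] + 20L
    info <- plant_edit_base(p, FALSE)
    claim(p, margin = 6L)  # keep bulk edits out of its seed-match interval
    add_site("edit", p, info["ref"], info["alt"], NA_real_,
             gene = coupled_gid, region = "Alu", coupled = TRUE)
  }
  plant_stage_gene <- function(i, stages_label) {
    alui <- utr3_alu_of(i)
    offs <- seq(10L, by = 12L, length.out = config$sites_per_stage_gene)
    for (o in offs) {
      p <- alui[1] + o
      minus <- gene_strand[i] == "-"
      info <- plant_edit_base(p, minus)
      claim(p, margin = 6L)  # keep bulk edits out of its seed-match interval
      add_site("edit", p, info["ref"], info["alt"], config$stage_gene_freq,
               gene = gene_id[i], region = "Alu", active = stages_label)
    }
  }
  st_assign <- rep(config$stages, length.out = length(stage_genes))
  for (j in seq_along(stage_genes))
    plant_stage_gene(stage_genes[j], st_assign[j])
  if (length(pair_genes) > 0) {
    for (j in seq_along(pair_genes)) {
      a <- ((j - 1L) %% (length(config$stages) - 1L)) + 1L
      plant_stage_gene(pair_genes[j],
                       paste(config$stages[a], config$stages[a + 1L],
                             sep = ","))
    }
  }
  n_planted_special <- length(truth)

  ## --- bulk Alu edits ------------------------------------------------
  n_alu_edits <- round(config$n_true_edits * config$alu_edit_frac) -
    n_planted_special
  tries <- 0L
  while (n_alu_edits > 0 && tries < 50000L) {
    tries <- tries + 1L
    ai <- sample(nrow(alu_dt), 1)
    p <- sample(seq(alu_dt$start[ai] + 3L, alu_dt$end[ai] - 3L), 1)
    if (!free_at(p) || !free_at(p - 1L) || !free_at(p + 1L)) next
    minus <- on_minus_gene(p)
    info <- plant_edit_base(p, minus)
    claim(p)
    add_site("edit", p, info["ref"], info["alt"], draw_freq(1),
             gene = NA_character_, region = "Alu")
    n_alu_edits <- n_alu_edits - 1L
  }

  ## --- non-Alu edits --------------------------------------------------
  n_nonalu <- config$n_true_edits - sum(vapply(truth, function(x)
    x$kind == "edit", NA))
  nonalu_slot <- function(i, kind) {
    s <- gene_start[i]; geo <- gene_geometry(gene_strand[i])
    switch(kind,
      utr3 = if (gene_strand[i] == "+") c(s + 4500L, s + 5800L)
             else c(s + 1300L, s + 2400L),
      cds = c(s + geo$cds[[2]][1] + 10L, s + geo$cds[[2]][2] - 10L),
      intron = if (gene_strand[i] == "+") c(s + 750L, s + 1650L)
               else c(s + 2750L, s + 3650L),
      intergenic = c(s + GENE_SPAN + 6000L, s + GENE_SPAN + 6500L))
  }
  kinds <- rep(c("utr3", "cds", "intron", "intergenic"),
               times = pmax(round(n_nonalu * c(0.3, 0.2, 0.2, 0.3)), 0))
  kinds <- head(kinds, n_nonalu)
  while (length(kinds) < n_nonalu) kinds <- c(kinds, "intergenic")
  for (kd in kinds) {
    placed <- FALSE; tries <- 0L
    while (!placed && tries < 2000L) {
      tries <- tries + 1L
      i <- sample(coding_idx, 1)
      slot <- nonalu_slot(i, kd)
      p <- sample(seq(slot[1], slot[2]), 1)
      if (!free_at(p) || !free_at(p - 1L) || !free_at(p + 1L)) next
      minus <- kd != "intergenic" && gene_strand[i] == "-"
      info <- plant_edit_base(p, minus)
      claim(p)
      add_site("edit", p, info["ref"], info["alt"], draw_freq(1),
               gene = if (kd == "intergenic") NA_character_ else gene_id[i],
               region = "non-Alu")
      placed <- TRUE
    }
  }

  ## --- SNPs (embryo-private, A-to-G, half heterozygous half fixed) ----
  embryos <- as.vector(vapply(config$stages, function(s)
    sprintf("%s_e%d", s, seq_len(config$embryos_per_stage)), character(config$embryos_per_stage)))
  n_placed <- 0L; tries <- 0L
  while (n_placed < config$n_snps && tries < 50000L) {
    tries <- tries + 1L
    i <- sample(config$n_genes, 1)
    p <- gene_start[i] + GENE_SPAN + 7000L + sample(2000L, 1)
    if (p > G - 2L || !free_at(p) || !free_at(p - 1L) || !free_at(p + 1L)) next
    genome[p] <- "A"
    if (genome[p + 1L] == "A") genome[p + 1L] <- "C"  # avoid A runs
    claim(p)
    n_placed <- n_placed + 1L
    add_site("snp", p, "A", "G", if (n_placed %% 2L == 0L) 1.0 else 0.5,
             embryo = embryos[((n_placed - 1L) %% length(embryos)) + 1L])
  }

  ## --- artifact sites (A-to-G inside Alu, the adversarial case) -------
  plant_artifacts <- function(kind, n) {
    placed <- 0L; tries <- 0L
    while (placed < n && tries < 50000L) {
      tries <- tries + 1L
      ai <- sample(nrow(alu_dt), 1)
      p <- sample(seq(alu_dt$start[ai] + 3L, alu_dt$end[ai] - 3L), 1)
      if (!free_at(p) || !free_at(p - 1L) || !free_at(p + 1L)) next
      minus <- on_minus_gene(p)
      info <- plant_edit_base(p, minus)
      claim(p)
      placed <- placed + 1L
      add_site(kind, p, info["ref"], info["alt"],
               runif(1, config$artifact_freq_range[1],
                     config$artifact_freq_range[2]), region = "Alu")
    }
  }
  plant_artifacts("strand_artifact", config$n_strand_artifacts)
  plant_artifacts("end_artifact", config$n_end_artifacts)

  truth_sites <- rbindlist(truth)
  if (nrow(truth_sites) == 0)
    truth_sites <- data.table(kind = character(), chrom = character(),
                              pos = integer(), ref = character(),
                              alt = character(), f_base = numeric(),
                              gene_id = character(), region = character(),
                              in_catalogue = logical(),
                              active_stages = character(),
                              embryo = character(), coupled = logical())
  truth_sites[, site_id := sprintf("S%05d", .I)]

  ## coupled-site base frequency placeholder resolved per cell
  ## --- catalogue: a fraction of non-Alu edits + decoys ----------------
  nonalu_edits <- truth_sites[kind == "edit" & region == "non-Alu"]
  in_cat <- rep(FALSE, nrow(nonalu_edits))
  in_cat[sample(nrow(nonalu_edits),
                round(config$catalogue_frac * nrow(nonalu_edits)))] <- TRUE
  truth_sites[kind == "edit" & region == "non-Alu", in_catalogue := in_cat]
  truth_sites[kind == "edit" & region == "Alu", in_catalogue := NA]
  cat_rows <- truth_sites[kind == "edit" & in_catalogue %in% TRUE]
  decoys <- data.table(chrom = chrom,
                       pos = gene_start[seq_len(min(25L, config$n_genes))] +
                         GENE_SPAN + 9500L,
                       strand = "+")
  catalogue <- rbind(
    data.table(chrom = cat_rows$chrom, pos = cat_rows$pos,
               strand = ifelse(cat_rows$ref == "T", "-", "+")),
    decoys)
  setorder(catalogue, chrom, pos)

  ## --- SNP list handed to the pipeline (known fraction) ---------------
  snp_truth <- truth_sites[kind == "snp"]
  known <- sample(nrow(snp_truth), round(config$snp_known_frac * nrow(snp_truth)))
  snps <- data.table(chrom = snp_truth$chrom[known], pos = snp_truth$pos[known],
                     ref = snp_truth$ref[known], alt = snp_truth$alt[known])
  setorder(snps, chrom, pos)

  ## --- miRNA-target intervals within 3'UTRs ---------------------------
  utr3 <- genes[feature == "three_prime_utr"]
  gr_utr3 <- GenomicRanges::GRanges(utr3$chrom,
                                    IRanges::IRanges(utr3$start, utr3$end))
  ed <- truth_sites[kind == "edit"]
  in_utr3 <- IRanges::overlapsAny(sites_granges(ed$chrom, ed$pos), gr_utr3)
  utr3_ed <- ed[in_utr3]
  utr3_ed[, locus := findInterval(pos, gene_start)]
  utr3_ed[, special := active_stages != "all" | coupled]
  ## stage-restricted / coupled loci get targets only on their dedicated
  ## sites, so the gene's miRNA-target editing carries the planted pattern
  tgt <- utr3_ed[, if (any(special)) head(.SD[special == TRUE], 4L)
                 else head(.SD, 4L), by = locus]
  mirna_targets <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tgt$chrom, IRanges::IRanges(tgt$pos - 3L, tgt$pos + 3L)))
  hit <- IRanges::overlapsAny(sites_granges(truth_sites$chrom, truth_sites$pos),
                              mirna_targets) & truth_sites$kind == "edit"
  truth_sites[, mirna_target := hit & truth_sites$pos %in% ed$pos[in_utr3]]

  reference <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(reference) <- chrom
  list(reference = reference, alu = alu, simple_repeats = simple_repeats,
       mirna_targets = mirna_targets, genes = genes,
       splice_sites = splice_sites, catalogue = catalogue, snps = snps,
       truth_sites = truth_sites, config = config,
       gene_start = gene_start, gene_strand = gene_strand,
       gene_id = gene_id, coding_idx = coding_idx,
       coupled_gene_id = coupled_gid)
}

#' Simulate the per-cell pileups, metadata, expression and truth
#'
#' For every cell the generator draws a depth factor, a stage-dependent
#' editing activity with lognormal noise, and a coupled ADAR expression
#' value; every planted site receives Poisson coverage and binomial
#' variant support at its per-cell frequency (edit frequency x activity,
#' capped into the configured range; SNPs near-fixed in the carrier
#' embryo only; artifacts one-strand or read-end confined), and
#' sequencing errors are scattered over the genome at the configured
#' per-base rate.
#'
#' @param config a [sim_config()].
#' @param bundle output of [simulate_genome()].
#' @return list with `pileup`, `meta`, `expression` (counts + RPKM),
#'   `truth_cells`, `site_freqs` (per-cell true frequencies at planted
#'   sites).
#' @export
simulate_cells <- function(config, bundle) {
  set.seed(config$seed + 1L)
  G <- as.integer(config$genome_length)
  ts <- bundle$truth_sites
  stages <- config$stages
  cells <- CJ(stage = factor(stages, levels = stages),
              emb = seq_len(config$embryos_per_stage),
              cell = seq_len(config$cells_per_embryo), sorted = FALSE)
  cells[, stage := as.character(stage)]
  cells[, embryo_id := sprintf("%s_e%d", stage, emb)]
  cells[, cell_id := sprintf("%s_e%d_c%d", stage, emb, cell)]
  n_cells <- nrow(cells)
  cells[, depth_factor := runif(n_cells, config$depth_range[1],
                                config$depth_range[2])]
  cells[, activity := config$stage_activity[stage] *
          exp(rnorm(n_cells, 0, config$activity_noise_sd))]
  cells[, adar_rpkm := config$adar_coupling * activity *
          exp(rnorm(n_cells, 0, config$adar_noise_sd))]
  cells[, mapped_bases := round(G * config$mean_depth * depth_factor)]
  stage_frac <- (match(cells$stage, stages) - 1) / max(length(stages) - 1, 1)
  cells[, coupled_freq := clamp(0.9 - 0.7 * stage_frac +
                                  rnorm(n_cells, 0, 0.05), 0.1, 0.9)]

  pileups <- vector("list", n_cells)
  freqs <- vector("list", n_cells)
  fmax <- config$edit_freq_range[2]
  for (ci in seq_len(n_cells)) {
    cell <- cells[ci]
    dmean <- config$mean_depth * cell$depth_factor
    ## per-site frequencies for this cell
    f <- numeric(nrow(ts))
    is_edit <- ts$kind == "edit"
    active <- ts$active_stages == "all" |
      vapply(strsplit(ts$active_stages, ","), function(s)
        cell$stage %in% s, NA)
    f[is_edit] <- clamp(ts$f_base[is_edit] * cell$activity, 0, fmax)
    f[is_edit & !active] <- 0
    f[is_edit & ts$coupled] <- cell$coupled_freq
    is_snp <- ts$kind == "snp"
    f[is_snp] <- ifelse(ts$embryo[is_snp] == cell$embryo_id,
                        ts$f_base[is_snp], 0)
    is_art <- ts$kind %in% c("strand_artifact", "end_artifact")
    f[is_art] <- ts$f_base[is_art]
    n <- rpois(nrow(ts), dmean)
    k <- rbinom(nrow(ts), n, f)
    alt_fwd <- ifelse(ts$kind == "strand_artifact", k, rbinom(nrow(ts), k, 0.5))
    ref_n <- n - k
    ref_fwd <- rbinom(nrow(ts), ref_n, 0.5)
    alt_end <- ifelse(ts$kind == "end_artifact", k,
                      rbinom(nrow(ts), k, config$end_frac))
    ref_end <- rbinom(nrow(ts), ref_n, config$end_frac)
    site_dt <- data.table(chrom = ts$chrom, pos = ts$pos, ref = ts$ref,
                          .__alt = ts$alt, n = n, k = k,
                          alt_fwd = alt_fwd, ref_fwd = ref_fwd,
                          alt_end2 = alt_end, ref_end2 = ref_end)
    ## sequencing-error columns scattered over the genome
    n_err <- rbinom(1, cell$mapped_bases, config$p_err)
    epos <- sample.int(G, n_err, replace = TRUE)
    epos <- epos[!epos %in% ts$pos]
    if (length(epos)) {
      edt <- data.table(pos = epos)[, .(ke = .N), by = pos]
      edt[, ref := reference_base(bundle$reference, rep("chr1", .N), pos)]
      edt <- edt[ref %in% BASES]
      edt[, n := pmax(rpois(.N, dmean), ke)]
      ## error base: uniform over the three non-reference bases
      nonref <- matrix(unlist(lapply(edt$ref, function(r) setdiff(BASES, r))),
                       ncol = 3, byrow = TRUE)
      edt[, alt := nonref[cbind(seq_len(.N), sample(3L, .N, replace = TRUE))]]
      err_dt <- data.table(chrom = "chr1", pos = edt$pos, ref = edt$ref,
                           .__alt = edt$alt, n = edt$n, k = edt$ke,
                           alt_fwd = rbinom(nrow(edt), edt$ke, 0.5),
                           ref_fwd = rbinom(nrow(edt), edt$n - edt$ke, 0.5),
                           alt_end2 = rbinom(nrow(edt), edt$ke, config$end_frac),
                           ref_end2 = rbinom(nrow(edt), edt$n - edt$ke,
                                             config$end_frac))
      site_dt <- rbind(site_dt, err_dt)
    }
    site_dt <- site_dt[n > 0]
    ## assemble the 8 strand-split base counts
    for (cc in c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                 "A_rev", "C_rev", "G_rev", "T_rev"))
      site_dt[, (cc) := 0L]
    ref_n2 <- site_dt$n - site_dt$k
    for (b in BASES) {
      sel <- site_dt$ref == b
      if (any(sel)) {
        site_dt[sel, (paste0(b, "_fwd")) :=
                  get(paste0(b, "_fwd")) + site_dt$ref_fwd[sel]]
        site_dt[sel, (paste0(b, "_rev")) :=
                  get(paste0(b, "_rev")) + ref_n2[sel] - site_dt$ref_fwd[sel]]
      }
      sel <- site_dt$.__alt == b
      if (any(sel)) {
        site_dt[sel, (paste0(b, "_fwd")) :=
                  get(paste0(b, "_fwd")) + site_dt$alt_fwd[sel]]
        site_dt[sel, (paste0(b, "_rev")) :=
                  get(paste0(b, "_rev")) + site_dt$k[sel] - site_dt$alt_fwd[sel]]
      }
    }
    pu <- site_dt[, .(cell_id = cell$cell_id, chrom, pos, ref, depth = n,
                      A_fwd, C_fwd, G_fwd, T_fwd, A_rev, C_rev, G_rev, T_rev,
                      alt_end = alt_end2, alt_mid = k - alt_end2,
                      ref_end = ref_end2, ref_mid = n - k - ref_end2)]
    pileups[[ci]] <- pu
    freqs[[ci]] <- data.table(cell_id = cell$cell_id, chrom = ts$chrom,
                              pos = ts$pos, f = f)
  }
  pileup <- rbindlist(pileups)
  setkey(pileup, cell_id, chrom, pos)

  ## --- expression table ------------------------------------------------
  genes <- bundle$genes
  glen <- genes[feature == "exon", .(len = sum(end - start + 1L)),
                by = gene_id]
  lambda <- setNames(exp(runif(nrow(glen), log(20), log(400))), glen$gene_id)
  if (!is.na(bundle$coupled_gene_id)) {
    ## coupled gene: expression rises across stages while editing falls
    lam_cg <- 40 * (1 + 9 * (match(cells$stage, stages) - 1) /
                      max(length(stages) - 1, 1))
  }
  total_reads <- round(cells$mapped_bases / config$read_len)
  counts <- matrix(0L, nrow = nrow(glen), ncol = n_cells,
                   dimnames = list(glen$gene_id, cells$cell_id))
  for (ci in seq_len(n_cells)) {
    lam <- lambda * cells$depth_factor[ci]
    if (!is.na(bundle$coupled_gene_id))
      lam[bundle$coupled_gene_id] <- lam_cg[ci] * cells$depth_factor[ci]
    counts[, ci] <- rpois(nrow(glen), lam)
  }
  rpkm_mat <- t(t(1e9 * counts / glen$len) / total_reads)
  ## ADAR tracks the per-cell activity; ADARB1 stays flat and low
  adar_len <- 2000
  adar_counts <- round(cells$adar_rpkm * adar_len * total_reads / 1e9)
  adarb1_counts <- round(1.0 * adar_len * total_reads / 1e9)
  counts <- rbind(counts, ADAR = adar_counts, ADARB1 = adarb1_counts)
  rpkm_mat <- rbind(rpkm_mat,
                    ADAR = 1e9 * adar_counts / (adar_len * total_reads),
                    ADARB1 = 1e9 * adarb1_counts / (adar_len * total_reads))
  gene_length <- c(setNames(glen$len, glen$gene_id),
                   ADAR = adar_len, ADARB1 = adar_len)

  meta <- cells[, .(cell_id, embryo_id, stage, layout = "single_end",
                    mapped_bases, aligned_bases = mapped_bases)]
  list(pileup = pileup, meta = meta,
       expression = list(counts = counts, rpkm = rpkm_mat,
                         gene_length = gene_length,
                         total_reads = setNames(total_reads, cells$cell_id)),
       truth_cells = cells[, .(cell_id, embryo_id, stage, depth_factor,
                               activity, adar_rpkm, mapped_bases,
                               coupled_freq)],
       site_freqs = rbindlist(freqs))
}

#' Simulate a full dataset (genome bundle + cells)
#'
#' @param config a [sim_config()].
#' @return list combining the genome bundle and the per-cell data.
#' @export
simulate_dataset <- function(config = sim_config()) {
  bundle <- simulate_genome(config)
  cells <- simulate_cells(config, bundle)
  c(bundle[c("reference", "alu", "simple_repeats", "mirna_targets", "genes",
             "splice_sites", "catalogue", "snps", "truth_sites",
             "coupled_gene_id")],
    cells, list(config = config))
}

#' Score a detected editome against the planted truth
#'
#' @param editome annotated editome (retained sites per cell).
#' @param truth_sites planted-site table from the bundle.
#' @param pileup pooled pileup (to restrict recall to recoverable sites:
#'   depth >= `min_depth` in at least one cell).
#' @param min_depth recoverability threshold.
#' @return list: `precision`, `recall`, `leakage` (per artifact/SNP kind),
#'   `n_detected`, `n_recoverable`.
#' @export
score_against_truth <- function(editome, truth_sites, pileup,
                                min_depth = 4L) {
  det <- unique(as.data.table(editome)[, .(chrom, pos)])
  edits <- truth_sites[kind == "edit"]
  cov <- as.data.table(pileup)[edits, on = c("chrom", "pos")]
  cov <- cov[!is.na(depth), .(maxd = max(depth)), by = .(chrom, pos)]
  recoverable <- cov[maxd >= min_depth]
  det_key <- site_key(det$chrom, det$pos)
  edit_key <- site_key(edits$chrom, edits$pos)
  rec_key <- site_key(recoverable$chrom, recoverable$pos)
  precision <- if (nrow(det) == 0) NA_real_ else mean(det_key %in% edit_key)
  recall <- if (length(rec_key) == 0) NA_real_ else
    mean(rec_key %in% det_key)
  leak <- vapply(c("snp", "strand_artifact", "end_artifact"), function(kd) {
    pl <- truth_sites[kind == kd]
    if (nrow(pl) == 0) return(NA_real_)
    mean(site_key(pl$chrom, pl$pos) %in% det_key)
  }, 0)
  list(precision = precision, recall = recall, leakage = as.list(leak),
       n_detected = nrow(det), n_recoverable = length(rec_key))
}

#' Write a small single-contig SAM file with planted variants
#'
#' Emits uniformly placed ungapped single-end reads over one reference
#' contig, flipping the base at each planted site with its configured
#' frequency and adding per-base errors, with constant Q40 qualities.
#' Minus-strand records store the aligned (reference-oriented) sequence
#' with flag 16. Used to exercise the alignment-level code paths.
#'
#' @param reference named `DNAStringSet` with one contig.
#' @param sites `data.table` with `pos`, `alt`, `f` (may be empty).
#' @param n_reads,read_len read geometry.
#' @param error_rate per-base error rate.
#' @param path output SAM path.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
simulate_sam <- function(reference, sites = data.table(pos = integer(),
                                                       alt = character(),
                                                       f = numeric()),
                         n_reads = 200L, read_len = 90L, error_rate = 0,
                         path = tempfile(fileext = ".sam"), seed = 1L) {
  set.seed(seed)
  chrom <- names(reference)[1]
  L <- Biostrings::width(reference)[1]
  refchar <- strsplit(as.character(reference[[1]]), "")[[1]]
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  strands <- sample(c(0L, 16L), n_reads, replace = TRUE)
  lines <- c(sprintf("@HD\tVN:1.6\tSO:coordinate"),
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, L))
  ord <- order(starts)
  recs <- vapply(ord, function(i) {
    s <- starts[i]
    bases <- refchar[s:(s + read_len - 1L)]
    for (j in seq_len(nrow(sites))) {
      off <- sites$pos[j] - s + 1L
      if (off >= 1 && off <= read_len && runif(1) < sites$f[j])
        bases[off] <- sites$alt[j]
    }
    if (error_rate > 0) {
      hit <- runif(read_len) < error_rate
      if (any(hit))
        bases[hit] <- vapply(bases[hit], function(b)
          sample(setdiff(BASES, b), 1), "")
    }
    sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s", i, strands[i],
            chrom, s, read_len, paste(bases, collapse = ""),
            strrep("I", read_len))
  }, "")
  writeLines(c(lines, recs), path)
  invisible(path)
}
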