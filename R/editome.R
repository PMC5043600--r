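## Cohort-level editome analytics: editing level, frequency matrix,
## clustering, correlations, stage specificity.

#' Per-cell editing level
#'
#' Edited bases (variant-supporting reads summed over retained sites) per
#' million uniquely mapped bases — a depth-normalised global editing
#' activity statistic.
#'
#' @param edited_bases per-cell sum of variant-supporting reads.
#' @param mapped_bases per-cell uniquely mapped bases.
#' @return numeric vector.
#' @export
editing_level <- function(edited_bases, mapped_bases) {
  assert_that(all(mapped_bases > 0), "zero mapped bases")
  1e6 * edited_bases / mapped_bases
}

#' Summarise per-cell editomes
#'
#' @param editome annotated editome table (`cell_id`, `k`, one row per
#'   retained site per cell).
#' @param meta cell metadata with `cell_id`, `embryo_id`, `stage`,
#'   `mapped_bases`.
#' @param candidates optional full candidate table (all mismatch-bearing
#'   columns, detected or not). When given, a cell's edited bases are its
#'   variant-supporting reads over the cohort union of retained sites —
#'   the editome is a cohort-level site set, so a cell contributes its
#'   edited bases there even where its own coverage was too thin to
#'   re-detect the site independently. Without it, only the cell's own
#'   detections are summed.
#' @param per_site if `TRUE`, the editing level counts sites instead of
#'   edited bases.
#' @return `data.table`: one row per cell with `n_sites` (sites detected
#'   in that cell), `edited_base_count`, `editing_level` (cells without
#'   retained sites get zeros).
#' @export
cell_editomes <- function(editome, meta, candidates = NULL,
                          per_site = FALSE) {
  ed <- as.data.table(editome)
  per_cell <- ed[, .(n_sites = .N, edited_base_count = sum(k)),
                 by = cell_id]
  if (!is.null(candidates) && nrow(ed) > 0) {
    sites <- unique(ed[, .(chrom, pos, alt)])
    eb <- as.data.table(candidates)[sites, on = c("chrom", "pos", "alt"),
                                    nomatch = 0L]
    eb <- eb[, .(edited_base_count = sum(k)), by = cell_id]
    per_cell <- merge(per_cell[, .(cell_id, n_sites)], eb,
                      by = "cell_id", all = TRUE)
    per_cell[is.na(n_sites), n_sites := 0L]
  }
  out <- merge(as.data.table(meta), per_cell, by = "cell_id", all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[is.na(edited_base_count), edited_base_count := 0L]
  numer <- if (per_site) out$n_sites else out$edited_base_count
  out[, editing_level := editing_level(numer, mapped_bases)]
  out[]
}

#' Editing-frequency matrix
#'
#' Rows are cells, columns the cohort union of retained sites (ordered by
#' chromosome then position). Entries are the editing frequency where the
#' site was detected in the cell, 0 where the cell covers the site with
#' depth >= `min_depth` but shows no edit, and -1 where depth < `min_depth`
#' (not qualified for determination).
#'
#' @param editome annotated editome (`cell_id`, `chrom`, `pos`, `freq`).
#' @param pileup pooled pileup columns supplying per-cell depths.
#' @param cell_ids cells to include, in row order.
#' @param min_depth depth below which an entry is coded -1.
#' @return numeric matrix with rownames = cells, colnames = "chrom:pos".
#' @export
build_editing_matrix <- function(editome, pileup, cell_ids,
                                 min_depth = 4L) {
  ed <- as.data.table(editome)
  sites <- unique(ed[, .(chrom, pos)])
  assert_that(nrow(sites) > 0, "no retained sites")
  setorder(sites, chrom, pos)
  sites[, col := .I]
  mat <- matrix(-1, nrow = length(cell_ids), ncol = nrow(sites),
                dimnames = list(cell_ids, site_key(sites$chrom, sites$pos)))
  pu <- as.data.table(pileup)[sites, on = c("chrom", "pos"), nomatch = 0L]
  pu <- pu[cell_id %in% cell_ids & depth >= min_depth]
  mat[cbind(match(pu$cell_id, cell_ids), pu$col)] <- 0
  edx <- ed[sites, on = c("chrom", "pos"), nomatch = 0L]
  edx <- edx[cell_id %in% cell_ids]
  mat[cbind(match(edx$cell_id, cell_ids), edx$col)] <- edx$freq
  mat
}

#' Hierarchical clustering of cells on the editing matrix
#'
#' Euclidean distances between matrix rows, agglomerated with complete
#' linkage (the default of the standard clustering routine); ties are
#' broken deterministically by cell order.
#'
#' @param mat editing matrix from [build_editing_matrix()].
#' @param linkage agglomeration method.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `dist`, and (when `k` is given) `labels`.
#' @export
cluster_cells <- function(mat, linkage = "complete", k = NULL) {
  assert_that(nrow(mat) >= 2, "clustering needs at least two cells")
  d <- stats::dist(mat, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Write a dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
}

#' Correlation with a two-sided test
#'
#' Pearson or Spearman correlation with the two-sided t-approximation P;
#' Spearman uses average ranks for ties.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need >= 3 complete pairs")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count reads assigned to the gene.
#' @param gene_length_bases gene (model) length in bases.
#' @param total_mapped_reads library total.
#' @return numeric vector.
#' @export
rpkm <- function(count, gene_length_bases, total_mapped_reads) {
  assert_that(all(gene_length_bases > 0) && all(total_mapped_reads > 0),
              "gene length and total mapped reads must be positive")
  1e9 * count / (gene_length_bases * total_mapped_reads)
}

#' Expression-frequency association for exonic-edited genes
#'
#' Per exonic-edited site, Spearman correlation between the editing
#' frequency (matrix entries >= 0) and the host gene's expression across
#' cells, BH-adjusted over all tested sites; sites with fewer than
#' `min_cells` usable cells are skipped.
#'
#' @param mat editing matrix (-1 coded).
#' @param site_genes `data.table` mapping matrix columns to genes:
#'   `site` (colname), `gene_id`.
#' @param expression RPKM matrix, genes x cells (colnames = cell ids).
#' @param min_cells minimum usable cells per site.
#' @param bh_alpha flag threshold on the adjusted P.
#' @return `data.table`: `gene_id`, `site`, `n_cells`, `rho`, `p`,
#'   `p_adjusted`, `flagged`.
#' @export
expression_vs_frequency <- function(mat, site_genes, expression,
                                    min_cells = 3L, bh_alpha = 0.1) {
  sg <- as.data.table(site_genes)
  sg <- sg[!is.na(gene_id) & site %in% colnames(mat) &
             gene_id %in% rownames(expression)]
  rows <- lapply(seq_len(nrow(sg)), function(i) {
    site <- sg$site[i]; gid <- sg$gene_id[i]
    f <- mat[, site]
    e <- expression[gid, match(rownames(mat), colnames(expression))]
    use <- f >= 0 & !is.na(e)
    if (sum(use) < min_cells || stats::sd(f[use]) == 0 ||
        stats::sd(e[use]) == 0) return(NULL)
    ct <- correlate(f[use], e[use], method = "spearman")
    data.table(gene_id = gid, site = site, n_cells = sum(use),
               rho = ct$r, p = ct$p)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0) return(out)
  out[, p_adjusted := bh_adjust(p)]
  out[, flagged := p_adjusted < bh_alpha]
  out[]
}

#' Stage-specific editing of miRNA-targeted genes
#'
#' For each gene, compares the number of cells edited in its
#' miRNA-targeted regions inside a stage (or a pair of sequential stages)
#' against all other stages with a two-tailed Fisher's exact test on
#' [[edited_in, unedited_in], [edited_out, unedited_out]]. A gene is
#' flagged for a stage when P < `alpha` and the in-stage edited fraction
#' exceeds the out-stage fraction (enrichment, not mere difference).
#' Stages with fewer than `min_cells_per_stage` cells are excluded.
#'
#' @param edited `data.table` with `cell_id`, `gene_id`, `edited`
#'   (logical): per cell, whether any miRNA-target site of the gene is
#'   edited. Missing (cell, gene) pairs count as unedited.
#' @param meta cell metadata (`cell_id`, `stage`).
#' @param mode `"single_stage"` or `"two_sequential"`.
#' @param alpha Fisher cutoff.
#' @param min_cells_per_stage exclusion threshold.
#' @return `data.table`: `gene_id`, `stage` (or "stageA+stageB"), counts,
#'   `fet_p`, `flagged`.
#' @export
stage_specific_editing <- function(edited, meta,
                                   mode = c("single_stage", "two_sequential"),
                                   alpha = 0.05, min_cells_per_stage = 4L) {
  mode <- match.arg(mode)
  meta <- as.data.table(meta)
  tab <- table(meta$stage)
  keep_stages <- intersect(STAGES, names(tab)[tab >= min_cells_per_stage])
  dropped <- setdiff(unique(meta$stage), keep_stages)
  if (length(dropped))
    warning("stages excluded for insufficient cells: ",
            paste(dropped, collapse = ", "))
  cells <- meta[stage %in% keep_stages]
  ed <- as.data.table(edited)[cell_id %in% cells$cell_id & edited == TRUE]
  groups <- if (mode == "single_stage") {
    lapply(keep_stages, function(s) list(label = s, stages = s))
  } else {
    assert_that(length(keep_stages) >= 2, "need >= 2 stages for pairs")
    lapply(seq_len(length(keep_stages) - 1L), function(i)
      list(label = paste(keep_stages[i], keep_stages[i + 1L], sep = "+"),
           stages = keep_stages[c(i, i + 1L)]))
  }
  res <- lapply(unique(ed$gene_id), function(gid) {
    edited_cells <- ed$cell_id[ed$gene_id == gid]
    rbindlist(lapply(groups, function(g) {
      inc <- cells$cell_id[cells$stage %in% g$stages]
      outc <- setdiff(cells$cell_id, inc)
      a <- sum(inc %in% edited_cells); b <- length(inc) - a
      c_ <- sum(outc %in% edited_cells); d <- length(outc) - c_
      p <- fet_p_vec(a, b, c_, d)
      enrich <- a / length(inc) > c_ / max(length(outc), 1L)
      data.table(gene_id = gid, stage = g$label, edited_in = a,
                 unedited_in = b, edited_out = c_, unedited_out = d,
                 fet_p = p, flagged = p < alpha & enrich)
    }))
  })
  rbindlist(res)
}

#' Per-cell edited indicator for miRNA-targeted genes
#'
#' @param editome annotated editome.
#' @return `data.table` with `cell_id`, `gene_id`, `edited = TRUE` for each
#'   cell-gene pair with at least one edited miRNA-target site.
#' @export
gene_cell_edited <- function(editome) {
  ed <- as.data.table(editome)[mirna_target == TRUE & !is.na(gene_id)]
  unique(ed[, .(cell_id, gene_id, edited = TRUE)])
}

#' Per-stage summaries of editome size and editing level
#'
#' Mean and sample standard deviation of per-cell retained-site counts and
#' editing levels per stage, plus two-sided Wilcoxon rank-sum tests on the
#' editing level between sequential stages (exact when both groups have
#' at most 10 cells, normal approximation with continuity correction
#' otherwise; average ranks on ties).
#'
#' @param cells output of [cell_editomes()].
#' @return list with `summary` (per stage) and `tests` (sequential stage
#'   pairs).
#' @export
stage_summaries <- function(cells) {
  cells <- as.data.table(cells)
  present <- intersect(STAGES, unique(cells$stage))
  smry <- cells[, .(n_cells = .N,
                    mean_sites = mean(n_sites),
                    sd_sites = if (.N > 1) stats::sd(n_sites) else 0,
                    single_cell = .N == 1L,
                    mean_level = mean(editing_level),
                    sd_level = if (.N > 1) stats::sd(editing_level) else 0),
                by = stage]
  smry <- smry[match(present, stage)]
  tests <- rbindlist(lapply(seq_len(max(length(present) - 1L, 0L)),
                            function(i) {
    a <- cells$editing_level[cells$stage == present[i]]
    b <- cells$editing_level[cells$stage == present[i + 1L]]
    if (length(unique(c(a, b))) == 1L) {
      p <- 1  # identical constant samples: no evidence of a shift
    } else {
      exact <- min(length(a), length(b)) <= 10
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = TRUE))
      p <- wt$p.value
    }
    data.table(stage_a = present[i], stage_b = present[i + 1L], p = p)
  }))
  list(summary = smry, tests = tests)
}
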