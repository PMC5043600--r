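test_that("editing level is edited bases per million mapped bases", {
  expect_equal(editing_level(0, 1e7), 0)
  expect_equal(editing_level(50, 1e7), 5)
  expect_equal(editing_level(100, 2e7), editing_level(50, 1e7))
  expect_error(editing_level(10, 0), "mapped")
})

test_that("editing matrix codes frequency, zero-coverage and thin coverage", {
  ed <- data.table::data.table(cell_id = "c1", chrom = "chr1", pos = 100L,
                               alt = "G", freq = 0.3, k = 6L, n = 20L)
  pu <- rbind(mk_pileup_row("c1", "chr1", 100L, "A", "G", 20, 6),
              mk_pileup_row("c2", "chr1", 100L, "A", "G", 15, 0),
              mk_pileup_row("c3", "chr1", 100L, "A", "G", 3, 0))
  m <- build_editing_matrix(ed, pu, c("c1", "c2", "c3", "c4"))
  expect_equal(dim(m), c(4L, 1L))
  expect_equal(unname(m[, 1]), c(0.3, 0, -1, -1))  # c4 has no column at all
  expect_equal(colnames(m), "chr1:100")
})

test_that("cells cluster by Euclidean distance with complete linkage", {
  m <- rbind(a = c(0, 1), b = c(0, 1), c = c(1, 0))
  cl <- cluster_cells(m, k = 2)
  expect_equal(as.matrix(cl$dist)["a", "b"], 0)
  expect_equal(as.matrix(cl$dist)["a", "c"], sqrt(2))
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
  expect_error(cluster_cells(m[1, , drop = FALSE]), "two cells")
  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl$hclust, nwk)
  expect_true(grepl("^\\(", readLines(nwk)[1]))
})

test_that("correlation matches the closed-form covariance formula", {
  expect_equal(correlate(1:10, 2 * (1:10) + 3, "pearson")$r, 1)
  expect_equal(correlate(1:10, 11 - (1:10), "spearman")$r, -1)
  set.seed(21)
  x <- rnorm(10); y <- rnorm(10)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(correlate(x, y, "pearson")$r - r_oracle), 1e-12)
  expect_error(correlate(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("RPKM follows 1e9 * count / (length * total)", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "positive")
})

test_that("expression-frequency association flags anti-coupled genes", {
  # perfectly anti-monotone fixture
  mat <- matrix(seq(0.9, 0.1, length.out = 9), nrow = 9,
                dimnames = list(paste0("c", 1:9), "chr1:10"))
  expr <- matrix(seq(1, 9), nrow = 1,
                 dimnames = list("g1", paste0("c", 1:9)))
  sg <- data.table::data.table(site = "chr1:10", gene_id = "g1")
  out <- expression_vs_frequency(mat, sg, expr)
  expect_equal(out$rho, -1)
  expect_true(out$flagged)
  # -1-coded (thin coverage) cells are excluded from the test
  mat[1, 1] <- -1
  out2 <- expression_vs_frequency(mat, sg, expr)
  expect_equal(out2$n_cells, 8)
  # sites with too few usable cells are skipped
  mat[1:7, 1] <- -1
  expect_equal(nrow(expression_vs_frequency(mat, sg, expr)), 0)
})

test_that("stage-specificity Fisher flags require enrichment and P < 0.05", {
  meta <- data.table::data.table(
    cell_id = sprintf("c%02d", 1:36),
    stage = rep(c("oocyte", "zygote", "2cell", "4cell", "8cell", "morula"),
                each = 6))
  # gene gO edited in all six oocytes and nowhere else
  edited <- data.table::data.table(cell_id = sprintf("c%02d", 1:6),
                                   gene_id = "gO", edited = TRUE)
  st <- stage_specific_editing(edited, meta, "single_stage")
  row <- st[gene_id == "gO" & stage == "oocyte"]
  expect_true(row$flagged)
  expect_equal(row$fet_p, oracle_fet(6, 0, 0, 30), tolerance = 1e-12)
  expect_false(any(st[stage != "oocyte", flagged]))
  # uniform editing in half the cells of every stage is never flagged
  edited_u <- data.table::data.table(
    cell_id = meta$cell_id[seq(1, 36, by = 2)], gene_id = "gU", edited = TRUE)
  st_u <- stage_specific_editing(edited_u, meta, "single_stage")
  expect_false(any(st_u[gene_id == "gU", flagged]))
  # two-sequential mode flags a zygote+2cell-confined gene at that pair
  edited_p <- data.table::data.table(cell_id = sprintf("c%02d", 7:18),
                                     gene_id = "gP", edited = TRUE)
  st_p <- stage_specific_editing(edited_p, meta, "two_sequential")
  expect_true(st_p[gene_id == "gP" & stage == "zygote+2cell", flagged])
  best <- st_p[gene_id == "gP"][which.min(fet_p)]
  expect_equal(best$stage, "zygote+2cell")
  # stages below the cell floor are excluded with a warning
  expect_warning(
    stage_specific_editing(edited, rbind(meta,
      data.table::data.table(cell_id = "x1", stage = "pronucleus")),
      "single_stage"),
    "pronucleus")
})

test_that("stage summaries report mean, sd and sequential rank-sum tests", {
  cells <- data.table::data.table(
    cell_id = sprintf("c%d", 1:9),
    stage = rep(c("oocyte", "zygote", "2cell"), c(4, 4, 1)),
    n_sites = c(10, 12, 11, 13, 5, 6, 4, 3, 8),
    editing_level = c(10, 12, 11, 13, 5, 6, 4, 3, 8))
  ss <- stage_summaries(cells)
  expect_equal(ss$summary$stage, c("oocyte", "zygote", "2cell"))
  expect_equal(ss$summary[stage == "oocyte", mean_sites], 11.5)
  expect_equal(ss$summary[stage == "zygote", mean_sites], 4.5)
  expect_true(ss$summary[stage == "2cell", single_cell])
  expect_equal(ss$summary[stage == "2cell", sd_level], 0)
  # fully separated levels give the exact two-sided minimum P for 4 v 4
  expect_equal(ss$tests[stage_a == "oocyte", p], 2 / choose(8, 4))
  # identical distributions are not significant
  cells2 <- data.table::data.table(cell_id = sprintf("c%d", 1:8),
                                   stage = rep(c("oocyte", "zygote"), 4),
                                   n_sites = 5, editing_level = 5)
  expect_gte(stage_summaries(cells2)$tests$p, 0.99)
})

test_that("editing level tracks planted activity across the simulated cohort", {
  sim <- tiny_sim()
  res <- tiny_result()
  tc <- sim$truth_cells[match(res$cells$cell_id, cell_id)]
  expect_gte(correlate(res$cells$editing_level, tc$activity, "pearson")$r, 0.7)
})
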