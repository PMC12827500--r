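toy_qc_atlas <- function() {
  # one cell (5, 0, 3) with gene 1 mitochondrial, one all-zero cell
  counts <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 1), x = c(5, 3),
                                 dims = c(3, 2))
  cell_atlas(counts, data.frame(symbol = c("mt-Nd1", "Actb", "Ccl2")),
             data.frame(barcode = c("c1", "c2")))
}

test_that("QC statistics match hand computation and handle empty cells", {
  expect_warning(qc <- compute_cell_qc(toy_qc_atlas()), "zero total")
  expect_equal(qc$detected_genes, c(2L, 0L))
  expect_equal(qc$mito_fraction, c(5 / 8, 0))
  expect_equal(qc$total_counts, c(8, 0))
})

test_that("QC fractions equal brute-force dense recomputation", {
  a <- generate_atlas(tiny_config(seed = 12, cells = 5))$atlas
  qc <- compute_cell_qc(a)
  dense <- as.matrix(a$counts)
  mito <- a$gene_meta$mito
  for (j in sample(ncol(dense), 50)) {
    expect_equal(qc$detected_genes[j], sum(dense[, j] > 0))
    expect_equal(qc$mito_fraction[j],
                 sum(dense[mito, j]) / max(sum(dense[, j]), 1))
  }
})

test_that("cell filtering keeps thresholds inclusive and is idempotent", {
  # craft detected-gene counts straddling the bounds
  n_genes <- 6010L
  make_cell <- function(k) { v <- numeric(n_genes); v[seq_len(k)] <- 1; v }
  m <- Matrix::Matrix(vapply(c(199L, 200L, 6000L, 6001L), make_cell,
                             numeric(n_genes)), sparse = TRUE)
  a <- cell_atlas(m, data.frame(symbol = sprintf("g%d", seq_len(n_genes))),
                  data.frame(barcode = paste0("c", 1:4)))
  kept <- filter_cells(a)
  expect_equal(kept$cell_meta$barcode, c("c2", "c3"))  # boundaries retained
  expect_equal(filter_cells(kept)$cell_meta$barcode, kept$cell_meta$barcode)

  # mito boundary: exactly 10% is retained, just above is not
  m2 <- Matrix::sparseMatrix(i = c(1, 2, 1, 2), j = c(1, 1, 2, 2),
                             x = c(10, 90, 11, 89), dims = c(300, 2))
  a2 <- cell_atlas(m2, data.frame(
    symbol = c("mt-Nd1", sprintf("g%d", 2:300))),
    data.frame(barcode = c("ok", "high")))
  kept2 <- filter_cells(a2, min_genes = 1L)
  expect_equal(kept2$cell_meta$barcode, "ok")
  expect_error(filter_cells(a2, min_genes = 1L, max_mito = 0.001),
               "no cells pass")
})

test_that("filtering equals the brute-force predicate on a random fixture", {
  a <- generate_atlas(tiny_config(seed = 13, cells = 10))$atlas
  qc <- compute_cell_qc(a)
  kept <- filter_cells(a, qc, min_genes = 60L, max_genes = 100L,
                       max_mito = 0.08)
  manual <- qc$barcode[qc$detected_genes >= 60 & qc$detected_genes <= 100 &
                         qc$mito_fraction <= 0.08]
  expect_equal(kept$cell_meta$barcode, manual)
})

test_that("log-normalization follows the formula and its invariances", {
  counts <- Matrix::Matrix(matrix(c(0, 10, 9990, 0, 5, 5), ncol = 2),
                           sparse = TRUE)
  norm <- log_normalize(counts, scale = 1e4)
  expect_equal(norm[1, 1], 0)
  expect_equal(norm[2, 1], log(11))        # 10/10000*1e4 + 1
  # doubling all counts of a cell changes nothing
  norm2 <- log_normalize(counts * 2, scale = 1e4)
  expect_equal(as.matrix(norm2), as.matrix(norm))
  # monotone within a cell
  expect_true(norm[3, 1] > norm[2, 1])
})

test_that("variable-gene selection recovers the planted marker genes", {
  a <- generate_atlas(default_sim_config(seed = 14, cells_per_group = 30L,
                                         n_genes = 150L))$atlas
  blood <- subset_atlas(a, cells = which(a$cell_meta$tissue == "blood"))
  # subgroup markers are bimodal across cells, hence highly variable
  markers <- c("Ly6c2", "Plac8", "Ms4a4c", "Treml4", "Ace", "Spn")
  top <- select_variable_genes(blood, n = 30L)
  expect_true(all(markers %in% top))
  # a zero-variance gene ranks last
  m <- rbind(as.matrix(blood$counts), zero = 0)
  ranking <- attr(select_variable_genes(m, n = 5L), "ranking")
  expect_equal(ranking$symbol[nrow(ranking)], "zero")
  expect_length(select_variable_genes(m, n = 40L), 40L)
  expect_error(select_variable_genes(m, n = 1000L), "only")
})

test_that("PCA embedding is deterministic, ordered and separates groups", {
  a <- generate_atlas(tiny_config(seed = 14))$atlas
  blood <- subset_atlas(a, cells = which(a$cell_meta$tissue == "blood" &
                                           a$cell_meta$subgroup %in%
                                           c("B.cells", "Ly6c+.Mon")))
  norm <- log_normalize(blood)
  hvg <- select_variable_genes(blood, n = 50L)
  e1 <- scale_and_pca(norm, hvg, n_pcs = 5L)
  e2 <- scale_and_pca(norm, hvg, n_pcs = 5L)
  expect_identical(e1, e2)
  sdev <- attr(e1, "sdev")
  expect_true(all(diff(sdev) <= 1e-8))      # non-increasing variance
  # the two subgroups separate in PC space (positive silhouette)
  lab <- blood$cell_meta$subgroup
  sil <- cluster::silhouette(as.integer(factor(lab)), dist(e1[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
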