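test_that("Prim MST matches exhaustive spanning-tree enumeration", {
  set.seed(31)
  for (n in c(4L, 5L, 6L)) {
    for (rep in 1:5) {
      pts <- matrix(runif(2 * n, 0, 10), ncol = 2)
      d <- as.matrix(dist(pts))
      edges <- myelotrace:::mst_edges(d)
      expect_equal(nrow(edges), n - 1L)
      expect_equal(sum(edges$weight), brute_mst_weight(d), tolerance = 1e-12)
    }
  }
})

test_that("MST edge set agrees with igraph on known centroid coordinates", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  edges <- myelotrace:::mst_edges(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  gm <- igraph::mst(g)
  expect_equal(sum(edges$weight), sum(igraph::E(gm)$weight),
               tolerance = 1e-12)
  key <- paste(edges$from, edges$to)
  expect_setequal(key, c("1 2", "2 3", "3 4"))
})

test_that("three-branch data recovers three states and true ordering", {
  cfg <- tiny_config(seed = 7, n_genes = 150L)
  tr <- generate_trajectory_data(cfg)
  model <- fit_trajectory(tr$embedding, tr$atlas$cell_meta$subgroup,
                          k_centroids = 25L, root_rule = "Ly6c+.Mon")
  expect_equal(model$n_states, 3L)
  expect_gte(matched_accuracy(model$cell_state, tr$truth$state), 0.8)
  expect_gte(cor(model$pseudotime, tr$truth$pseudotime,
                 method = "spearman"), 0.9)
  expect_true(all(model$pseudotime >= 0))
  # root-assigned cells sit at minimal pseudotime
  root_cells <- model$cell_centroid == model$root
  expect_lt(mean(model$pseudotime[root_cells]),
            mean(model$pseudotime[!root_cells]))
})

test_that("linear data yields a single state with monotone pseudotime", {
  cfg <- tiny_config(seed = 8, n_genes = 120L)
  tr <- generate_trajectory_data(cfg, linear_branch_spec())
  model <- fit_trajectory(tr$embedding, tr$atlas$cell_meta$subgroup,
                          k_centroids = 12L, root_rule = "Ly6c+.Mon")
  expect_equal(model$n_states, 1L)
  expect_gte(cor(model$pseudotime, tr$truth$pseudotime,
                 method = "spearman"), 0.9)
})

test_that("degenerate embeddings and bad arguments are rejected", {
  emb <- matrix(1, nrow = 50, ncol = 2)
  expect_error(fit_trajectory(emb, rep("a", 50), k_centroids = 5L,
                              root_rule = "a"),
               "degenerate")
  emb2 <- matrix(rnorm(100), ncol = 2)
  expect_error(fit_trajectory(emb2, rep("a", 50), k_centroids = 60L,
                              root_rule = "a"),
               "fewer cells")
  expect_error(fit_trajectory(emb2, rep("a", 50), k_centroids = 5L,
                              root_rule = "missing"),
               "not present")
})

test_that("branch-dependent genes are detected with planted sensitivity", {
  cfg <- tiny_config(seed = 9, n_genes = 150L)
  tr <- generate_trajectory_data(cfg)
  model <- fit_trajectory(tr$embedding, tr$atlas$cell_meta$subgroup,
                          k_centroids = 25L, root_rule = "Ly6c+.Mon")
  norm <- log_normalize(tr$atlas)
  res <- branch_dependent_genes(norm, model)
  expect_true(all(res$p_adj >= res$p))
  prog_genes <- tr$truth$programs$gene
  sens <- mean(res$significant[match(prog_genes, res$gene)])
  expect_gte(sens, 0.9)
  # a gene with identical expression across states is not significant
  flat <- res[!res$gene %in% prog_genes & res$f < 1, ]
  expect_gt(nrow(flat), 0)
})

test_that("gene subgroup clustering recovers the six planted programs", {
  cfg <- tiny_config(seed = 10, n_genes = 150L)
  tr <- generate_trajectory_data(cfg)
  model <- fit_trajectory(tr$embedding, tr$atlas$cell_meta$subgroup,
                          k_centroids = 25L, root_rule = "Ly6c+.Mon")
  norm <- log_normalize(tr$atlas)
  res <- branch_dependent_genes(norm, model)
  cl <- cluster_branch_genes(res, k = 6L)
  prog <- tr$truth$programs
  common <- intersect(names(cl), prog$gene)
  ari <- mclust::adjustedRandIndex(cl[common],
                                   prog$program[match(common, prog$gene)])
  expect_gte(ari, 0.8)
  # k = 1 puts everything in one subgroup
  one <- cluster_branch_genes(res, k = 1L)
  expect_true(all(one == 1L))
  # permuting input gene order leaves the partition unchanged
  res2 <- res[sample(nrow(res)), ]
  attr(res2, "state_means") <- attr(res, "state_means")
  class(res2) <- class(res)
  cl2 <- cluster_branch_genes(res2, k = 6L)
  expect_equal(cl2[names(cl)], cl)
  expect_error(cluster_branch_genes(res, k = nrow(res) + 10L),
               "smaller k")
})
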