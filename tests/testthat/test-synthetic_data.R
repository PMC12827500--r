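test_that("generation is deterministic under a fixed seed", {
  a <- generate_atlas(tiny_config(seed = 5))
  b <- generate_atlas(tiny_config(seed = 5))
  expect_identical(as.matrix(a$atlas$counts), as.matrix(b$atlas$counts))
  expect_identical(a$atlas$cell_meta, b$atlas$cell_meta)
  c <- generate_atlas(tiny_config(seed = 6))
  expect_false(identical(as.matrix(a$atlas$counts),
                         as.matrix(c$atlas$counts)))
})

test_that("an injected condition effect is recovered from group means", {
  spec <- data.frame(tissue = "cortex", subgroup = "aMG",
                     condition = rep(c("TBI", "Sham"), 2),
                     timepoint = rep(c("24h", "7d"), each = 2), n = 500L)
  cfg <- sim_config(seed = 2, tissues = "cortex", subgroup_spec = spec,
                    n_genes = 50L,
                    condition_effects = data.frame(
                      gene = "Ccl2", tissue = "cortex", subgroup = "aMG",
                      timepoint = "24h", log2fc = 1.5))
  a <- generate_atlas(cfg)$atlas
  sel24 <- a$cell_meta$timepoint == "24h"
  tbi <- mean(a$counts["Ccl2", sel24 & a$cell_meta$condition == "TBI"])
  sham <- mean(a$counts["Ccl2", sel24 & a$cell_meta$condition == "Sham"])
  expect_equal(log2(tbi / sham), 1.5, tolerance = 0.25)
  # no effect at the other timepoint
  tbi7 <- mean(a$counts["Ccl2", !sel24 & a$cell_meta$condition == "TBI"])
  sham7 <- mean(a$counts["Ccl2", !sel24 & a$cell_meta$condition == "Sham"])
  expect_lt(abs(log2(tbi7 / sham7)), 0.5)
})

test_that("a null configuration keeps per-gene type-I error near 5%", {
  spec <- data.frame(tissue = "blood", subgroup = "B.cells",
                     condition = c("TBI", "Sham"), timepoint = "24h",
                     n = 60L)
  cfg <- sim_config(seed = 4, tissues = "blood", subgroup_spec = spec,
                    n_genes = 300L)
  a <- generate_atlas(cfg)$atlas
  norm <- log_normalize(a)
  tbi <- a$cell_meta$condition == "TBI"
  p <- apply(as.matrix(norm), 1L, function(v) {
    if (stats::sd(v[tbi]) == 0 && stats::sd(v[!tbi]) == 0) return(1)
    student_t(v[tbi], v[!tbi])$p_value
  })
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("configs referencing unknown subgroups or tissues are rejected", {
  spec <- data.frame(tissue = "blood", subgroup = "B.cells",
                     condition = "TBI", timepoint = "24h", n = 10L)
  expect_error(sim_config(seed = 1, tissues = "blood", subgroup_spec = spec,
                          condition_effects = data.frame(
                            gene = "Ccl2", tissue = "blood",
                            subgroup = "nope", timepoint = "24h",
                            log2fc = 1)),
               "unknown subgroup")
  expect_error(sim_config(seed = 1, tissues = "blood", subgroup_spec = spec,
                          marker_spec = data.frame(subgroup = "ghost",
                                                   gene = "Ccl2",
                                                   log2fc = 1)),
               "unknown subgroup")
  spec$n <- 0L
  expect_error(sim_config(seed = 1, tissues = "blood", subgroup_spec = spec),
               "> 0")
})

test_that("PPI generation yields true pairs plus decoys, deduplicated", {
  cfg <- tiny_config(seed = 3)
  tp <- list(c("Ccl2", "Ccr2"), c("Ccl7", "Ccr2"),
             c("Tnf", "Tnfrsf1b"), c("Grn", "Flna"))
  ppi <- generate_ppi(cfg, tp, n_decoys = 50L)
  expect_equal(nrow(ppi), 54L)
  expect_true(all(ppi$gene_a < ppi$gene_b))
  # the four true edges are present
  key <- paste(ppi$gene_a, ppi$gene_b)
  for (p in tp) expect_true(paste(min(p), max(p)) %in% key)
  # duplicate true pair supplied twice is stored once; empty is empty
  dup <- generate_ppi(cfg, list(c("Ccl2", "Ccr2"), c("Ccr2", "Ccl2")),
                      n_decoys = 0L)
  expect_equal(nrow(dup), 1L)
  expect_equal(nrow(generate_ppi(cfg, list(), n_decoys = 0L)), 0L)
})

test_that("location assignment is total, single-labeled and validated", {
  cfg <- tiny_config(seed = 3)
  loc <- generate_locations(cfg, secreted = c("Ccl2", "Ccl7"),
                            membrane = "Ccr2")
  expect_equal(unname(loc["Ccl2"]), "secreted")
  expect_equal(unname(loc["Ccr2"]), "plasma membrane")
  expect_equal(unname(loc["Gene0001"]), "other")
  expect_equal(sort(names(loc)), sort(cfg$genes))
  expect_error(generate_locations(cfg, secreted = "Ccl2",
                                  membrane = "Ccl2"),
               "both secreted and membrane")
})

test_that("gene-set generation plants sets verbatim and round-trips", {
  cfg <- tiny_config(seed = 8)
  planted <- list(MYELOID = c("Ccl2", "Ccr2", "Tnf"))
  sets <- generate_genesets(cfg, planted, n_filler = 5L)
  expect_equal(sets$MYELOID, planted$MYELOID)
  expect_equal(length(sets), 6L)
  dir <- withr::local_tempdir()
  write_gmt(sets, file.path(dir, "s.gmt"))
  back <- read_gmt(file.path(dir, "s.gmt"))
  expect_equal(back[names(sets)], sets, ignore_attr = TRUE)
})

test_that("noise-free qPCR plates invert to the injected fold change", {
  plate <- generate_qpcr(7, genes = c("Ccl2", "Tnf"),
                         fold_changes = c(4, 2), ct_sd = 0)
  res <- suppressWarnings(ddct_analysis(plate))
  expect_equal(res$fold_change[res$gene == "Ccl2"], 4, tolerance = 1e-10)
  expect_equal(res$fold_change[res$gene == "Tnf"], 2, tolerance = 1e-10)
  expect_equal(res$sd, c(0, 0), tolerance = 1e-10)
})

test_that("a unit fold change is not called significant at typical n", {
  plate <- generate_qpcr(9, genes = "Ccl2", fold_changes = 1,
                         n_bio = 3L, ct_sd = 0.2)
  res <- ddct_analysis(plate)
  expect_gt(res$p, 0.05)
  expect_equal(res$fold_change, 1, tolerance = 0.5)
})

test_that("trajectory data carries the designed states and programs", {
  cfg <- tiny_config(seed = 6)
  tr <- generate_trajectory_data(cfg)
  expect_equal(sort(unique(tr$truth$state)), 1:3)
  expect_equal(nrow(tr$embedding), ncol(tr$atlas$counts))
  # root segment carries the monocyte label
  expect_true(all(tr$atlas$cell_meta$subgroup[tr$truth$state == 1] ==
                    "Ly6c+.Mon"))
  # program genes are elevated on their active states
  prog <- tr$truth$programs
  g <- prog$gene[prog$program == 2][1]      # active on state 2 only
  m_on <- mean(tr$atlas$counts[g, tr$truth$state == 2])
  m_off <- mean(tr$atlas$counts[g, tr$truth$state != 2])
  expect_gt(log2(m_on / m_off), 1)
  # linear spec: a single state
  lin <- generate_trajectory_data(cfg, linear_branch_spec())
  expect_equal(sort(unique(lin$truth$state)), 1:2)  # two segments, one path
})
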