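meta_from_counts <- function(counts, tissue = "blood") {
  data.frame(barcode = sprintf("%s_c%d", tissue, seq_len(sum(counts))),
             tissue = tissue,
             subgroup = rep(names(counts), counts),
             stringsAsFactors = FALSE)
}

test_that("atlas-level percentages reproduce printed two-decimal values", {
  blood <- c(B.cells = 13416L, CD4T = 3690L, CD8T = 1565L,
             NK.cells = 1216L, `Ly6c+.Mon` = 1015L, GRAN = 857L,
             `Treml4+.Mon` = 816L, MEGK = 225L)
  tab <- subgroup_proportions(meta_from_counts(blood), by = "tissue")
  expect_equal(sum(tab$n), 22800L)
  expect_equal(tab$percent[tab$subgroup == "B.cells"], 58.84)
  expect_equal(tab$percent[tab$subgroup == "Ly6c+.Mon"], 4.45)
  expect_equal(tab$percent[tab$subgroup == "Treml4+.Mon"], 3.58)
  hip <- c(ODC = 5808L, ASC = 4598L, NEU = 4270L, END = 3914L,
           aMG = 2641L, OPC = 2018L, MG = 1801L, CPE = 910L)
  # the hippocampus myeloid percentages, against their printed values
  tab2 <- subgroup_proportions(meta_from_counts(hip, "hippocampus"))
  expect_equal(tab2$percent[tab2$subgroup == "aMG"],
               round_half_up_oracle(100 * 2641 / sum(hip)))
  expect_equal(round_half_up_oracle(100 * 2641 / 29012), 9.10)
  expect_equal(tab2$percent[tab2$subgroup == "MG"],
               round_half_up_oracle(100 * 1801 / sum(hip)))
})

test_that("percentages sum to 100 and are permutation invariant", {
  a <- generate_atlas(tiny_config(seed = 15))$atlas
  meta <- a$cell_meta
  tab <- subgroup_proportions(meta, by = c("tissue", "condition",
                                           "timepoint"))
  sums <- tapply(tab$percent,
                 paste(tab$tissue, tab$condition, tab$timepoint), sum)
  expect_true(all(abs(sums - 100) < 0.05))
  perm <- meta[sample(nrow(meta)), ]
  tab2 <- subgroup_proportions(perm, by = c("tissue", "condition",
                                            "timepoint"))
  expect_equal(tab, tab2)
  # zero-count subgroup reported as 0.00
  meta0 <- meta[meta$tissue == "blood", ]
  meta0$subgroup[meta0$subgroup == "MEGK"] <- "B.cells"
  meta0$subgroup[1] <- "MEGK"; meta0$condition[1] <- "TBI"
  tabz <- subgroup_proportions(meta0, by = c("tissue", "condition"))
  z <- tabz[tabz$condition == "Sham" & tabz$subgroup == "MEGK", ]
  expect_equal(z$n, 0L)
  expect_equal(z$percent, 0)
})

test_that("restricted fractions use the family denominator", {
  meta <- data.frame(barcode = paste0("c", 1:120),
                     tissue = "cortex",
                     subgroup = c(rep("MG", 30), rep("aMG", 70),
                                  rep("NEU", 20)))
  fr <- restricted_fractions(meta, c("MG", "aMG"), by = "tissue")
  expect_equal(fr$percent[fr$subgroup == "aMG"], 70.00)
  expect_equal(fr$denominator, c(100L, 100L))
  # family member absent from a group: 0.00, no error
  fr2 <- restricted_fractions(meta[meta$subgroup != "MG", ],
                              c("MG", "aMG"), by = "tissue")
  expect_equal(fr2$percent[fr2$subgroup == "MG"], 0)
  expect_error(restricted_fractions(meta[meta$subgroup == "NEU", ],
                                    c("MG", "aMG")),
               "no cells belong")
})

test_that("condition contrasts recover planted composition shifts", {
  a <- generate_atlas(tiny_config(seed = 16, cells = 40))$atlas
  meta <- a$cell_meta[a$cell_meta$tissue == "cortex", ]
  fr <- restricted_fractions(meta, c("MG", "aMG"),
                             by = c("tissue", "condition", "timepoint"))
  con <- condition_contrast(fr)
  amg24 <- con$delta_pp[con$subgroup == "aMG" & con$timepoint == "24h"]
  expect_gt(amg24, 5)   # planted doubling of aMG at TBI 24h
  amg7 <- con$delta_pp[con$subgroup == "aMG" & con$timepoint == "7d"]
  expect_equal(amg7, 0) # equal designed counts at 7d
  # equal proportions give a zero delta, missing level errors
  expect_error(condition_contrast(fr[fr$condition == "TBI", ]),
               "missing condition")
})
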