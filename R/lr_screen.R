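# Five-criteria ligand-receptor screen: a candidate ordered pair
# (A, B) over the branch-gene subgroup map is retained iff
#   (1) A belongs to a ligand-eligible gene subgroup (1, 2, 3 or 6),
#   (2) A is annotated "secreted",
#   (3) B belongs to a receptor-eligible subgroup (4 or 5),
#   (4) B is annotated "plasma membrane",
#   (5) A and B share a protein-protein interaction record.
# Self-pairs are excluded; direction is fixed ligand -> receptor.

#' Screen ligand-receptor pairs
#'
#' Evaluates the five-predicate conjunction over all ordered gene pairs
#' drawn from the subgroup map. The returned table records the
#' predicate outcomes for every candidate matching at least
#' `audit_min` predicates (an audit trail for near-misses) with the
#' retained pairs flagged; output is sorted by (ligand, receptor).
#'
#' @param gene_subgroups Named integer vector: gene -> subgroup 1..6
#'   (from [cluster_branch_genes()]).
#' @param locations Named character vector: gene -> location label
#'   (from [read_locations()] / [generate_locations()]).
#' @param ppi Interaction `data.frame` with `gene_a`, `gene_b`
#'   (undirected).
#' @param ligand_subgroups,receptor_subgroups Eligible subgroup ids.
#' @param audit_min Minimum number of satisfied predicates for a
#'   candidate to appear in the audit table.
#' @return `data.frame` of class `"lr_screen"`: `ligand`, `receptor`,
#'   the five predicate columns, `n_ok`, `retained`.
#' @export
screen_lr_pairs <- function(gene_subgroups, locations, ppi,
                            ligand_subgroups = c(1L, 2L, 3L, 6L),
                            receptor_subgroups = c(4L, 5L),
                            audit_min = 4L) {
  if (!length(gene_subgroups)) stop("empty gene subgroup map")
  if (is.null(names(gene_subgroups))) stop("gene_subgroups must be named")
  if (!nrow(ppi)) stop("empty interaction table")
  genes <- names(gene_subgroups)
  loc <- locations[genes]
  names(loc) <- genes
  loc[is.na(loc)] <- "other"
  edge_key <- paste(pmin(ppi$gene_a, ppi$gene_b),
                    pmax(ppi$gene_a, ppi$gene_b))

  grid <- expand.grid(ligand = genes, receptor = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ligand != grid$receptor, , drop = FALSE]
  grid$A_subgroup_ok <- gene_subgroups[grid$ligand] %in% ligand_subgroups
  grid$A_secreted <- loc[grid$ligand] == "secreted"
  grid$B_subgroup_ok <- gene_subgroups[grid$receptor] %in% receptor_subgroups
  grid$B_membrane <- loc[grid$receptor] == "plasma membrane"
  grid$interaction_present <- paste(pmin(grid$ligand, grid$receptor),
                                    pmax(grid$ligand, grid$receptor)) %in%
    edge_key
  pred <- c("A_subgroup_ok", "A_secreted", "B_subgroup_ok", "B_membrane",
            "interaction_present")
  grid$n_ok <- rowSums(grid[pred])
  grid$retained <- grid$n_ok == 5L
  out <- grid[grid$n_ok >= audit_min, , drop = FALSE]
  out <- out[order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lr_screen", "data.frame")
  out
}

#' @export
print.lr_screen <- function(x, ...) {
  kept <- x[x$retained, , drop = FALSE]
  cat(sprintf("lr_screen: %d retained pair(s), %d audited candidate(s)\n",
              nrow(kept), nrow(x)))
  if (nrow(kept)) {
    cat(paste0("  ", kept$ligand, " - ", kept$receptor, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Retained pairs of a screen
#' @param screen An `lr_screen` result.
#' @return `data.frame` with `ligand`, `receptor` of retained pairs.
#' @export
retained_pairs <- function(screen) {
  stopifnot(inherits(screen, "lr_screen"))
  out <- screen[screen$retained, c("ligand", "receptor"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential-expression annotation of screened genes
#'
#' For each (gene, subgroup, timepoint) in one tissue's atlas: a
#' two-sided Student's t-test of log-normalized per-cell expression,
#' TBI vs Sham, with star labels. A per-mouse pseudobulk mode (mean
#' expression per mouse as the unit of replication) is available
#' because per-cell tests treat cells as independent replicates.
#'
#' @param norm Normalized genes-by-cells matrix for one tissue.
#' @param cell_meta Matching per-cell metadata (needs `subgroup`,
#'   `condition`, `timepoint`, `mouse`).
#' @param genes Genes to annotate.
#' @param subgroups Subgroups to test (default: all present).
#' @param pseudobulk Per-mouse means instead of per-cell values.
#' @param equal_var Student (TRUE) or Welch.
#' @return `data.frame`: `gene`, `tissue`, `subgroup`, `timepoint`,
#'   `mean_tbi`, `mean_sham`, `t`, `p`, `star`.
#' @export
lr_expression_stats <- function(norm, cell_meta, genes, subgroups = NULL,
                                pseudobulk = FALSE, equal_var = TRUE) {
  genes <- intersect(genes, rownames(norm))
  if (!length(genes)) stop("none of the requested genes are in the matrix")
  if (is.null(subgroups)) subgroups <- sort(unique(cell_meta$subgroup))
  tissue <- if ("tissue" %in% names(cell_meta))
    unique(cell_meta$tissue)[1L] else NA_character_
  rows <- list()
  for (gene in genes) {
    expr <- as.numeric(norm[gene, ])
    for (sg in subgroups) {
      for (tp in intersect(VALID_TIMEPOINTS, unique(cell_meta$timepoint))) {
        sel <- cell_meta$subgroup == sg & cell_meta$timepoint == tp
        if (!any(sel)) next
        vals <- expr[sel]
        cond <- cell_meta$condition[sel]
        if (pseudobulk) {
          mice <- cell_meta$mouse[sel]
          agg <- tapply(vals, list(mice), mean)
          mcond <- tapply(cond, list(mice), function(x) x[1L])
          vals <- as.numeric(agg)
          cond <- as.character(mcond)
        }
        xt <- vals[cond == "TBI"]; xs <- vals[cond == "Sham"]
        if (length(xt) < 2L || length(xs) < 2L) next
        tt <- student_t(xt, xs, equal_var = equal_var)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, tissue = tissue, subgroup = sg, timepoint = tp,
          mean_tbi = tt$means[1], mean_sham = tt$means[2],
          t = tt$statistic, p = tt$p_value, star = star_label(tt$p_value),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable (gene, subgroup, timepoint) cell groups")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
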