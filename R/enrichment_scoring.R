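# Gene-set machinery: hypergeometric over-representation for gene
# subgroups and a rank-based per-cell pathway activity score.

#' Over-representation analysis (hypergeometric tail)
#'
#' For each gene set (intersected with the universe) the upper-tail
#' hypergeometric probability of observing at least the realized
#' overlap with the query, P(X >= overlap), with Benjamini-Hochberg
#' adjustment across all tested sets. Significant iff adjusted p <
#' `alpha`.
#'
#' @param query Character vector of query genes (must lie in
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param genesets Named list of character vectors.
#' @param alpha Adjusted-p cutoff.
#' @return `data.frame`: `set`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p`, `p_adj`, `significant`.
#' @export
ora <- function(query, universe, genesets, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  out <- setdiff(query, universe)
  if (length(out)) stop("query gene(s) outside the universe: ",
                        paste(utils::head(out, 5), collapse = ", "))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(genesets), function(nm) {
    s <- intersect(genesets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- if (length(s) == 0L) 1 else
      stats::phyper(k - 1L, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = q, set_size = length(s),
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Rank-based per-cell pathway activity (GSVA-style)
#'
#' For each cell, genes are ranked by expression (ties broken by stable
#' gene order, most-expressed first). A weighted random walk steps up
#' by `rank^tau / sum(member ranks^tau)` at member genes and down by
#' `1/(n_genes - n_members)` elsewhere; the score is the maximum plus
#' the minimum of the running sum (the maximum-deviation-difference
#' convention), which lies in [-1, 1]. This is a single-sample
#' enrichment statistic of the ssGSEA/GSVA random-walk family; it is
#' not the kernel-CDF estimator of the original GSVA publication.
#'
#' @param expr Genes-by-cells numeric matrix (log2 scale expected but
#'   any monotone-equivalent input gives identical scores, the
#'   statistic being rank-based).
#' @param genesets Named list of gene sets.
#' @param tau Rank weight exponent (default 1).
#' @return Sets-by-cells numeric matrix of scores in [-1, 1].
#' @export
gsva_like <- function(expr, genesets, tau = 1) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need >= 2 genes")
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix must have gene rownames")
  sets <- lapply(genesets, function(s) which(genes %in% s))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("gene set(s) empty after universe intersection: ",
         paste(names(sets)[empty], collapse = ", "))
  }
  full <- lengths(sets) == nrow(expr)
  if (any(full)) {
    stop("gene set(s) cover every gene (down-step undefined): ",
         paste(names(sets)[full], collapse = ", "))
  }
  n <- nrow(expr)
  scores <- matrix(0, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(names(genesets), colnames(expr)))
  for (cell in seq_len(ncol(expr))) {
    ord <- order(-expr[, cell])             # stable: ties by gene order
    rank_val <- numeric(n)
    rank_val[ord] <- n - seq_len(n) + 1L    # top gene gets rank n
    for (si in seq_along(sets)) {
      member <- logical(n)
      member[sets[[si]]] <- TRUE
      m_ord <- member[ord]
      w <- rank_val[ord]^tau
      up <- ifelse(m_ord, w / sum(w[m_ord]), 0)
      down <- ifelse(m_ord, 0, 1 / (n - sum(member)))
      walk <- cumsum(up - down)
      scores[si, cell] <- max(walk) + min(walk)
    }
  }
  scores
}

#' Compare pathway activity between cell groups
#'
#' Per gene set, a two-sided two-sample t-test (Student by default,
#' Welch optionally) of activity scores between two cell groups.
#' Significance is assessed on the raw p-value at `alpha` by default —
#' the convention used for pathway-level comparisons here — with an
#' optional Benjamini-Hochberg flag.
#'
#' @param scores Sets-by-cells matrix from [gsva_like()].
#' @param groups Factor/character vector (2 levels) over cells.
#' @param alpha Significance cutoff.
#' @param equal_var Student (TRUE) or Welch (FALSE).
#' @param adjust Apply BH across sets before thresholding.
#' @return `data.frame`: `set`, `mean_1`, `mean_2`, `t`, `p`,
#'   (`p_adj`,) `significant`. Group 1 is the first factor level.
#' @export
compare_activity <- function(scores, groups, alpha = 0.05,
                             equal_var = TRUE, adjust = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (length(groups) != ncol(scores)) {
    stop("groups must match score columns")
  }
  g1 <- groups == levels(groups)[1L]
  if (sum(g1) < 2L || sum(!g1) < 2L) {
    stop("need >= 2 cells per group")
  }
  rows <- lapply(rownames(scores), function(nm) {
    tt <- student_t(scores[nm, g1], scores[nm, !g1], equal_var = equal_var)
    data.frame(set = nm, mean_1 = tt$means[1], mean_2 = tt$means[2],
               t = tt$statistic, p = tt$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust) {
    res$p_adj <- bh_adjust(res$p)
    res$significant <- res$p_adj < alpha
  } else {
    res$significant <- res$p < alpha
  }
  rownames(res) <- NULL
  res
}
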