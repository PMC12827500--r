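# Per-tissue preprocessing: cell QC, depth normalization, variable-gene
# selection (vst-style standardized variance) and PCA embedding.

#' Per-cell quality-control statistics
#'
#' Detected genes (count > 0), total counts, and mitochondrial fraction
#' per cell. Cells with zero total counts get `mito_fraction = 0` with a
#' warning (the fraction is otherwise 0/0).
#'
#' @param atlas A `cell_atlas` with mitochondrial flags in `gene_meta`.
#' @return `data.frame` of class `"cell_qc"` with columns `barcode`,
#'   `detected_genes`, `total_counts`, `mito_fraction`.
#' @export
compute_cell_qc <- function(atlas) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (!"mito" %in% names(atlas$gene_meta)) {
    stop("gene_meta lacks the 'mito' flag column")
  }
  counts <- atlas$counts
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_total <- Matrix::colSums(counts[atlas$gene_meta$mito, , drop = FALSE])
  frac <- ifelse(total > 0, mito_total / total, 0)
  if (any(total == 0)) {
    warning(sum(total == 0),
            " cell(s) with zero total counts; mito_fraction set to 0")
  }
  out <- data.frame(barcode = atlas$cell_meta$barcode,
                    detected_genes = as.integer(detected),
                    total_counts = as.numeric(total),
                    mito_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_qc", "data.frame")
  out
}

#' Filter cells on QC thresholds
#'
#' A cell is retained iff `min_genes <= detected <= max_genes` and
#' `mito_fraction <= max_mito`. The boundary is inclusive: the
#' exclusion rule is stated with strict inequalities (fewer than 200 or
#' more than 6,000 detected genes, more than 10% mitochondrial reads),
#' so a cell sitting exactly on a threshold is kept. Filtering is
#' idempotent.
#'
#' @param atlas A `cell_atlas`.
#' @param qc Optional precomputed [compute_cell_qc()] result.
#' @param min_genes,max_genes Detected-gene bounds.
#' @param max_mito Maximum mitochondrial fraction.
#' @return The filtered `cell_atlas`; an error if no cell survives.
#' @export
filter_cells <- function(atlas, qc = NULL, min_genes = 200L,
                         max_genes = 6000L, max_mito = 0.10) {
  stopifnot(inherits(atlas, "cell_atlas"))
  if (min_genes <= 0 || max_genes <= min_genes) {
    stop("need 0 < min_genes < max_genes")
  }
  if (is.null(qc)) qc <- compute_cell_qc(atlas)
  keep <- qc$detected_genes >= min_genes & qc$detected_genes <= max_genes &
    qc$mito_fraction <= max_mito
  if (!any(keep)) stop("no cells pass QC thresholds")
  subset_atlas(atlas, cells = which(keep))
}

#' Depth-normalize counts (log-normalization)
#'
#' Per-cell scaling to a fixed pseudo-depth followed by natural log:
#' `value = ln(1 + count / cell_total * scale)`. Zero counts stay zero
#' and the result is invariant to rescaling all counts within a cell.
#'
#' @param atlas A `cell_atlas` (or a sparse genes-by-cells matrix).
#' @param scale Scale factor (default 1e4).
#' @return Sparse genes-by-cells `dgCMatrix` with the scale factor in
#'   the `"scale_factor"` attribute.
#' @export
log_normalize <- function(atlas, scale = 1e4) {
  counts <- if (inherits(atlas, "cell_atlas")) atlas$counts else
    methods::as(Matrix::Matrix(atlas, sparse = TRUE), "CsparseMatrix")
  total <- Matrix::colSums(counts)
  total[total == 0] <- 1  # all-zero cells stay all-zero
  norm <- counts
  # scale the nonzero entries column-wise without densifying
  percol <- diff(norm@p)
  norm@x <- log1p(norm@x / rep.int(total, percol) * scale)
  attr(norm, "scale_factor") <- scale
  norm
}

#' Select highly variable genes (vst-style)
#'
#' Fits a loess trend of log10(variance) on log10(mean) of the raw
#' counts, standardizes each gene's counts by the trend-predicted sd
#' (clipping standardized values at sqrt(N)), and ranks genes by the
#' variance of the clipped standardized counts. Genes with zero
#' variance rank last. For fixtures with too few positive-variance
#' genes for a stable loess fit, a quadratic polynomial trend is used
#' instead.
#'
#' @param atlas A `cell_atlas` or raw genes-by-cells count matrix.
#' @param n Number of genes to return.
#' @param span Loess span for the mean-variance trend.
#' @return Character vector of the top `n` gene symbols, with the full
#'   ranking table in the `"ranking"` attribute.
#' @export
select_variable_genes <- function(atlas, n = 2000L, span = 0.3) {
  counts <- if (inherits(atlas, "cell_atlas")) atlas$counts else atlas
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  }
  if (n > nrow(counts)) {
    stop("requested ", n, " genes but matrix has only ", nrow(counts))
  }
  N <- ncol(counts)
  mu <- as.numeric(Matrix::rowMeans(counts))
  v <- as.numeric(Matrix::rowMeans(counts^2) * N / (N - 1) -
                    mu^2 * N / (N - 1))
  v[v < 0] <- 0
  ok <- v > 0 & mu > 0
  std_var <- numeric(nrow(counts))
  if (sum(ok) >= 3L) {
    lx <- log10(mu[ok]); ly <- log10(v[ok])
    pred <- if (sum(ok) >= 20L && length(unique(lx)) >= 10L) {
      fit <- stats::loess(ly ~ lx, span = span, degree = 2)
      stats::predict(fit, lx)
    } else {
      fit <- stats::lm(ly ~ stats::poly(lx, degree = min(2L, length(unique(lx)) - 1L)))
      stats::predict(fit)
    }
    sd_pred <- sqrt(10^pred)
    clip <- sqrt(N)
    dense <- as.matrix(counts[ok, , drop = FALSE])
    z <- (dense - mu[ok]) / sd_pred
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[ok] <- rowSums(z^2) / (N - 1)
  }
  ranking <- data.frame(symbol = rownames(counts), mean = mu, variance = v,
                        standardized_variance = std_var,
                        stringsAsFactors = FALSE)
  ord <- order(-ranking$standardized_variance, ranking$symbol)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  out <- utils::head(ranking$symbol, n)
  attr(out, "ranking") <- ranking
  out
}

#' Scale selected genes and embed by PCA
#'
#' Per-gene z-scoring (clipped at `|z| <= clip`) over the selected
#' genes, then exact singular-value decomposition. Components are
#' ordered by decreasing explained variance and each is given a
#' deterministic sign: the loading of largest magnitude is made
#' positive, which removes the SVD sign ambiguity.
#'
#' @param norm Normalized genes-by-cells matrix (from
#'   [log_normalize()]).
#' @param genes Genes to use (e.g. from [select_variable_genes()]);
#'   `NULL` uses all rows.
#' @param n_pcs Number of components.
#' @param clip Z-score clipping bound.
#' @return Cells-by-`n_pcs` matrix with attributes `sdev` (component
#'   standard deviations) and `loadings`.
#' @export
scale_and_pca <- function(norm, genes = NULL, n_pcs = 30L, clip = 10) {
  m <- if (is.null(genes)) norm else norm[genes, , drop = FALSE]
  x <- t(as.matrix(m))                      # cells x genes
  x <- scale(x, center = TRUE, scale = TRUE)
  x[is.na(x)] <- 0                          # constant genes carry no signal
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (n_pcs < 1L) stop("too few cells/genes for PCA")
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    l <- sv$v[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  emb <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2L, flip, `*`)
  loadings <- sweep(sv$v, 2L, flip, `*`)
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("PC", seq_len(n_pcs))
  attr(emb, "sdev") <- sv$d[seq_len(n_pcs)] / sqrt(max(nrow(x) - 1L, 1L))
  attr(emb, "loadings") <- loadings
  emb
}
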