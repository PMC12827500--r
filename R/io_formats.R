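# Readers/writers for every on-disk format the workflow touches:
# 10x-style Matrix Market triplets, tab-separated metadata, GMT gene-set
# collections, protein-protein interaction edge lists and subcellular
# location tables. Parsers validate and reject rather than coerce.

VALID_CONDITIONS <- c("TBI", "Sham")
VALID_TIMEPOINTS <- c("24h", "7d")

# Open a path transparently, decompressing *.gz to a temp file first so
# downstream readers that want a plain file (Matrix::readMM) still work.
local_plain_file <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile()
    inc <- gzfile(path, "rb")
    out <- file(tmp, "wb")
    on.exit({ close(inc); close(out) })
    repeat {
      chunk <- readBin(inc, "raw", n = 1e6)
      if (!length(chunk)) break
      writeBin(chunk, out)
    }
    tmp
  } else {
    path
  }
}

find_triplet_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("none of ", paste(stems, collapse = ", "), " found in ", dir)
}

#' Construct and validate a cell atlas
#'
#' The central container for the package: a sparse genes-by-cells count
#' matrix with per-gene metadata (symbol, mitochondrial flag) and
#' per-cell metadata (barcode, tissue, subgroup, condition, timepoint,
#' mouse). Counts must be non-negative integers and dimensions must
#' agree with the metadata tables; barcodes must be unique within each
#' tissue.
#'
#' @param counts A genes-by-cells matrix (coerced to `dgCMatrix`).
#' @param gene_meta `data.frame` with at least a `symbol` column; a
#'   logical `mito` column is derived from `mito_regex` when absent.
#' @param cell_meta `data.frame` with at least a `barcode` column;
#'   `tissue`, `subgroup`, `condition`, `timepoint`, `mouse` columns are
#'   attached by [read_metadata()] or the synthetic generator.
#' @param mito_regex Pattern identifying mitochondrial gene symbols
#'   (mouse convention `mt-`, case-insensitive).
#' @return An object of class `"cell_atlas"`.
#' @export
cell_atlas <- function(counts, gene_meta, cell_meta, mito_regex = "^mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (!"symbol" %in% names(gene_meta)) stop("gene_meta must have a 'symbol' column")
  if (!"barcode" %in% names(cell_meta)) stop("cell_meta must have a 'barcode' column")
  if (nrow(gene_meta) != nrow(counts)) {
    stop("dimension mismatch: ", nrow(counts), " matrix rows vs ",
         nrow(gene_meta), " gene_meta rows")
  }
  if (nrow(cell_meta) != ncol(counts)) {
    stop("dimension mismatch: ", ncol(counts), " matrix columns vs ",
         nrow(cell_meta), " cell_meta rows")
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(gene_meta$symbol)) {
    gene_meta$symbol <- make.unique(as.character(gene_meta$symbol))
    message("duplicate gene symbols disambiguated with numeric suffixes")
  }
  if (!"mito" %in% names(gene_meta)) {
    gene_meta$mito <- grepl(mito_regex, gene_meta$symbol, ignore.case = TRUE)
  }
  tissue <- if ("tissue" %in% names(cell_meta)) cell_meta$tissue else "unknown"
  if (anyDuplicated(paste(tissue, cell_meta$barcode))) {
    stop("duplicate barcodes within a tissue")
  }
  if ("condition" %in% names(cell_meta)) {
    bad <- setdiff(unique(cell_meta$condition), VALID_CONDITIONS)
    if (length(bad)) stop("invalid condition value(s): ", paste(bad, collapse = ", "))
  }
  if ("timepoint" %in% names(cell_meta)) {
    bad <- setdiff(unique(cell_meta$timepoint), VALID_TIMEPOINTS)
    if (length(bad)) stop("invalid timepoint value(s): ", paste(bad, collapse = ", "))
  }
  rownames(counts) <- gene_meta$symbol
  colnames(counts) <- cell_meta$barcode
  structure(list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("cell_atlas: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  for (col in c("tissue", "subgroup", "condition", "timepoint")) {
    if (col %in% names(x$cell_meta)) {
      lv <- unique(x$cell_meta[[col]])
      cat(sprintf("  %s: %s\n", col,
                  paste(utils::head(lv, 8), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
dim.cell_atlas <- function(x) dim(x$counts)

# Subset an atlas by gene and/or cell index, keeping metadata aligned.
#' Subset a cell atlas
#' @param atlas A `cell_atlas`.
#' @param genes,cells Index vectors (integer, logical or character).
#' @return The subset `cell_atlas`.
#' @export
subset_atlas <- function(atlas, genes = NULL, cells = NULL) {
  stopifnot(inherits(atlas, "cell_atlas"))
  counts <- atlas$counts
  gm <- atlas$gene_meta
  cm <- atlas$cell_meta
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, gm$symbol)
    counts <- counts[genes, , drop = FALSE]
    gm <- gm[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, cm$barcode)
    counts <- counts[, cells, drop = FALSE]
    cm <- cm[cells, , drop = FALSE]
  }
  rownames(gm) <- NULL
  rownames(cm) <- NULL
  structure(list(counts = counts, gene_meta = gm, cell_meta = cm),
            class = "cell_atlas")
}

#' Read a 10x-style triplet directory
#'
#' Expects `matrix.mtx`, a features file (`features.tsv` or `genes.tsv`,
#' 1 column of symbols or 3 columns id/symbol/type) and `barcodes.tsv`,
#' each optionally gzipped. The Matrix Market body is validated against
#' its declared header (entry count, non-negative integer values) before
#' parsing, so malformed files fail with a descriptive error rather than
#' a silent coercion.
#'
#' @param dir Directory containing the triplet.
#' @param mito_regex Pattern for mitochondrial gene symbols.
#' @return A `cell_atlas` (cell metadata holds barcodes only until
#'   [read_metadata()] attaches the rest).
#' @export
read_10x_triplet <- function(dir, mito_regex = "^mt-") {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx_path <- find_triplet_file(dir, "matrix.mtx")
  feat_path <- find_triplet_file(dir, c("features.tsv", "genes.tsv"))
  bc_path <- find_triplet_file(dir, "barcodes.tsv")

  plain <- local_plain_file(mtx_path)
  lines <- readLines(plain)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (length(body) < 1L) stop(mtx_path, ": no size header line")
  hdr <- scan(text = body[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 3L) stop(mtx_path, ": malformed size header '", body[1], "'")
  nnz_declared <- hdr[3]
  nnz_body <- length(body) - 1L
  if (nnz_body != nnz_declared) {
    stop(mtx_path, ": header declares ", nnz_declared,
         " entries but body has ", nnz_body, " lines")
  }
  m <- Matrix::readMM(plain)
  if (length(m@x) && any(m@x != round(m@x) | m@x < 0)) {
    stop(mtx_path, ": non-integer or negative count entries")
  }

  feats <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             stringsAsFactors = FALSE)
  symbol <- if (ncol(feats) >= 2L) feats[[2]] else feats[[1]]
  gene_meta <- data.frame(symbol = symbol, stringsAsFactors = FALSE)
  if (ncol(feats) >= 2L) gene_meta$feature_id <- feats[[1]]

  barcodes <- readLines(bc_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (anyDuplicated(barcodes)) stop(bc_path, ": duplicate barcodes")
  if (nrow(feats) != nrow(m)) {
    stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
         feat_path, " lists ", nrow(feats), " features")
  }
  if (length(barcodes) != ncol(m)) {
    stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
         bc_path, " lists ", length(barcodes), " barcodes")
  }
  cell_atlas(m, gene_meta, data.frame(barcode = barcodes,
                                      stringsAsFactors = FALSE),
             mito_regex = mito_regex)
}

#' Write a cell atlas as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (Matrix Market, 1-based indices), `features.tsv`,
#' `barcodes.tsv` and, when cell metadata is present, `metadata.tsv`.
#'
#' @param atlas A `cell_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x_triplet <- function(atlas, dir) {
  stopifnot(inherits(atlas, "cell_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  feats <- atlas$gene_meta$symbol
  writeLines(feats, file.path(dir, "features.tsv"))
  writeLines(atlas$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  if (ncol(atlas$cell_meta) > 1L) {
    utils::write.table(atlas$cell_meta, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Attach per-cell metadata to an atlas
#'
#' Inner-joins a TSV metadata table (keyed by `barcode`) to the atlas;
#' cells without a metadata row are dropped with a message reporting the
#' count. Condition and timepoint values are validated against the
#' study vocabulary (`TBI`/`Sham`, `24h`/`7d`).
#'
#' @param path TSV file with a header row and a `barcode` column, or a
#'   `data.frame`.
#' @param atlas A `cell_atlas`.
#' @param required Metadata columns that must be present.
#' @return The atlas with metadata attached (possibly fewer cells).
#' @export
read_metadata <- function(path, atlas,
                          required = c("barcode", "tissue", "subgroup",
                                       "condition", "timepoint", "mouse")) {
  stopifnot(inherits(atlas, "cell_atlas"))
  meta <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- atlas$cell_meta$barcode %in% meta$barcode
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " cell(s) without metadata dropped")
  }
  if (!any(keep)) stop("no barcodes in common between atlas and metadata")
  out <- subset_atlas(atlas, cells = which(keep))
  m <- meta[match(out$cell_meta$barcode, meta$barcode), , drop = FALSE]
  rownames(m) <- NULL
  cell_atlas(out$counts, out$gene_meta, m)
}

#' Read / write GMT gene-set collections
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(path, " line ", i, ": GMT lines need name, description and >=1 member")
    }
    nm <- f[1]
    if (nm %in% names(sets)) stop(path, ": duplicate set name '", nm, "'")
    sets[[nm]] <- unique(f[-(1:2)])
    descs[nm] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a protein-protein interaction edge list
#'
#' TSV with header columns `gene_a`, `gene_b`. Edges are undirected:
#' `(A,B)` and `(B,A)` collapse to one row, self-loops are rejected.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `gene_a`, `gene_b`, deduplicated
#'   with `gene_a <= gene_b` lexicographically.
#' @export
read_ppi <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    stop(path, ": PPI table needs 'gene_a' and 'gene_b' columns")
  }
  canonical_edges(tab$gene_a, tab$gene_b)
}

canonical_edges <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) stop("self-interactions are not allowed in the PPI table")
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- unique(data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE))
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_ppi
#' @param edges `data.frame` with `gene_a`, `gene_b` columns.
#' @export
write_ppi <- function(edges, path) {
  utils::write.table(canonical_edges(edges$gene_a, edges$gene_b), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a subcellular-location table
#'
#' TSV with header columns `gene`, `location`; every gene carries
#' exactly one label from `secreted`, `plasma membrane`, `other`.
#' A gene listed twice with conflicting labels is an error.
#'
#' @param path TSV file path.
#' @return Named character vector mapping gene to location.
#' @export
read_locations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("gene", "location") %in% names(tab))) {
    stop(path, ": location table needs 'gene' and 'location' columns")
  }
  bad <- setdiff(unique(tab$location), c("secreted", "plasma membrane", "other"))
  if (length(bad)) stop(path, ": invalid location label(s): ",
                        paste(bad, collapse = ", "))
  dup <- tab[tab$gene %in% tab$gene[duplicated(tab$gene)], , drop = FALSE]
  if (nrow(dup)) {
    conf <- tapply(dup$location, dup$gene, function(l) length(unique(l)) > 1L)
    if (any(conf)) {
      stop(path, ": conflicting locations for gene(s): ",
           paste(names(conf)[conf], collapse = ", "))
    }
    tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  }
  stats::setNames(tab$location, tab$gene)
}

#' @rdname read_locations
#' @param locations Named character vector (gene -> label).
#' @export
write_locations <- function(locations, path) {
  utils::write.table(data.frame(gene = names(locations),
                                location = unname(locations)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
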