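# Subgroup composition dynamics across tissue x condition x timepoint.
# Percentages are reported to 2 decimals with half-up rounding, the
# precision convention used for the atlas-level composition figures.

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Subgroup proportions within groupings
#'
#' Tallies cells per subgroup within each grouping (e.g. tissue, or
#' tissue x condition x timepoint) and reports percentages of the
#' grouping denominator to 2 decimals (half-up). Subgroups present in a
#' grouping's tissue but absent from the grouping itself are reported
#' as 0.00. Proportions are pooled over mice within a grouping.
#'
#' @param cell_meta Per-cell metadata `data.frame` (needs `subgroup`;
#'   grouping columns as requested).
#' @param by Character vector of grouping columns (default: `tissue`
#'   alone if present, else none).
#' @return `data.frame` of class `"composition_table"` with the
#'   grouping columns plus `subgroup`, `n`, `denominator`, `percent`.
#' @export
subgroup_proportions <- function(cell_meta,
                                 by = intersect("tissue", names(cell_meta))) {
  if (!"subgroup" %in% names(cell_meta)) {
    stop("cell_meta needs a 'subgroup' column")
  }
  miss <- setdiff(by, names(cell_meta))
  if (length(miss)) stop("grouping column(s) not found: ",
                         paste(miss, collapse = ", "))
  grp <- if (length(by)) interaction(cell_meta[by], drop = TRUE, sep = "|")
  else factor(rep("all", nrow(cell_meta)))
  if (!nrow(cell_meta)) stop("empty cell metadata")
  tissue_col <- if ("tissue" %in% names(cell_meta)) cell_meta$tissue
  else rep("all", nrow(cell_meta))

  out <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    denom <- sum(sel)
    if (denom == 0L) stop("empty denominator for grouping ", g)
    # subgroup universe: everything observed in the same tissue(s)
    tis <- unique(tissue_col[sel])
    subs <- sort(unique(cell_meta$subgroup[tissue_col %in% tis]))
    cnt <- table(factor(cell_meta$subgroup[sel], levels = subs))
    keyvals <- if (length(by)) strsplit(g, "|", fixed = TRUE)[[1]] else character()
    row <- as.data.frame(as.list(stats::setNames(keyvals, by)),
                         stringsAsFactors = FALSE)
    block <- if (length(by)) row[rep(1L, length(subs)), , drop = FALSE]
    else data.frame(row.names = seq_along(subs))
    block$subgroup <- subs
    block$n <- as.integer(cnt)
    block$denominator <- denom
    block$percent <- round_half_up(100 * as.integer(cnt) / denom, 2L)
    out[[g]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "denominator") <- "all cells in grouping"
  class(res) <- c("composition_table", "data.frame")
  res
}

#' Fractions restricted to a subgroup family
#'
#' Same tallies but with the denominator restricted to a named family
#' of subgroups within each grouping — e.g. activated microglia as a
#' fraction of all microglia (`family = c("MG", "aMG")`), or Treml4+
#' monocytes among all monocytes. A family member absent from a
#' grouping is reported as 0.00 without error.
#'
#' @param cell_meta Per-cell metadata.
#' @param family Character vector of subgroup names forming the
#'   denominator.
#' @param by Grouping columns.
#' @return A `composition_table` restricted to the family.
#' @export
restricted_fractions <- function(cell_meta, family,
                                 by = intersect(c("tissue", "condition",
                                                  "timepoint"),
                                                names(cell_meta))) {
  if (!length(family)) stop("family must name at least one subgroup")
  sub <- cell_meta[cell_meta$subgroup %in% family, , drop = FALSE]
  if (!nrow(sub)) stop("no cells belong to the family ",
                       paste(family, collapse = ", "))
  grp <- if (length(by)) interaction(sub[by], drop = TRUE, sep = "|")
  else factor(rep("all", nrow(sub)))
  out <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    denom <- sum(sel)
    cnt <- table(factor(sub$subgroup[sel], levels = sort(family)))
    keyvals <- if (length(by)) strsplit(g, "|", fixed = TRUE)[[1]] else character()
    row <- as.data.frame(as.list(stats::setNames(keyvals, by)),
                         stringsAsFactors = FALSE)
    block <- if (length(by)) row[rep(1L, length(family)), , drop = FALSE]
    else data.frame(row.names = seq_along(family))
    block$subgroup <- sort(family)
    block$n <- as.integer(cnt)
    block$denominator <- denom
    block$percent <- round_half_up(100 * as.integer(cnt) / denom, 2L)
    out[[g]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "denominator") <- paste("cells in family:",
                                    paste(sort(family), collapse = ", "))
  class(res) <- c("composition_table", "data.frame")
  res
}

#' Condition contrast of composition percentages
#'
#' Signed percentage-point differences (TBI minus Sham) per subgroup at
#' each timepoint (and tissue, when present). Descriptive only — no
#' inferential statistics are attached.
#'
#' @param table A `composition_table` whose grouping includes
#'   `condition` (and usually `timepoint`).
#' @return `data.frame` with the non-condition grouping columns,
#'   `subgroup`, `percent_tbi`, `percent_sham`, `delta_pp`.
#' @export
condition_contrast <- function(table) {
  if (!"condition" %in% names(table)) {
    stop("composition table lacks a 'condition' grouping column")
  }
  have <- unique(table$condition)
  missing_lv <- setdiff(VALID_CONDITIONS, have)
  if (length(missing_lv)) {
    stop("missing condition level(s): ", paste(missing_lv, collapse = ", "))
  }
  keys <- setdiff(names(table),
                  c("condition", "n", "denominator", "percent"))
  tbi <- table[table$condition == "TBI", , drop = FALSE]
  sham <- table[table$condition == "Sham", , drop = FALSE]
  kt <- do.call(paste, c(tbi[keys], sep = "|"))
  ks <- do.call(paste, c(sham[keys], sep = "|"))
  common <- intersect(kt, ks)
  tbi <- tbi[match(common, kt), , drop = FALSE]
  sham <- sham[match(common, ks), , drop = FALSE]
  out <- tbi[keys]
  out$percent_tbi <- tbi$percent
  out$percent_sham <- sham$percent
  out$delta_pp <- tbi$percent - sham$percent
  rownames(out) <- NULL
  out
}
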