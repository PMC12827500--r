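# Delta-delta-Ct relative quantification for qPCR plates with a
# reference gene and a control group.

#' Delta-delta-Ct analysis
#'
#' Technical replicates are averaged per (biological replicate, gene);
#' delta-Ct = Ct_target - Ct_reference per biological replicate;
#' delta-delta-Ct of a treated replicate is its delta-Ct minus the mean
#' control delta-Ct; fold change per replicate is `2^-ddCt`. The
#' reported fold change is the mean (with SD) across treated
#' biological replicates on the fold-change scale (log-scale SD by
#' flag). The p-value comes from a two-sided Student's t-test on
#' delta-Ct values (the log-scale measurement, standard practice),
#' with Benjamini-Hochberg adjustment across target genes.
#'
#' @param plate Well table (`qpcr_plate` or `data.frame`) with columns
#'   `group`, `gene`, `bio_rep`, `tech_rep`, `ct`.
#' @param reference_gene Reference (housekeeping) gene.
#' @param control_group Label of the control group.
#' @param log_sd Report SD on the log2 (delta-delta-Ct) scale instead.
#' @return `data.frame` of class `"qpcr_result"`: `gene`,
#'   `fold_change`, `sd`, `p`, `p_adj`, `n_bio`.
#' @export
ddct_analysis <- function(plate, reference_gene = "Gapdh",
                          control_group = "control", log_sd = FALSE) {
  need <- c("group", "gene", "bio_rep", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate lacks column(s): ", paste(miss, collapse = ", "))
  if (any(plate$ct <= 0)) stop("Ct values must be positive")
  groups <- unique(plate$group)
  if (!control_group %in% groups) {
    stop("control group '", control_group, "' not in plate")
  }
  if (length(groups) != 2L) stop("exactly two groups expected")
  treated_group <- setdiff(groups, control_group)

  # average technical replicates
  agg <- stats::aggregate(ct ~ group + gene + bio_rep, data = plate,
                          FUN = mean)
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  targets <- setdiff(unique(agg$gene), reference_gene)
  if (!length(targets)) stop("no target genes on the plate")

  # reference Ct per (group, bio_rep)
  key <- function(g, b) paste(g, b, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref$group, ref$bio_rep))
  all_bio <- unique(agg[c("group", "bio_rep")])
  missing_ref <- !key(all_bio$group, all_bio$bio_rep) %in% names(ref_ct)
  if (any(missing_ref)) {
    bad <- all_bio[missing_ref, , drop = FALSE]
    stop("reference gene missing for replicate(s): ",
         paste(paste(bad$group, bad$bio_rep, sep = "/"), collapse = ", "))
  }

  rows <- list()
  for (gene in targets) {
    sub <- agg[agg$gene == gene, , drop = FALSE]
    sub$dct <- sub$ct - ref_ct[key(sub$group, sub$bio_rep)]
    ctrl <- sub$dct[sub$group == control_group]
    trt <- sub$dct[sub$group == treated_group]
    if (length(ctrl) < 2L || length(trt) < 2L) {
      stop("need >= 2 biological replicates per group for ", gene)
    }
    ddct <- trt - mean(ctrl)
    fc <- 2^(-ddct)
    tt <- student_t(trt, ctrl)
    rows[[gene]] <- data.frame(
      gene = gene,
      fold_change = mean(fc),
      sd = if (log_sd) stats::sd(-ddct) else stats::sd(fc),
      p = tt$p_value, n_bio = length(trt), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  class(res) <- c("qpcr_result", "data.frame")
  res
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("delta-delta-Ct results:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s fold change %.2f +/- %.2f (p = %.4g, BH p = %.4g)\n",
                x$gene[i], x$fold_change[i], x$sd[i], x$p[i], x$p_adj[i]))
  }
  invisible(x)
}
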