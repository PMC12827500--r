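# End-to-end orchestration: simulate -> qc -> composition ->
# trajectory -> enrichment -> lr-screen -> qpcr, as independent stages
# communicating through plain files (TSV / Matrix Market / GMT) so any
# stage can be re-run or tested on its own. A manifest of md5 hashes
# of every output makes determinism checkable: same config + seed,
# same hashes.

#' Default pipeline configuration
#'
#' All stage toggles and parameters in one list. The QC thresholds
#' here are scaled to the synthetic data's shallow depth (a ~200-gene
#' universe); on real 10x data the classic 200/6000/10% settings apply
#' and can be set in the config.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Nested named list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("myelotrace_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, qc = TRUE, composition = TRUE,
                  trajectory = TRUE, enrich = TRUE, lr_screen = TRUE,
                  qpcr = TRUE),
    simulate = list(cells_per_group = 30L, n_genes = 200L),
    qc = list(min_genes = 20L, max_genes = 6000L, max_mito = 0.10,
              n_hvg = 100L, n_pcs = 10L),
    composition = list(families = list(
      blood = c("Ly6c+.Mon", "Treml4+.Mon"),
      cortex = c("MG", "aMG"),
      hippocampus = c("MG", "aMG"))),
    trajectory = list(k_centroids = 25L, root_subgroup = "Ly6c+.Mon",
                      k_gene_subgroups = 6L),
    enrich = list(alpha = 0.05),
    qpcr = list(genes = c("Ccl2", "Tnf", "Grn"),
                fold_changes = c(4.5, 5.1, 3.7),
                reference_gene = "Gapdh", control_group = "control"))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (!nm %in% names(base)) stop("unknown config key: ", nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "families") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order under `out_dir`,
#' writing plain-file artifacts, a resolved-config YAML and a manifest
#' of md5 content hashes. A failing stage aborts with an error naming
#' the stage; a stage whose inputs are missing (e.g. the screen without
#' the trajectory outputs) fails fast.
#'
#' @param config A config list (see [default_pipeline_config()]), a
#'   path to a YAML file of overrides, or `NULL` for defaults.
#' @param seed Optional seed override.
#' @return Invisibly, a list with `status` (0 on success), `out_dir`
#'   and the `manifest` data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config = NULL, seed = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, enabled, fun) {
    if (!enabled) { message("stage ", name, ": skipped"); return(invisible()) }
    message("stage ", name, ": running")
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim_cfg <- default_sim_config(seed = cfg$seed,
                                cells_per_group = cfg$simulate$cells_per_group,
                                n_genes = cfg$simulate$n_genes)

  run_stage("simulate", cfg$stages$simulate, function() {
    res <- generate_atlas(sim_cfg)
    for (tis in sim_cfg$tissues) {
      sub <- subset_atlas(res$atlas,
                          cells = which(res$atlas$cell_meta$tissue == tis))
      write_10x_triplet(sub, file.path(out, "sim", tis))
    }
    traj <- generate_trajectory_data(sim_cfg)
    write_10x_triplet(traj$atlas, file.path(out, "sim", "trajectory"))
    emb <- data.frame(barcode = rownames(traj$embedding),
                      dim1 = traj$embedding[, 1], dim2 = traj$embedding[, 2])
    utils::write.table(emb, file.path(out, "sim", "trajectory",
                                      "embedding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    true_pairs <- list(c("Ccl2", "Ccr2"), c("Ccl7", "Ccr2"),
                       c("Tnf", "Tnfrsf1b"), c("Grn", "Flna"))
    write_ppi(generate_ppi(sim_cfg, true_pairs, n_decoys = 50L),
              file.path(out, "sim", "ppi.tsv"))
    loc <- generate_locations(sim_cfg,
                              secreted = c("Ccl2", "Ccl7", "Tnf", "Grn"),
                              membrane = c("Ccr2", "Tnfrsf1b", "Flna"))
    write_locations(loc, file.path(out, "sim", "locations.tsv"))
    sets <- generate_genesets(sim_cfg, planted = list(
      CHEMOTAXIS_RESPONSE = c("Ccl2", "Ccl7", "Ccr2", "Tnf", "Tnfrsf1b",
                              "Grn", "Flna")))
    write_gmt(sets, file.path(out, "sim", "genesets.gmt"))
    plate <- generate_qpcr(sim_cfg, genes = cfg$qpcr$genes,
                           fold_changes = cfg$qpcr$fold_changes)
    utils::write.table(plate, file.path(out, "sim", "qpcr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  read_tissue <- function(tis) {
    dir <- file.path(out, "sim", tis)
    if (!dir.exists(dir)) stop("missing input: ", dir,
                               " (enable the simulate stage)")
    atlas <- read_10x_triplet(dir)
    read_metadata(file.path(dir, "metadata.tsv"), atlas)
  }

  run_stage("qc", cfg$stages$qc, function() {
    dir.create(file.path(out, "qc"), showWarnings = FALSE)
    for (tis in sim_cfg$tissues) {
      atlas <- read_tissue(tis)
      qc <- compute_cell_qc(atlas)
      utils::write.table(qc, file.path(out, "qc", paste0(tis, "_qc.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      kept <- filter_cells(atlas, qc, min_genes = cfg$qc$min_genes,
                           max_genes = cfg$qc$max_genes,
                           max_mito = cfg$qc$max_mito)
      writeLines(kept$cell_meta$barcode,
                 file.path(out, "qc", paste0(tis, "_retained_barcodes.txt")))
      norm <- log_normalize(kept)
      hvg <- select_variable_genes(kept, n = min(cfg$qc$n_hvg, nrow(norm)))
      emb <- scale_and_pca(norm, hvg, n_pcs = cfg$qc$n_pcs)
      utils::write.table(
        data.frame(barcode = kept$cell_meta$barcode, round(emb, 6)),
        file.path(out, "qc", paste0(tis, "_pca.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  run_stage("composition", cfg$stages$composition, function() {
    dir.create(file.path(out, "composition"), showWarnings = FALSE)
    meta <- do.call(rbind, lapply(sim_cfg$tissues,
                                  function(t) read_tissue(t)$cell_meta))
    tab <- subgroup_proportions(meta, by = c("tissue", "condition",
                                             "timepoint"))
    utils::write.table(tab, file.path(out, "composition", "proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fams <- cfg$composition$families
    for (tis in names(fams)) {
      sub <- meta[meta$tissue == tis, , drop = FALSE]
      fr <- restricted_fractions(sub, fams[[tis]],
                                 by = c("condition", "timepoint"))
      utils::write.table(
        fr, file.path(out, "composition", paste0(tis, "_family.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    contrast <- condition_contrast(tab)
    utils::write.table(contrast,
                       file.path(out, "composition", "contrast.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("trajectory", cfg$stages$trajectory, function() {
    dir.create(file.path(out, "trajectory"), showWarnings = FALSE)
    tdir <- file.path(out, "sim", "trajectory")
    if (!dir.exists(tdir)) stop("missing input: ", tdir,
                                " (enable the simulate stage)")
    atlas <- read_10x_triplet(tdir)
    meta <- utils::read.table(file.path(tdir, "metadata.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    atlas <- read_metadata(meta, atlas)
    emb <- utils::read.table(file.path(tdir, "embedding.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    emb <- as.matrix(emb[match(atlas$cell_meta$barcode, emb$barcode),
                         c("dim1", "dim2")])
    model <- fit_trajectory(emb, atlas$cell_meta$subgroup,
                            k_centroids = cfg$trajectory$k_centroids,
                            root_rule = cfg$trajectory$root_subgroup)
    utils::write.table(
      data.frame(barcode = atlas$cell_meta$barcode,
                 state = model$cell_state,
                 pseudotime = round(model$pseudotime, 6)),
      file.path(out, "trajectory", "states.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    norm <- log_normalize(atlas)
    bg <- branch_dependent_genes(norm, model)
    sub <- cluster_branch_genes(bg, k = cfg$trajectory$k_gene_subgroups)
    # polarity of each gene subgroup: where does its mean profile peak?
    sm <- attr(bg, "state_means")
    peak <- vapply(split(names(sub), sub), function(gs) {
      prof <- rowMeans(scale(sm[, gs, drop = FALSE]))
      which.max(prof)
    }, numeric(1))
    utils::write.table(
      data.frame(gene = names(sub), subgroup = as.integer(sub)),
      file.path(out, "trajectory", "gene_subgroups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(subgroup = as.integer(names(peak)),
                 peak_state = as.integer(peak)),
      file.path(out, "trajectory", "subgroup_peaks.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("enrich", cfg$stages$enrich, function() {
    dir.create(file.path(out, "enrich"), showWarnings = FALSE)
    gs_path <- file.path(out, "sim", "genesets.gmt")
    sub_path <- file.path(out, "trajectory", "gene_subgroups.tsv")
    if (!file.exists(sub_path)) stop("missing input: ", sub_path,
                                     " (enable the trajectory stage)")
    sets <- read_gmt(gs_path)
    subs <- utils::read.table(sub_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    tdir <- file.path(out, "sim", "trajectory")
    atlas <- read_10x_triplet(tdir)
    universe <- atlas$gene_meta$symbol
    res <- do.call(rbind, lapply(sort(unique(subs$subgroup)), function(k) {
      r <- ora(subs$gene[subs$subgroup == k], universe, sets,
               alpha = cfg$enrich$alpha)
      cbind(gene_subgroup = k, r)
    }))
    utils::write.table(res, file.path(out, "enrich", "ora.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # pathway activity in CNS myeloid cells, activated vs resting
    cortex <- read_tissue("cortex")
    mg <- subset_atlas(cortex,
                       cells = which(cortex$cell_meta$subgroup %in%
                                       c("MG", "aMG")))
    norm <- log_normalize(mg)
    log2e <- norm / log(2)
    scores <- gsva_like(as.matrix(log2e), sets)
    act <- compare_activity(scores, mg$cell_meta$subgroup,
                            alpha = cfg$enrich$alpha)
    utils::write.table(act, file.path(out, "enrich", "activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("lr_screen", cfg$stages$lr_screen, function() {
    dir.create(file.path(out, "lr"), showWarnings = FALSE)
    sub_path <- file.path(out, "trajectory", "gene_subgroups.tsv")
    peak_path <- file.path(out, "trajectory", "subgroup_peaks.tsv")
    if (!file.exists(sub_path)) stop("missing input: ", sub_path,
                                     " (enable the trajectory stage)")
    subs <- utils::read.table(sub_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    peaks <- utils::read.table(peak_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    smap <- stats::setNames(subs$subgroup, subs$gene)
    loc <- read_locations(file.path(out, "sim", "locations.tsv"))
    ppi <- read_ppi(file.path(out, "sim", "ppi.tsv"))
    # microglial-state (2/3) subgroups are ligand-eligible, the
    # monocyte/macrophage root state (1) subgroups receptor-eligible
    lig <- peaks$subgroup[peaks$peak_state %in% c(2L, 3L)]
    rec <- peaks$subgroup[peaks$peak_state == 1L]
    screen <- screen_lr_pairs(smap, loc, ppi, ligand_subgroups = lig,
                              receptor_subgroups = rec)
    utils::write.table(screen, file.path(out, "lr", "screen_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(retained_pairs(screen),
                       file.path(out, "lr", "retained_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # differential-expression annotation in each tissue
    stats_all <- list()
    for (tis in sim_cfg$tissues) {
      atlas <- read_tissue(tis)
      norm <- log_normalize(atlas)
      genes <- unique(unlist(retained_pairs(screen)))
      genes <- intersect(genes, rownames(norm))
      if (!length(genes)) next
      keep_sub <- if (tis == "blood") c("Ly6c+.Mon", "Treml4+.Mon")
      else c("MG", "aMG", "MAC")
      stats_all[[tis]] <- lr_expression_stats(norm, atlas$cell_meta, genes,
                                              subgroups = keep_sub)
    }
    utils::write.table(do.call(rbind, stats_all),
                       file.path(out, "lr", "expression_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("qpcr", cfg$stages$qpcr, function() {
    dir.create(file.path(out, "qpcr"), showWarnings = FALSE)
    plate_path <- file.path(out, "sim", "qpcr.tsv")
    if (!file.exists(plate_path)) stop("missing input: ", plate_path)
    plate <- utils::read.table(plate_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    res <- ddct_analysis(plate, reference_gene = cfg$qpcr$reference_gene,
                         control_group = cfg$qpcr$control_group)
    utils::write.table(res, file.path(out, "qpcr", "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  # the config echo records the output path itself and is metadata, not
  # a stage artifact; the manifest tracks stage outputs
  files <- setdiff(files, file.path(out, c("manifest.tsv",
                                           "config_resolved.yaml")))
  manifest <- data.frame(
    file = substring(files, nchar(out) + 2L),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(status = 0L, out_dir = out, manifest = manifest))
}
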