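# Ground-truth data generators emulating the structure of a
# multi-tissue (blood / cortex / hippocampus) TBI single-cell study:
# negative-binomial count atlases with planted markers and
# condition x timepoint effects, interaction and location annotation
# tables, GMT gene-set collections, branch-structured trajectory data
# and delta-delta-Ct qPCR plates. Every generator draws from R's
# default Mersenne-Twister stream, re-seeded per call from the config
# seed plus a fixed per-generator offset, so a fixed seed gives
# bit-identical output regardless of call order.

stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

#' Simulation configuration
#'
#' Bundles the design of the synthetic study: tissues, subgroup cell
#' counts per condition x timepoint, the gene universe, planted marker
#' genes, planted condition effects, and the count model (negative
#' binomial with common dispersion, log-normal library sizes). The
#' defaults, built by [default_sim_config()], encode the study design
#' the package targets: blood, cortex and hippocampus atlases; TBI vs
#' Sham at 24h and 7d; chemokine/cytokine up-regulation (Ccl2, Ccl7,
#' Tnf at 24h and Grn at 7d) in CNS microglia, receptor up-regulation
#' (Ccr2, Tnfrsf1b at 24h, Flna at 7d) in blood monocytes, and an
#' activated-microglia expansion at TBI 24h.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param tissues Character vector of tissue names.
#' @param subgroup_spec `data.frame` with columns `tissue`, `subgroup`,
#'   `condition`, `timepoint`, `n` (cells per group).
#' @param n_genes Number of filler genes in addition to named genes.
#' @param marker_spec `data.frame` with columns `subgroup`, `gene`,
#'   `log2fc`: marker elevation within the subgroup (all tissues).
#' @param condition_effects `data.frame` with columns `gene`, `tissue`,
#'   `subgroup`, `timepoint`, `log2fc`: TBI-vs-Sham effects.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param mito_gene_count Number of mitochondrial (`mt-`) genes.
#' @param baseline_mean Baseline per-gene mean count at library factor 1.
#' @param mice_per_group Biological replicates per condition x timepoint.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       tissues = c("blood", "cortex", "hippocampus"),
                       subgroup_spec,
                       n_genes = 200L,
                       marker_spec = NULL,
                       condition_effects = NULL,
                       nb_dispersion = 0.4,
                       mito_gene_count = 10L,
                       baseline_mean = 0.8,
                       mice_per_group = 3L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  need <- c("tissue", "subgroup", "condition", "timepoint", "n")
  if (!all(need %in% names(subgroup_spec))) {
    stop("subgroup_spec needs columns ", paste(need, collapse = ", "))
  }
  if (any(subgroup_spec$n <= 0)) stop("all cell counts must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  if (!all(subgroup_spec$tissue %in% tissues)) {
    stop("subgroup_spec references unknown tissue(s)")
  }
  cfg <- list(seed = as.integer(seed), tissues = tissues,
              subgroup_spec = subgroup_spec, n_genes = as.integer(n_genes),
              marker_spec = marker_spec, condition_effects = condition_effects,
              nb_dispersion = nb_dispersion,
              mito_gene_count = as.integer(mito_gene_count),
              baseline_mean = baseline_mean,
              mice_per_group = as.integer(mice_per_group))
  class(cfg) <- "sim_config"
  cfg$genes <- build_gene_universe(cfg)
  validate_sim_config(cfg)
  cfg
}

named_study_genes <- function() {
  c("Ccl2", "Ccl7", "Tnf", "Grn", "Ccr2", "Tnfrsf1b", "Flna")
}

build_gene_universe <- function(cfg) {
  named <- named_study_genes()
  if (!is.null(cfg$marker_spec)) named <- union(named, cfg$marker_spec$gene)
  if (!is.null(cfg$condition_effects)) {
    named <- union(named, cfg$condition_effects$gene)
  }
  mito <- if (cfg$mito_gene_count > 0)
    paste0("mt-Sim", seq_len(cfg$mito_gene_count)) else character()
  filler_n <- max(cfg$n_genes - length(named) - length(mito), 0L)
  filler <- sprintf("Gene%04d", seq_len(filler_n))
  c(named, mito, filler)
}

validate_sim_config <- function(cfg) {
  subs <- unique(cfg$subgroup_spec$subgroup)
  if (!is.null(cfg$marker_spec)) {
    bad <- setdiff(cfg$marker_spec$subgroup, subs)
    if (length(bad)) stop("marker_spec references unknown subgroup(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$condition_effects)) {
    ce <- cfg$condition_effects
    need <- c("gene", "tissue", "subgroup", "timepoint", "log2fc")
    if (!all(need %in% names(ce))) {
      stop("condition_effects needs columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(ce$subgroup, subs)
    if (length(bad)) stop("condition_effects references unknown subgroup(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(ce$tissue, cfg$tissues)
    if (length(bad)) stop("condition_effects references unknown tissue(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(ce$timepoint, VALID_TIMEPOINTS)
    if (length(bad)) stop("condition_effects references unknown timepoint(s): ",
                          paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Default synthetic study design
#'
#' A scaled-down rendition of the study the package targets: the full
#' subgroup roster per tissue (8 blood, 13 cortex, 17 hippocampus
#' subgroups), four condition x timepoint groups each, planted marker
#' genes per myeloid subgroup, the chemokine/receptor condition effects
#' described above, and a doubled activated-microglia (and macrophage)
#' compartment at TBI 24h in CNS tissues. Cell numbers per group are a
#' config choice (the original per-mouse counts are not published):
#' `cells_per_group` (default 30) keeps a full three-tissue atlas at
#' around five thousand cells.
#'
#' @param seed Integer seed.
#' @param cells_per_group Baseline cells per subgroup x condition x
#'   timepoint.
#' @param n_genes Gene universe size.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, cells_per_group = 30L,
                               n_genes = 200L) {
  blood_subs <- c("B.cells", "CD4T", "CD8T", "NK.cells", "Ly6c+.Mon",
                  "GRAN", "Treml4+.Mon", "MEGK")
  cortex_subs <- c("NEU", "ASC", "ODC", "END", "aMG", "MG", "OPC",
                   "NeuroG1", "PER", "nODC", "MAC", "SMC", "NeuroG2")
  hippo_subs <- c("ODC", "ASC", "NEU", "END", "aMG", "OPC", "MG", "CPE",
                  "nODC", "MAC", "PER", "SMC", "CR", "NeuroG1", "FB",
                  "NeuroG2", "EPEN")
  grid <- expand.grid(condition = VALID_CONDITIONS,
                      timepoint = VALID_TIMEPOINTS,
                      stringsAsFactors = FALSE)
  spec <- do.call(rbind, lapply(
    list(blood = blood_subs, cortex = cortex_subs, hippocampus = hippo_subs),
    function(subs) {
      do.call(rbind, lapply(subs, function(s) {
        data.frame(subgroup = s, grid, n = cells_per_group,
                   stringsAsFactors = FALSE)
      }))
    }))
  spec$tissue <- rep(c("blood", "cortex", "hippocampus"),
                     times = c(length(blood_subs), length(cortex_subs),
                               length(hippo_subs)) * nrow(grid))
  # planted composition shifts: aMG and MAC expand at TBI 24h in CNS;
  # Treml4+ monocytes expand at TBI 24h in blood
  bump <- with(spec, (subgroup %in% c("aMG", "MAC") &
                        tissue != "blood" |
                        subgroup == "Treml4+.Mon" & tissue == "blood") &
                 condition == "TBI" & timepoint == "24h")
  spec$n[bump] <- spec$n[bump] * 2L

  markers <- data.frame(
    subgroup = rep(c("Ly6c+.Mon", "Treml4+.Mon", "MG", "aMG", "MAC"),
                   each = 3L),
    gene = c("Ly6c2", "Plac8", "Ms4a4c",
             "Treml4", "Ace", "Spn",
             "P2ry12", "Tmem119", "Cx3cr1",
             "Cd68", "Aif1", "Tyrobp",
             "Lyz2", "Mrc1", "Cd163"),
    log2fc = 2.5, stringsAsFactors = FALSE)

  ce <- rbind(
    data.frame(gene = "Ccl2", tissue = "cortex", subgroup = "aMG",
               timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Ccl2", tissue = "hippocampus",
               subgroup = c("MG", "aMG"), timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Ccl7", tissue = "cortex", subgroup = "aMG",
               timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Ccl7", tissue = "hippocampus",
               subgroup = c("MG", "aMG"), timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Tnf", tissue = "cortex", subgroup = "aMG",
               timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Tnf", tissue = "hippocampus",
               subgroup = c("MG", "aMG"), timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Grn", tissue = c("cortex", "cortex",
                                        "hippocampus", "hippocampus"),
               subgroup = c("MG", "aMG", "MG", "aMG"),
               timepoint = "7d", log2fc = 1.2),
    data.frame(gene = "Ccr2", tissue = "blood", subgroup = "Ly6c+.Mon",
               timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Tnfrsf1b", tissue = "blood",
               subgroup = c("Ly6c+.Mon", "Treml4+.Mon"),
               timepoint = "24h", log2fc = 1.5),
    data.frame(gene = "Flna", tissue = "blood",
               subgroup = c("Ly6c+.Mon", "Treml4+.Mon"),
               timepoint = "7d", log2fc = 1.2))

  sim_config(seed = seed, subgroup_spec = spec, n_genes = n_genes,
             marker_spec = markers, condition_effects = ce)
}

#' Generate a synthetic multi-tissue cell atlas
#'
#' Draws negative-binomial counts for every cell defined by the config's
#' `subgroup_spec`. Per-gene baseline means are log-normal around
#' `baseline_mean`; per-cell library factors are log-normal; marker
#' elevations and condition effects act multiplicatively (2^log2fc) on
#' the mean of the affected cells. Mitochondrial genes are named with
#' the mouse `mt-` prefix and given a higher baseline so mito fractions
#' are non-trivial.
#'
#' @param config A `sim_config`.
#' @return A list with `atlas` (a `cell_atlas`) and `truth` (per-cell
#'   labels and the planted `markers` / `condition_effects` tables).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 101L))
  genes <- config$genes
  n_genes <- length(genes)

  spec <- config$subgroup_spec
  cells <- spec[rep(seq_len(nrow(spec)), spec$n), , drop = FALSE]
  n_cells <- nrow(cells)
  grp_key <- paste(cells$tissue, cells$condition, cells$timepoint)
  mouse_no <- stats::ave(seq_len(n_cells), grp_key, FUN = function(i) {
    ((seq_along(i) - 1L) %% config$mice_per_group) + 1L
  })
  cells$mouse <- paste0("m_", gsub(" ", "_", grp_key), "_", mouse_no)
  cells$barcode <- sprintf("%s_c%06d", cells$tissue,
                           stats::ave(seq_len(n_cells), cells$tissue,
                                      FUN = seq_along))
  gene_base <- config$baseline_mean * stats::rlnorm(n_genes, 0, 0.8)
  names(gene_base) <- genes
  # the named study genes (chemokines/receptors the design plants
  # effects in) are robustly expressed in myeloid cells; give them a
  # stable moderate baseline instead of a random draw
  named <- intersect(named_study_genes(), genes)
  gene_base[named] <- config$baseline_mean * 3
  mito <- startsWith(genes, "mt-")
  gene_base[mito] <- gene_base[mito] * 1.5  # mito transcripts are abundant
  lib <- stats::rlnorm(n_cells, 0, 0.3)

  log2mult <- matrix(0, nrow = n_genes, ncol = n_cells,
                     dimnames = list(genes, NULL))
  if (!is.null(config$marker_spec)) {
    for (i in seq_len(nrow(config$marker_spec))) {
      ms <- config$marker_spec[i, ]
      j <- which(cells$subgroup == ms$subgroup)
      log2mult[ms$gene, j] <- log2mult[ms$gene, j] + ms$log2fc
    }
  }
  if (!is.null(config$condition_effects)) {
    for (i in seq_len(nrow(config$condition_effects))) {
      ce <- config$condition_effects[i, ]
      j <- which(cells$tissue == ce$tissue & cells$subgroup == ce$subgroup &
                   cells$timepoint == ce$timepoint & cells$condition == "TBI")
      log2mult[ce$gene, j] <- log2mult[ce$gene, j] + ce$log2fc
    }
  }
  mu <- sweep(2^log2mult * gene_base, 2L, lib, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                  size = 1 / config$nb_dispersion),
                   nrow = n_genes)
  cm <- cells[, c("barcode", "tissue", "subgroup", "condition",
                  "timepoint", "mouse")]
  rownames(cm) <- NULL
  atlas <- cell_atlas(counts,
                      data.frame(symbol = genes, mito = mito,
                                 stringsAsFactors = FALSE),
                      cm)
  truth <- list(cell_subgroup = stats::setNames(cm$subgroup, cm$barcode),
                markers = config$marker_spec,
                condition_effects = config$condition_effects)
  list(atlas = atlas, truth = truth)
}

#' Generate a synthetic protein-protein interaction table
#'
#' All `true_pairs` plus `n_decoys` random undirected decoy edges drawn
#' from `decoy_pool` (by default the gene universe minus the genes in
#' `true_pairs`, so decoy edges cannot recreate a true interaction).
#' Output is deduplicated and canonically ordered.
#'
#' @param config A `sim_config`.
#' @param true_pairs List of length-2 character vectors (or a 2-column
#'   matrix/data.frame) of interacting genes.
#' @param n_decoys Number of decoy edges.
#' @param decoy_pool Genes decoy edges are drawn from.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
generate_ppi <- function(config, true_pairs, n_decoys = 50L,
                         decoy_pool = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 202L))
  tp <- normalize_pairs(true_pairs)
  bad <- setdiff(unique(unlist(tp)), config$genes)
  if (length(bad)) stop("true_pairs reference unknown gene(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(decoy_pool)) decoy_pool <- setdiff(config$genes, unlist(tp))
  edges <- if (length(tp)) {
    data.frame(gene_a = vapply(tp, `[`, "", 1L),
               gene_b = vapply(tp, `[`, "", 2L), stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(), gene_b = character())
  }
  made <- 0L
  while (made < n_decoys) {
    pair <- sample(decoy_pool, 2L)
    key <- paste(min(pair), max(pair))
    have <- paste(pmin(edges$gene_a, edges$gene_b),
                  pmax(edges$gene_a, edges$gene_b))
    if (!key %in% have) {
      edges <- rbind(edges, data.frame(gene_a = pair[1], gene_b = pair[2]))
      made <- made + 1L
    }
  }
  if (!nrow(edges)) return(data.frame(gene_a = character(),
                                      gene_b = character()))
  canonical_edges(edges$gene_a, edges$gene_b)
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.list(pairs) && !length(pairs))) return(list())
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) as.character(unlist(pairs[i, 1:2])))
  }
  unique(lapply(pairs, function(p) as.character(p[1:2])))
}

#' Generate a subcellular-location table
#'
#' Every gene in the universe gets exactly one label: listed genes get
#' `"secreted"` or `"plasma membrane"`, everything else `"other"`. A
#' gene in both lists is a validation error.
#'
#' @param config A `sim_config`.
#' @param secreted,membrane Character vectors of genes.
#' @return Named character vector (gene -> label).
#' @export
generate_locations <- function(config, secreted = character(),
                               membrane = character()) {
  stopifnot(inherits(config, "sim_config"))
  both <- intersect(secreted, membrane)
  if (length(both)) stop("gene(s) listed as both secreted and membrane: ",
                         paste(both, collapse = ", "))
  bad <- setdiff(c(secreted, membrane), config$genes)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  loc <- stats::setNames(rep("other", length(config$genes)), config$genes)
  loc[secreted] <- "secreted"
  loc[membrane] <- "plasma membrane"
  loc
}

#' Generate a gene-set collection
#'
#' Planted sets are kept verbatim; filler sets are drawn uniformly from
#' the gene universe, so under a null query their over-representation
#' p-values are approximately uniform.
#'
#' @param config A `sim_config`.
#' @param planted Named list of character vectors.
#' @param n_filler Number of random filler sets.
#' @param filler_size Size range (length-2) of filler sets.
#' @return Named list of gene sets (GMT-compatible, see [write_gmt()]).
#' @export
generate_genesets <- function(config, planted = list(), n_filler = 20L,
                              filler_size = c(10L, 40L)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 303L))
  bad <- setdiff(unique(unlist(planted)), config$genes)
  if (length(bad)) stop("planted sets reference unknown gene(s): ",
                        paste(bad, collapse = ", "))
  sets <- lapply(planted, unique)
  for (i in seq_len(n_filler)) {
    sz <- sample(seq(filler_size[1], filler_size[2]), 1L)
    sets[[sprintf("FILLER_%03d", i)]] <- sample(config$genes, sz)
  }
  attr(sets, "description") <- stats::setNames(
    rep("synthetic", length(sets)), names(sets))
  sets
}

#' Generate a synthetic qPCR plate
#'
#' Emulates the validation design: a control and a treated group with
#' `n_bio` biological replicates each, measured in `n_tech` technical
#' replicates, one reference gene (`Gapdh`) plus the target genes. The
#' treated group's target Ct is shifted by `-log2(fold_change)`;
#' Gaussian noise with sd `ct_sd` is added per well; a per-sample
#' random intercept (shared by reference and targets, so it cancels in
#' the delta-Ct) mimics loading variation.
#'
#' @param config A `sim_config` (only its seed is used) or an integer
#'   seed.
#' @param genes Character vector of target genes.
#' @param fold_changes Positive reals, aligned with `genes`.
#' @param n_bio,n_tech Biological / technical replicates.
#' @param ct_sd Per-well Ct noise sd (cycles).
#' @param reference_gene Reference gene name.
#' @return `data.frame` of wells of class `"qpcr_plate"`: `sample`,
#'   `group`, `gene`, `bio_rep`, `tech_rep`, `ct`.
#' @export
generate_qpcr <- function(config, genes, fold_changes, n_bio = 3L,
                          n_tech = 3L, ct_sd = 0.2,
                          reference_gene = "Gapdh") {
  seed <- if (inherits(config, "sim_config")) config$seed else as.integer(config)
  set.seed(stream_seed(seed, 404L))
  if (length(genes) != length(fold_changes)) {
    stop("fold_changes must align with genes")
  }
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  base_ct <- stats::setNames(stats::runif(length(genes), 22, 26), genes)
  ref_ct <- 18
  rows <- list()
  for (group in c("control", "treated")) {
    for (b in seq_len(n_bio)) {
      sample_id <- paste0(group, "_b", b)
      samp_eff <- stats::rnorm(1, 0, 0.3)  # cancels in delta-Ct
      for (gene in c(reference_gene, genes)) {
        shift <- if (gene != reference_gene && group == "treated")
          -log2(fold_changes[match(gene, genes)]) else 0
        mu <- if (gene == reference_gene) ref_ct else base_ct[gene]
        for (tch in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, group = group, gene = gene,
            bio_rep = b, tech_rep = tch,
            ct = mu + samp_eff + shift + stats::rnorm(1, 0, ct_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  plate <- do.call(rbind, rows)
  class(plate) <- c("qpcr_plate", "data.frame")
  attr(plate, "reference_gene") <- reference_gene
  plate
}

#' Generate branch-structured trajectory data
#'
#' Places cells along the segments of a rooted tree in a 2-D latent
#' space (uniform position along each segment plus isotropic Gaussian
#' noise) and draws negative-binomial expression in which each branch
#' program's genes are elevated (2^log2fc) on the states where the
#' program is active. Cells on the root-incident segment carry the
#' monocyte label so root inference by subgroup composition is
#' testable.
#'
#' @param config A `sim_config` (seed, dispersion and baseline are
#'   reused).
#' @param branch_spec List with `nodes` (`data.frame`: `id`, `x`, `y`),
#'   `edges` (`data.frame`: `from`, `to`; must form a tree), `root`
#'   (node id), `cells_per_branch`, `noise_sd`, `labels` (per-edge
#'   subgroup label), and `programs` (`data.frame`: `gene`, `log2fc`,
#'   plus one logical column per state `state<k>` saying where the
#'   program is active). See [default_branch_spec()].
#' @return List with `atlas` (a `cell_atlas` whose cell metadata has
#'   the true `state`), `embedding` (cells x 2 latent coordinates) and
#'   `truth` (true state, true pseudotime, program table).
#' @export
generate_trajectory_data <- function(config, branch_spec = default_branch_spec()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 505L))
  nodes <- branch_spec$nodes
  edges <- branch_spec$edges
  if (nrow(edges) != nrow(nodes) - 1L) stop("branch_spec edges must form a tree")
  root <- branch_spec$root
  if (!root %in% nodes$id) stop("root node not in branch_spec nodes")
  ncell <- branch_spec$cells_per_branch
  noise_sd <- branch_spec$noise_sd %||% 0.3

  # geodesic node depth from root (edge weights = Euclidean length)
  coord <- as.matrix(nodes[, c("x", "y")])
  rownames(coord) <- nodes$id
  adj <- lapply(stats::setNames(nodes$id, nodes$id), function(i) {
    c(edges$to[edges$from == i], edges$from[edges$to == i])
  })
  depth <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  depth[root] <- 0
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + sqrt(sum((coord[u, ] - coord[v, ])^2))
        queue <- c(queue, v)
      }
    }
  }
  if (anyNA(depth)) stop("branch_spec tree is disconnected")

  cell_rows <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]
    # orient each segment away from the root
    if (depth[a] > depth[b]) { tmp <- a; a <- b; b <- tmp }
    t <- stats::runif(ncell)
    pos <- coord[rep(a, ncell), , drop = FALSE] +
      t * (coord[rep(b, ncell), , drop = FALSE] - coord[rep(a, ncell), , drop = FALSE])
    pos <- pos + matrix(stats::rnorm(2 * ncell, 0, noise_sd), ncol = 2)
    seg_len <- sqrt(sum((coord[a, ] - coord[b, ])^2))
    cell_rows[[e]] <- data.frame(
      x = pos[, 1], y = pos[, 2], state = e,
      subgroup = branch_spec$labels[e],
      pseudotime = depth[a] + t * seg_len, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  n_cells <- nrow(cells)
  cells$barcode <- sprintf("traj_c%05d", seq_len(n_cells))

  prog <- branch_spec$programs
  genes <- union(config$genes, prog$gene)
  gene_base <- config$baseline_mean * stats::rlnorm(length(genes), 0, 0.5)
  names(gene_base) <- genes
  log2mult <- matrix(0, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, NULL))
  if (!is.null(prog)) {
    state_cols <- grep("^state", names(prog), value = TRUE)
    for (i in seq_len(nrow(prog))) {
      active <- as.integer(sub("state", "", state_cols))[
        unlist(prog[i, state_cols])]
      j <- which(cells$state %in% active)
      log2mult[prog$gene[i], j] <- log2mult[prog$gene[i], j] + prog$log2fc[i]
    }
  }
  lib <- stats::rlnorm(n_cells, 0, 0.2)
  mu <- sweep(2^log2mult * gene_base, 2L, lib, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                  size = 1 / config$nb_dispersion),
                   nrow = length(genes))
  cm <- data.frame(barcode = cells$barcode, tissue = "blood",
                   subgroup = cells$subgroup, condition = "TBI",
                   timepoint = "24h", mouse = "m1", state = cells$state,
                   stringsAsFactors = FALSE)
  atlas <- cell_atlas(counts,
                      data.frame(symbol = genes,
                                 mito = startsWith(genes, "mt-"),
                                 stringsAsFactors = FALSE),
                      cm)
  emb <- as.matrix(cells[, c("x", "y")])
  rownames(emb) <- cells$barcode
  list(atlas = atlas, embedding = emb,
       truth = list(state = stats::setNames(cells$state, cells$barcode),
                    pseudotime = stats::setNames(cells$pseudotime,
                                                 cells$barcode),
                    programs = prog))
}

#' Default three-branch trajectory design
#'
#' A Y-shaped tree: a root segment carrying monocytes (state 1) that
#' splits into an activated-microglia branch (state 2) and a microglia
#' branch (state 3), mirroring the three-state trajectory the package's
#' trajectory model is designed to recover. Six gene programs of
#' `genes_per_program` genes each are planted with distinct activity
#' patterns across the three states.
#'
#' @param cells_per_branch Cells per segment.
#' @param genes_per_program Genes per planted program.
#' @param log2fc Planted elevation of program genes on active states.
#' @param noise_sd Latent-space noise sd.
#' @return A branch spec list for [generate_trajectory_data()].
#' @export
default_branch_spec <- function(cells_per_branch = 150L,
                                genes_per_program = 15L, log2fc = 2,
                                noise_sd = 0.3) {
  nodes <- data.frame(id = c("A", "B", "C", "D"),
                      x = c(0, 5, 10, 10), y = c(0, 0, 4, -4))
  edges <- data.frame(from = c("A", "B", "B"), to = c("B", "C", "D"))
  # activity patterns across states 1..3, one per program, chosen to be
  # pairwise distinct so six separable profile clusters exist
  pat <- rbind(c(FALSE, TRUE, TRUE),   # shared microglial
               c(FALSE, TRUE, FALSE),  # activated microglia only
               c(FALSE, FALSE, TRUE),  # microglia only
               c(TRUE, FALSE, FALSE),  # monocyte/root only
               c(TRUE, TRUE, FALSE),   # root + activated
               c(TRUE, FALSE, TRUE))   # root + microglia
  progs <- do.call(rbind, lapply(1:6, function(k) {
    data.frame(gene = sprintf("Prog%d_%02d", k, seq_len(genes_per_program)),
               program = k, log2fc = log2fc,
               state1 = pat[k, 1], state2 = pat[k, 2], state3 = pat[k, 3],
               stringsAsFactors = FALSE)
  }))
  # the study's ligands ride the microglial programs, the receptors the
  # monocyte/root program, so the downstream screen sees them as branch
  # genes with the expected polarity
  named <- data.frame(
    gene = c("Ccl2", "Ccl7", "Grn", "Tnf", "Ccr2", "Tnfrsf1b", "Flna"),
    program = c(1L, 1L, 1L, 2L, 4L, 4L, 4L), log2fc = log2fc,
    stringsAsFactors = FALSE)
  named <- cbind(named, pat[named$program, , drop = FALSE] |>
                   `colnames<-`(c("state1", "state2", "state3")))
  progs <- rbind(progs, named)
  list(nodes = nodes, edges = edges, root = "A",
       cells_per_branch = cells_per_branch, noise_sd = noise_sd,
       labels = c("Ly6c+.Mon", "aMG", "MG"), programs = progs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
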