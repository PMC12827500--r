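# Independent oracles used to cross-check the package implementation:
# exhaustive hypergeometric enumeration, exhaustive spanning-tree
# search via Pruefer sequences, permutation-matched cluster accuracy.

# P(overlap >= k) by enumerating every possible query draw of size q
# from the universe and counting how many intersect the set in >= k
# genes. Exact and completely independent of any distribution function.
enum_ora_p <- function(universe, set, query) {
  set <- intersect(set, universe)
  k <- length(intersect(set, query))
  q <- length(query)
  draws <- utils::combn(length(universe), q)
  in_set <- universe %in% set
  hits <- colSums(matrix(in_set[draws], nrow = q))
  mean(hits >= k)
}

# Decode a Pruefer sequence (values in 1..n, length n-2) to the edge
# list of the labeled tree it encodes.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# Minimum spanning-tree weight by brute force over all n^(n-2) labeled
# trees (Cayley's formula), n <= 6.
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], n)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# Accuracy of a clustering against truth under the best one-to-one
# label permutation (predicted label count must be small).
matched_accuracy <- function(pred, truth) {
  pl <- sort(unique(pred))
  tl <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  stopifnot(length(pl) <= 6L)
  labs <- union(pl, tl)
  best <- 0
  for (perm in perms(seq_along(labs))) {
    mapped <- labs[perm][match(pred, labs)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# Brute-force evaluation of the five-predicate ligand-receptor screen
# over all ordered pairs, written independently of screen_lr_pairs().
brute_lr_screen <- function(subgroups, locations, ppi,
                            lig = c(1, 2, 3, 6), rec = c(4, 5)) {
  genes <- names(subgroups)
  keep <- list()
  edge_key <- paste(pmin(ppi$gene_a, ppi$gene_b),
                    pmax(ppi$gene_a, ppi$gene_b))
  for (a in genes) {
    for (b in genes) {
      if (a == b) next
      ok <- subgroups[[a]] %in% lig &&
        identical(unname(locations[a]), "secreted") &&
        subgroups[[b]] %in% rec &&
        identical(unname(locations[b]), "plasma membrane") &&
        paste(min(a, b), max(a, b)) %in% edge_key
      if (ok) keep[[length(keep) + 1L]] <- c(a, b)
    }
  }
  if (!length(keep)) return(character())
  sort(vapply(keep, paste, "", collapse = "->"))
}

# A randomized screen fixture: genes with random subgroups, locations
# and edges (no structure guaranteed) for oracle-equivalence checks.
random_lr_fixture <- function(seed, n_genes = 25L, n_edges = 40L) {
  set.seed(seed)
  genes <- sprintf("rg%02d", seq_len(n_genes))
  subgroups <- stats::setNames(sample(1:6, n_genes, replace = TRUE), genes)
  locations <- stats::setNames(
    sample(c("secreted", "plasma membrane", "other"), n_genes,
           replace = TRUE), genes)
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  ok <- a != b
  ppi <- unique(data.frame(gene_a = pmin(a[ok], b[ok]),
                           gene_b = pmax(a[ok], b[ok]),
                           stringsAsFactors = FALSE))
  list(subgroups = subgroups, locations = locations, ppi = ppi)
}

# The screen fixture encoding the study configuration: four true
# ligand-receptor pairs with eligible subgroups/locations plus decoys
# engineered to fail exactly one criterion each.
study_lr_fixture <- function(seed = 1, n_decoys_per_criterion = 10L) {
  set.seed(seed)
  base_sub <- c(Ccl2 = 1L, Ccl7 = 2L, Tnf = 3L, Grn = 6L,
                Ccr2 = 4L, Tnfrsf1b = 5L, Flna = 4L)
  base_loc <- c(Ccl2 = "secreted", Ccl7 = "secreted", Tnf = "secreted",
                Grn = "secreted", Ccr2 = "plasma membrane",
                Tnfrsf1b = "plasma membrane", Flna = "plasma membrane")
  edges <- data.frame(gene_a = c("Ccl2", "Ccl7", "Tnf", "Grn"),
                      gene_b = c("Ccr2", "Ccr2", "Tnfrsf1b", "Flna"),
                      stringsAsFactors = FALSE)
  n <- n_decoys_per_criterion
  subs <- base_sub
  locs <- base_loc
  # each decoy ligand-receptor candidate fails exactly one criterion
  for (i in seq_len(n)) {
    # fails (1): ligand in a receptor subgroup, everything else fine
    l <- sprintf("d1L%02d", i); r <- sprintf("d1R%02d", i)
    subs[c(l, r)] <- c(4L, 5L)
    locs[c(l, r)] <- c("secreted", "plasma membrane")
    edges <- rbind(edges, data.frame(gene_a = l, gene_b = r))
    # fails (2): ligand not secreted
    l <- sprintf("d2L%02d", i); r <- sprintf("d2R%02d", i)
    subs[c(l, r)] <- c(1L, 4L)
    locs[c(l, r)] <- c("other", "plasma membrane")
    edges <- rbind(edges, data.frame(gene_a = l, gene_b = r))
    # fails (3): receptor in a ligand subgroup
    l <- sprintf("d3L%02d", i); r <- sprintf("d3R%02d", i)
    subs[c(l, r)] <- c(2L, 6L)
    locs[c(l, r)] <- c("secreted", "plasma membrane")
    edges <- rbind(edges, data.frame(gene_a = l, gene_b = r))
    # fails (4): receptor not on the membrane
    l <- sprintf("d4L%02d", i); r <- sprintf("d4R%02d", i)
    subs[c(l, r)] <- c(3L, 5L)
    locs[c(l, r)] <- c("secreted", "other")
    edges <- rbind(edges, data.frame(gene_a = l, gene_b = r))
    # fails (5): fully eligible pair with no interaction record
    l <- sprintf("d5L%02d", i); r <- sprintf("d5R%02d", i)
    subs[c(l, r)] <- c(1L, 5L)
    locs[c(l, r)] <- c("secreted", "plasma membrane")
  }
  list(subgroups = subs, locations = locs,
       ppi = canonical_ppi(edges))
}

canonical_ppi <- function(edges) {
  df <- unique(data.frame(gene_a = pmin(edges$gene_a, edges$gene_b),
                          gene_b = pmax(edges$gene_a, edges$gene_b),
                          stringsAsFactors = FALSE))
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

# Small default-design config kept cheap for unit tests.
tiny_config <- function(seed = 1, cells = 20L, n_genes = 120L) {
  default_sim_config(seed = seed, cells_per_group = cells,
                     n_genes = n_genes)
}

# A labeled linear two-segment branch spec (no branch point -> one
# state), with the monocyte label on the root half so the root is
# identifiable.
linear_branch_spec <- function(cells = 150L) {
  list(nodes = data.frame(id = c("A", "B", "C"),
                          x = c(0, 5, 10), y = c(0, 0, 0)),
       edges = data.frame(from = c("A", "B"), to = c("B", "C")),
       root = "A", cells_per_branch = cells, noise_sd = 0.3,
       labels = c("Ly6c+.Mon", "aMG"), programs = NULL)
}

# Half-up rounding to 2 decimals, written directly from the definition.
round_half_up_oracle <- function(x) floor(x * 100 + 0.5) / 100
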