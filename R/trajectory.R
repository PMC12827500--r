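# Simplified branching-pseudotime model: k-means centroids on a 2-D
# embedding, a minimum spanning tree over the centroids, root selection
# by subgroup composition, states as maximal unbranched tree segments,
# and pseudotime as geodesic distance along the tree. This is a
# deliberate surrogate for reversed-graph-embedding trajectory tools:
# it preserves the observable contract (states, root, pseudotime
# ordering, branch-dependent genes) with a transparent algorithm.

# Prim's algorithm on a symmetric distance matrix; returns the edge
# list (i < j) of the minimum spanning tree. Verified in the tests
# against exhaustive enumeration of all spanning trees and igraph.
mst_edges <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(data.frame(from = integer(), to = integer(),
                                 weight = numeric()))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_dist <- d[1L, ]
  best_from <- rep(1L, n)
  edges <- data.frame(from = integer(n - 1L), to = integer(n - 1L),
                      weight = numeric(n - 1L))
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_dist[cand])]
    edges$from[k] <- min(best_from[j], j)
    edges$to[k] <- max(best_from[j], j)
    edges$weight[k] <- best_dist[j]
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best_dist
    best_dist[upd] <- d[j, upd]
    best_from[upd] <- j
  }
  edges
}

#' Fit a branching-pseudotime trajectory
#'
#' Clusters the embedding into `k_centroids` k-means centroids (fixed
#' internal seed), joins the centroids by a Euclidean minimum spanning
#' tree, picks as root the degree-1 tree node whose assigned cells are
#' richest in the `root_rule` subgroup (ties broken by lower centroid
#' id), cuts the tree into states at branch points (nodes of degree
#' >= 3), and assigns each cell a pseudotime: the geodesic tree
#' distance from the root to the cell's orthogonal projection onto the
#' nearest centroid's incident edge, clamped to the edge.
#'
#' Short pendant segments of the centroid tree (noise spurs produced by
#' over-clustering) are pruned before states are cut: any leaf-to-branch
#' path with at most `min_spur_centroids` centroids is removed and its
#' cells are reassigned to the nearest surviving centroid, iterating
#' until no such spur remains. Pruning never removes the root-richest
#' leaf.
#'
#' @param embedding Cells-by-2 (or more) numeric matrix.
#' @param subgroups Per-cell subgroup labels (same order as rows).
#' @param k_centroids Number of k-means centroids.
#' @param root_rule Subgroup name anchoring the root.
#' @param seed Seed for the k-means initialization.
#' @param min_spur_centroids Pendant segments with up to this many
#'   centroids are treated as noise spurs (0 disables pruning).
#' @return An object of class `"trajectory_model"`.
#' @export
fit_trajectory <- function(embedding, subgroups, k_centroids = 25L,
                           root_rule, seed = 42L, min_spur_centroids = 2L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(subgroups) != n) stop("subgroups must match embedding rows")
  if (n < k_centroids) stop("fewer cells than centroids")
  if (all(apply(embedding, 2L, function(col) length(unique(col)) == 1L))) {
    stop("degenerate embedding: all points identical")
  }
  if (!root_rule %in% subgroups) {
    stop("root_rule subgroup '", root_rule, "' not present")
  }
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k_centroids, nstart = 10L,
                      iter.max = 100L)
  centroids <- km$centers
  assign <- km$cluster

  build_tree <- function(centroids) {
    d <- as.matrix(stats::dist(centroids))
    edges <- mst_edges(d)
    k <- nrow(centroids)
    adj <- vector("list", k)
    for (e in seq_len(nrow(edges))) {
      adj[[edges$from[e]]] <- c(adj[[edges$from[e]]], edges$to[e])
      adj[[edges$to[e]]] <- c(adj[[edges$to[e]]], edges$from[e])
    }
    list(d = d, edges = edges, adj = adj, degree = lengths(adj))
  }

  # root = leaf richest in the root subgroup; ties (e.g. two leaves of
  # pure monocytes) go to the leaf holding more root-subgroup cells,
  # then to the lower centroid id
  root_leaf <- function(adj, degree, assign, subgroups) {
    leaves <- which(degree == 1L)
    frac <- vapply(leaves, function(v) {
      cells <- assign == v
      if (!any(cells)) return(0)
      mean(subgroups[cells] == root_rule)
    }, numeric(1))
    nroot <- vapply(leaves, function(v) {
      sum(subgroups[assign == v] == root_rule)
    }, numeric(1))
    leaves[order(-frac, -nroot, leaves)][1L]
  }

  tree <- build_tree(centroids)
  if (min_spur_centroids > 0L && nrow(centroids) > 2L) {
    repeat {
      anchor <- root_leaf(tree$adj, tree$degree, assign, subgroups)
      drop <- NULL
      for (leaf in which(tree$degree == 1L)) {
        if (leaf == anchor) next
        path <- leaf
        v <- leaf
        while (tree$degree[v] <= 2L) {
          nxt <- setdiff(tree$adj[[v]], path)
          if (!length(nxt)) break
          v <- nxt[1L]
          if (tree$degree[v] >= 3L) break
          path <- c(path, v)
        }
        if (tree$degree[v] >= 3L && length(path) <= min_spur_centroids) {
          drop <- path
          break
        }
      }
      if (is.null(drop)) break
      keep <- setdiff(seq_len(nrow(centroids)), drop)
      centroids <- centroids[keep, , drop = FALSE]
      relocate <- assign %in% drop
      if (any(relocate)) {
        d2 <- as.matrix(stats::dist(rbind(embedding[relocate, , drop = FALSE],
                                          centroids)))
        nr <- sum(relocate)
        near <- apply(d2[seq_len(nr), nr + seq_len(nrow(centroids)),
                         drop = FALSE], 1L, which.min)
        newassign <- match(assign, keep)
        newassign[relocate] <- near
        assign <- newassign
      } else {
        assign <- match(assign, keep)
      }
      tree <- build_tree(centroids)
      if (nrow(centroids) <= 2L) break
    }
  }
  d <- tree$d
  edges <- tree$edges
  adj <- tree$adj
  degree <- tree$degree
  k <- nrow(centroids)

  root <- root_leaf(adj, degree, assign, subgroups)

  # geodesic depth + parent via BFS from root
  depth <- rep(NA_real_, k)
  parent <- rep(NA_integer_, k)
  depth[root] <- 0
  queue <- root
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + d[u, v]
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  if (anyNA(depth)) stop("spanning tree is disconnected")

  # states: maximal unbranched segments; an edge inherits its parent
  # edge's state unless the parent node is a branch point
  state_of_node <- rep(NA_integer_, k)
  state_of_node[root] <- 1L
  next_state <- 1L
  queue <- root
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    children <- adj[[u]][is.na(state_of_node[adj[[u]]])]
    for (v in children) {
      if (degree[u] >= 3L && u != root) {
        next_state <- next_state + 1L
        state_of_node[v] <- next_state
      } else if (u == root && match(v, children) > 1L) {
        next_state <- next_state + 1L
        state_of_node[v] <- next_state
      } else {
        state_of_node[v] <- state_of_node[u]
      }
      queue <- c(queue, v)
    }
  }

  # cell pseudotime: project onto the incident edges of its centroid
  pseudotime <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- assign[i]
    nb <- adj[[c0]]
    best <- Inf; best_pt <- depth[c0]
    for (v in nb) {
      a <- centroids[c0, ]; b <- centroids[v, ]
      ab <- b - a
      len2 <- sum(ab^2)
      alpha <- if (len2 > 0) sum((embedding[i, ] - a) * ab) / len2 else 0
      alpha <- min(max(alpha, 0), 1)
      proj <- a + alpha * ab
      dist2 <- sum((embedding[i, ] - proj)^2)
      if (dist2 < best) {
        best <- dist2
        # walk from the endpoint nearer the root
        if (depth[c0] <= depth[v]) {
          best_pt <- depth[c0] + alpha * sqrt(len2)
        } else {
          best_pt <- depth[v] + (1 - alpha) * sqrt(len2)
        }
      }
    }
    pseudotime[i] <- best_pt
  }

  model <- list(embedding = embedding, centroids = centroids,
                edges = edges, root = root,
                centroid_state = state_of_node,
                cell_centroid = assign,
                cell_state = state_of_node[assign],
                pseudotime = pseudotime,
                branch_points = which(degree >= 3L),
                n_states = max(state_of_node),
                subgroups = subgroups, root_rule = root_rule,
                k_centroids = k_centroids)
  class(model) <- "trajectory_model"
  model
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("trajectory_model: %d cells, %d centroids, %d state(s), %d branch point(s)\n",
              nrow(x$embedding), nrow(x$centroids), x$n_states,
              length(x$branch_points)))
  cat(sprintf("  root centroid %d (anchored on '%s'); pseudotime range [%.2f, %.2f]\n",
              x$root, x$root_rule, min(x$pseudotime), max(x$pseudotime)))
  invisible(x)
}

#' @export
summary.trajectory_model <- function(object, ...) {
  tab <- table(state = object$cell_state)
  cat("Cells per state:\n")
  print(tab)
  cat("\nMean pseudotime per state:\n")
  print(round(tapply(object$pseudotime, object$cell_state, mean), 3))
  invisible(list(cells_per_state = tab))
}

#' @export
plot.trajectory_model <- function(x, ...) {
  plot(x$embedding[, 1:2], col = x$cell_state, pch = 16, cex = 0.5,
       xlab = "dim 1", ylab = "dim 2", main = "trajectory states", ...)
  segments(x$centroids[x$edges$from, 1], x$centroids[x$edges$from, 2],
           x$centroids[x$edges$to, 1], x$centroids[x$edges$to, 2], lwd = 2)
  points(x$centroids, pch = 21, bg = "white")
  points(x$centroids[x$root, 1], x$centroids[x$root, 2], pch = 8, cex = 2)
  invisible(x)
}

#' Branch-dependent gene detection
#'
#' One-way equal-variance ANOVA of normalized expression across
#' trajectory states, per gene, with Benjamini-Hochberg adjustment;
#' a gene is branch-dependent at adjusted p < `alpha`.
#'
#' @param norm Normalized genes-by-cells matrix (cells in the order of
#'   the model's embedding).
#' @param model A `trajectory_model` with >= 2 states.
#' @param alpha Adjusted-p significance cutoff.
#' @return `data.frame` of class `"branch_gene_result"`: `gene`, `f`,
#'   `p`, `p_adj`, `significant`, plus the states-by-gene mean profile
#'   in the `"state_means"` attribute.
#' @export
branch_dependent_genes <- function(norm, model, alpha = 0.05) {
  stopifnot(inherits(model, "trajectory_model"))
  if (model$n_states < 2L) stop("branch test needs >= 2 states")
  if (ncol(norm) != length(model$cell_state)) {
    stop("matrix columns must match the model's cells")
  }
  an <- row_anova(norm, model$cell_state)
  res <- data.frame(gene = rownames(norm), f = an$statistic, p = an$p_value,
                    stringsAsFactors = FALSE)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  sm <- t(an$group_means)                   # states x genes
  colnames(sm) <- rownames(norm)
  rownames(sm) <- paste0("state", sort(unique(model$cell_state)))
  attr(res, "state_means") <- sm
  class(res) <- c("branch_gene_result", "data.frame")
  res
}

#' Cluster branch-dependent genes into expression subgroups
#'
#' Hierarchically clusters (Ward linkage on Euclidean distance) the
#' row-standardized state-mean profiles of the significant genes and
#' cuts at `k` subgroups. Subgroup ids are renumbered in dendrogram
#' order so the labeling is deterministic and invariant to input gene
#' order.
#'
#' @param result A `branch_gene_result`.
#' @param k Number of gene subgroups (default 6).
#' @return Named integer vector mapping gene to subgroup `1..k`.
#' @export
cluster_branch_genes <- function(result, k = 6L) {
  stopifnot(inherits(result, "branch_gene_result"))
  sig <- result$gene[result$significant]
  if (length(sig) < k) {
    stop(length(sig), " significant gene(s) but k = ", k,
         "; use a smaller k")
  }
  prof <- t(attr(result, "state_means")[, sig, drop = FALSE])  # genes x states
  prof <- prof[order(rownames(prof)), , drop = FALSE]          # order-invariant
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (prof - mu) / sdv
  if (k == 1L) {
    return(stats::setNames(rep(1L, nrow(z)), rownames(z)))
  }
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance in dendrogram order
  first <- raw[hc$order]
  mapping <- stats::setNames(seq_len(k), unique(first))
  out <- mapping[as.character(raw)]
  stats::setNames(as.integer(out), names(raw))
}
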