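# Density-based clustering with noise, in the HDBSCAN style: mutual
# reachability distances from k-nearest-neighbor core distances, a minimum
# spanning tree, single-linkage condensation with a minimum cluster size,
# and excess-of-mass cluster extraction. Points never absorbed into a
# stable cluster are labelled noise (-1).

prim_mst <- function(d) {
  n <- nrow(d)
  in_tree <- logical(n)
  best <- rep(Inf, n)
  parent <- integer(n)
  best[1] <- 0
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n)) {
    u <- which.min(replace(best, in_tree, Inf))
    in_tree[u] <- TRUE
    if (k > 1L) edges[k - 1L, ] <- c(parent[u], u, best[u])
    upd <- !in_tree & d[u, ] < best
    best[upd] <- d[u, upd]
    parent[upd] <- u
  }
  edges
}

collect_leaves <- function(left, right, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, left[v - n], right[v - n])
  }
  out
}

#' Density-based clustering of a similarity or distance matrix
#'
#' Clusters the rows of a square symmetric matrix, labelling points that do
#' not belong to any sufficiently dense, persistent group as noise (-1).
#' The algorithm follows the HDBSCAN recipe: core distance of each point is
#' its distance to the `min_samples`-th nearest neighbour (self included);
#' pairwise distances are lifted to mutual reachability; the single-linkage
#' hierarchy over the minimum spanning tree is condensed with
#' `min_cluster_size`; clusters are selected by excess-of-mass stability
#' (the all-points root is never selected).
#'
#' @param x Square symmetric matrix. With `input = "similarity"` (e.g. a
#'   Pearson similarity matrix) it is converted to distance `1 - x`; with
#'   `"distance"` it is used as is.
#' @param min_cluster_size Smallest group size reported as a cluster
#'   (default 5; must be at least 2).
#' @param min_samples Neighbour count for core distances (defaults to
#'   `min_cluster_size`).
#' @param input `"similarity"` or `"distance"`.
#' @return Integer vector of labels parallel to the rows: -1 for noise,
#'   1..k for clusters. Cluster count, noise fraction and parameters are
#'   recorded in the `provenance` attribute.
#' @export
cluster_hdbscan <- function(x, min_cluster_size = 5L, min_samples = NULL,
                            input = c("similarity", "distance")) {
  input <- match.arg(input)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 rows to cluster")
  if (ncol(x) != n) stop("input must be a square matrix")
  if (max(abs(x - t(x))) > 1e-8) stop("input must be symmetric")
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(min_samples, n)
  d <- if (input == "similarity") 1 - x else x
  diag(d) <- 0
  core <- apply(d, 1, function(r) sort(r)[min_samples])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  edges <- prim_mst(mr)
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1
  uf_parent <- seq_len(2L * n - 1L)
  uf_find <- function(i) {
    while (uf_parent[i] != i) i <- uf_parent[i]
    i
  }
  left <- integer(n - 1L); right <- integer(n - 1L)
  ndist <- numeric(n - 1L); nsize <- integer(2L * n - 1L)
  nsize[seq_len(n)] <- 1L
  for (k in seq_len(n - 1L)) {
    ru <- uf_find(edges[k, 1]); rv <- uf_find(edges[k, 2])
    node <- n + k
    left[k] <- ru; right[k] <- rv
    ndist[k] <- edges[k, 3]
    nsize[node] <- nsize[ru] + nsize[rv]
    uf_parent[ru] <- node; uf_parent[rv] <- node
  }
  root <- 2L * n - 1L

  # condense the hierarchy
  n_clusters <- 1L
  cl_parent <- c(0L)   # cluster tree parent pointers
  cl_birth <- c(0)     # lambda at which each cluster appears
  pt_cluster <- integer(0); pt_id <- integer(0); pt_lambda <- numeric(0)
  stack_node <- root; stack_cl <- 1L
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]; cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    k <- v - n
    lam <- 1 / max(ndist[k], 1e-12)
    l <- left[k]; r <- right[k]
    sl <- nsize[l]; sr <- nsize[r]
    if (sl >= min_cluster_size && sr >= min_cluster_size) {
      for (child in c(l, r)) {
        n_clusters <- n_clusters + 1L
        cl_parent <- c(cl_parent, cl)
        cl_birth <- c(cl_birth, lam)
        stack_node <- c(stack_node, child)
        stack_cl <- c(stack_cl, n_clusters)
      }
    } else if (sl >= min_cluster_size || sr >= min_cluster_size) {
      big <- if (sl >= min_cluster_size) l else r
      small <- if (sl >= min_cluster_size) r else l
      pts <- collect_leaves(left, right, small, n)
      pt_cluster <- c(pt_cluster, rep(cl, length(pts)))
      pt_id <- c(pt_id, pts)
      pt_lambda <- c(pt_lambda, rep(lam, length(pts)))
      stack_node <- c(stack_node, big)
      stack_cl <- c(stack_cl, cl)
    } else {
      pts <- collect_leaves(left, right, v, n)
      pt_cluster <- c(pt_cluster, rep(cl, length(pts)))
      pt_id <- c(pt_id, pts)
      pt_lambda <- c(pt_lambda, rep(lam, length(pts)))
    }
  }

  # a cluster pushed onto the stack whose node is a leaf cannot happen:
  # leaves have size 1 < min_cluster_size
  stability <- numeric(n_clusters)
  for (i in seq_along(pt_cluster)) {
    stability[pt_cluster[i]] <- stability[pt_cluster[i]] +
      (pt_lambda[i] - cl_birth[pt_cluster[i]])
  }
  for (c_id in seq_len(n_clusters)[-1]) {
    stability[cl_parent[c_id]] <- stability[cl_parent[c_id]] +
      nsize_of_cluster(c_id, pt_cluster, cl_parent, n_clusters) *
      (cl_birth[c_id] - cl_birth[cl_parent[c_id]])
  }

  # excess-of-mass selection, children before parents (ids increase
  # downward, so reverse id order is a valid bottom-up order)
  selected <- logical(n_clusters)
  subtree_stab <- stability
  children <- split(seq_len(n_clusters)[-1], cl_parent[-1])
  for (c_id in rev(seq_len(n_clusters))) {
    kids <- children[[as.character(c_id)]]
    kid_sum <- if (is.null(kids)) 0 else sum(subtree_stab[kids])
    if (c_id == 1L) {          # the all-points root is never a cluster
      subtree_stab[c_id] <- kid_sum
    } else if (is.null(kids) || stability[c_id] >= kid_sum) {
      selected[c_id] <- TRUE
      subtree_stab[c_id] <- stability[c_id]
      # deselect descendants
      desc <- kids
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(children[as.character(desc)])
      }
    } else {
      subtree_stab[c_id] <- kid_sum
    }
  }

  labels <- rep(-1L, n)
  if (any(selected)) {
    sel_label <- integer(n_clusters)
    sel_label[selected] <- seq_len(sum(selected))
    for (i in seq_along(pt_cluster)) {
      c_id <- pt_cluster[i]
      while (c_id != 0L) {
        if (selected[c_id]) { labels[pt_id[i]] <- sel_label[c_id]; break }
        c_id <- cl_parent[c_id]
      }
    }
    # renumber clusters by order of first appearance for stable output
    seen <- unique(labels[labels > 0])
    labels[labels > 0] <- match(labels[labels > 0], seen)
  }
  names(labels) <- rownames(x)
  attr(labels, "provenance") <- list(
    n_clusters = length(unique(labels[labels > 0])),
    noise_fraction = mean(labels == -1L),
    min_cluster_size = min_cluster_size, min_samples = min_samples,
    input = input)
  labels
}

# number of points recorded under cluster c_id and its descendants
nsize_of_cluster <- function(c_id, pt_cluster, cl_parent, n_clusters) {
  members <- c_id
  repeat {
    kids <- which(cl_parent %in% members & !(seq_len(n_clusters) %in% members))
    if (!length(kids)) break
    members <- c(members, kids)
  }
  sum(pt_cluster %in% members)
}
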