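# Feature reduction (zero-variance, collinearity, condition concatenation,
# low-dimensional embedding), similarity matrices, hierarchical clustering
# and heatmap/network export.

set_reduction <- function(m, provenance) {
  attr(m, "reduction") <- provenance
  m
}

#' Reduction provenance of a matrix
#' @param m A reduced matrix.
#' @return The recorded provenance list (method, parameters, removed
#'   features), or `NULL`.
#' @export
reduction_provenance <- function(m) attr(m, "reduction")

#' Remove zero-variance features
#'
#' Drops exactly the columns with zero standard deviation across all rows
#' (uninformative features); the removed names are recorded in the
#' provenance.
#'
#' @param matrix Numeric matrix (rows = treatments, columns = features).
#' @return The matrix without constant columns.
#' @export
drop_zero_variance <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 1) stop("need at least one row")
  rng <- apply(m, 2, function(v) max(v) - min(v))
  constant <- rng == 0
  if (all(constant)) stop("all features have zero variance")
  out <- m[, !constant, drop = FALSE]
  set_reduction(out, list(method = "zero_variance",
                          removed = colnames(m)[constant]))
}

#' Remove collinear features by pairwise Pearson correlation
#'
#' Iteratively resolves all feature pairs with `|r|` strictly above
#' `r_cut`: pairs are processed in descending `|r|` (stable name
#' tie-break), and of each pair the member with the higher mean absolute
#' correlation to all remaining features is removed, until no pair exceeds
#' the cut. The procedure is deterministic and idempotent, and the removed
#' set is recorded so the reduction can be replayed.
#'
#' @param matrix Numeric matrix with at least 3 rows.
#' @param r_cut Correlation threshold in (0, 1), default 0.8.
#' @return The reduced matrix; provenance lists `r_cut` and the removed
#'   features in removal order.
#' @export
remove_collinear <- function(matrix, r_cut = 0.8) {
  if (r_cut <= 0 || r_cut >= 1) stop("r_cut must be in (0, 1)")
  m <- as.matrix(matrix)
  if (nrow(m) < 3) stop("need at least 3 rows for correlations")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  cm <- abs(suppressWarnings(stats::cor(m)))
  if (anyNA(cm)) {
    cp_log("warn", "zero-variance features present; their correlations treated as 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 0
  removed <- character(0)
  while (ncol(cm) > 1) {
    mx <- max(cm)
    if (mx <= r_cut) break
    hits <- which(cm == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_names <- cbind(rownames(cm)[hits[, 1]], colnames(cm)[hits[, 2]])
    ord <- order(pair_names[, 1], pair_names[, 2])
    pair <- pair_names[ord[1], ]
    mean_r <- vapply(pair, function(f) {
      mean(cm[f, setdiff(colnames(cm), f)])
    }, 0)
    drop <- if (mean_r[1] > mean_r[2]) pair[1] else
      if (mean_r[2] > mean_r[1]) pair[2] else sort(pair)[2]
    removed <- c(removed, drop)
    keep <- colnames(cm) != drop
    cm <- cm[keep, keep, drop = FALSE]
  }
  out <- m[, setdiff(colnames(m), removed), drop = FALSE]
  set_reduction(out, list(method = "collinearity", r_cut = r_cut,
                          removed = removed))
}

#' Concatenate per-condition fingerprints column-wise
#'
#' Joins the resting and activated fingerprint of each treatment into one
#' wide vector (e.g. 482 + 482 = 964 features), suffixing feature names
#' with the condition. Row keys must match exactly.
#'
#' @param matrix_resting,matrix_activated Matrices with identical row keys.
#' @param suffixes Condition suffixes appended to feature names.
#' @return The concatenated matrix.
#' @export
concat_conditions <- function(matrix_resting, matrix_activated,
                              suffixes = c("_resting", "_activated")) {
  a <- as.matrix(matrix_resting); b <- as.matrix(matrix_activated)
  if (!setequal(rownames(a), rownames(b))) {
    stop("row keys differ between conditions: ",
         paste(utils::head(c(setdiff(rownames(a), rownames(b)),
                             setdiff(rownames(b), rownames(a))), 10),
               collapse = ", "))
  }
  b <- b[rownames(a), , drop = FALSE]
  colnames(a) <- paste0(colnames(a), suffixes[1])
  colnames(b) <- paste0(colnames(b), suffixes[2])
  out <- cbind(a, b)
  set_reduction(out, list(method = "concat_conditions", suffixes = suffixes))
}

#' Embed fingerprints into a low-dimensional component space
#'
#' Projects the rows to `n_components` dimensions by classical
#' multidimensional scaling (principal coordinates) of the chosen pairwise
#' distance -- correlation distance `1 - r` by default, matching the
#' similarity metric used for clustering. The output components play the
#' same role as PCA components; the embedding is deterministic, and all
#' parameters are recorded in the provenance. When fewer informative axes
#' exist than requested (at most `n_rows - 1`), the remaining components
#' are zero and the effective rank is recorded.
#'
#' @param matrix Numeric matrix (rows = treatments).
#' @param n_components Target dimensionality (default 100).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param seed Accepted for interface uniformity with the pipeline's
#'   stochastic stages; the embedding itself is deterministic.
#' @return `n_rows x n_components` matrix with provenance.
#' @export
embed_fingerprints <- function(matrix, n_components = 100L,
                               metric = c("correlation", "euclidean"),
                               seed = NULL) {
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  if (nrow(m) < 3) stop("too few rows to embed (need at least 3)")
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(t(m)))
  } else {
    stats::dist(m)
  }
  k <- min(n_components, nrow(m) - 1L)
  emb <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(emb) < n_components) {
    emb <- cbind(emb, matrix(0, nrow(m), n_components - ncol(emb)))
  }
  # fix component signs: largest-magnitude loading positive
  for (j in seq_len(ncol(emb))) {
    v <- emb[, j]
    if (any(v != 0) && v[which.max(abs(v))] < 0) emb[, j] <- -v
  }
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("C", seq_len(n_components))
  set_reduction(emb, list(method = "pcoa", metric = metric,
                          n_components = n_components,
                          effective_rank = sum(apply(emb, 2, function(v) any(v != 0))),
                          seed = seed))
}

#' Pairwise similarity (or distance) matrix of fingerprints
#'
#' `"pearson"` yields the Pearson correlation between all row pairs
#' (symmetric, unit diagonal); rows with zero variance are flagged and
#' their similarities set missing. `"euclidean"` yields the pairwise
#' Euclidean distance matrix (a dissimilarity; zero diagonal).
#'
#' @param matrix Numeric matrix with at least 2 rows.
#' @param metric `"pearson"` or `"euclidean"`.
#' @return Square symmetric matrix with row keys on both axes.
#' @export
similarity_matrix <- function(matrix, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 rows")
  if (metric == "pearson") {
    sds <- apply(m, 1, stats::sd)
    s <- suppressWarnings(stats::cor(t(m)))
    if (any(sds == 0)) {
      cp_log("warn", sum(sds == 0), " zero-variance row(s); similarity set missing")
      s[sds == 0, ] <- NA_real_
      s[, sds == 0] <- NA_real_
    }
    diag(s) <- ifelse(sds == 0, NA_real_, 1)
    s
  } else {
    as.matrix(stats::dist(m))
  }
}

#' Hierarchical clustering of fingerprint rows or columns
#'
#' Complete-linkage agglomeration with Pearson correlation distance
#' (`1 - r`, sign-aware); the leaf order is the deterministic `hclust`
#' order with stable tie-breaks.
#'
#' @param matrix Numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @return An [stats::hclust] tree; `leaf_order` attribute gives labels in
#'   dendrogram order.
#' @export
cluster_hierarchical <- function(matrix, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(matrix)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 leaves")
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(m))))
  d[is.na(d)] <- 2  # zero-variance leaves: maximally distant
  h <- stats::hclust(d, method = "complete")
  attr(h, "leaf_order") <- h$labels[h$order]
  h
}

#' Export a clustered heatmap as plain-text files
#'
#' Writes the matrix reordered by the supplied row/column trees as a
#' tab-delimited file, plus one merge-table file per tree, in a form
#' consumable by standard tree-viewing software. Columns can instead be
#' grouped by stained-compartment prefix (the part of the feature name
#' before the first underscore), keeping each compartment contiguous.
#'
#' @param matrix Numeric matrix.
#' @param row_tree,col_tree [stats::hclust] trees whose labels match the
#'   matrix axes (either may be `NULL` to keep the axis order).
#' @param path_prefix Output path prefix; files get `_matrix.tsv`,
#'   `_rowtree.txt`, `_coltree.txt` suffixes.
#' @param compartment_sort If `TRUE`, order columns by compartment prefix
#'   (then by tree/current order within a compartment).
#' @return Invisibly, the written file paths.
#' @export
export_heatmap <- function(matrix, row_tree = NULL, col_tree = NULL,
                           path_prefix = "heatmap", compartment_sort = FALSE) {
  m <- as.matrix(matrix)
  if (nrow(m) == 0) stop("cannot export an empty matrix")
  row_order <- rownames(m); col_order <- colnames(m)
  if (!is.null(row_tree)) {
    if (!setequal(row_tree$labels, rownames(m))) {
      stop("row tree leaves do not match matrix rows")
    }
    row_order <- attr(row_tree, "leaf_order") %||% row_tree$labels[row_tree$order]
  }
  if (!is.null(col_tree)) {
    if (!setequal(col_tree$labels, colnames(m))) {
      stop("column tree leaves do not match matrix columns")
    }
    col_order <- attr(col_tree, "leaf_order") %||% col_tree$labels[col_tree$order]
  }
  if (compartment_sort) {
    comp <- sub("_.*$", "", col_order)
    col_order <- col_order[order(match(comp, unique(comp)))]
  }
  m <- m[row_order, col_order, drop = FALSE]
  paths <- paste0(path_prefix, c("_matrix.tsv", "_rowtree.txt", "_coltree.txt"))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  write_tree_file <- function(tree, path) {
    if (is.null(tree)) return()
    merges <- data.frame(node = seq_len(nrow(tree$merge)),
                         left = tree$merge[, 1], right = tree$merge[, 2],
                         height = tree$height)
    utils::write.table(merges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_tree_file(row_tree, paths[2])
  write_tree_file(col_tree, paths[3])
  invisible(paths[c(TRUE, !is.null(row_tree), !is.null(col_tree))])
}

#' Similarity network edge list
#'
#' Edges between all row pairs whose similarity strictly exceeds the cut,
#' in long format for network tools.
#'
#' @param similarity Square similarity matrix.
#' @param cut Minimum similarity retained.
#' @return data.frame `from`, `to`, `similarity`.
#' @export
similarity_edges <- function(similarity, cut = 0.7) {
  s <- as.matrix(similarity)
  idx <- which(upper.tri(s) & !is.na(s) & s > cut, arr.ind = TRUE)
  data.frame(from = rownames(s)[idx[, 1]], to = colnames(s)[idx[, 2]],
             similarity = s[idx], stringsAsFactors = FALSE)
}
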