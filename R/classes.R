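# Target-class analysis: in-class vs out-of-class similarity enrichment
# (one-sided two-sample KS) and class-consolidation entropy between the
# resting and activated conditions.

normalize_classes <- function(classes) {
  # accept a long data.frame (compound_id, class) or a named list of labels
  if (is.data.frame(classes)) {
    stopifnot(all(c("compound_id", "class") %in% names(classes)))
    classes <- classes[!is.na(classes$class) & nzchar(classes$class), ]
    split(as.character(classes$compound_id), classes$class)
  } else {
    stats::setNames(lapply(classes, as.character), names(classes))
  }
}

#' In-class vs out-of-class similarity enrichment per target class
#'
#' For every annotated class, compares the distribution of pairwise
#' similarities among class members against the similarities between
#' members and non-members with a one-sided two-sample Kolmogorov-Smirnov
#' test (alternative: in-class similarities stochastically greater). A
#' higher -log10(p) means the class is more readily distinguishable from
#' the rest of the screen. Classes with fewer than 2 members present in
#' the matrix are skipped with a warning. Raw p-values drive the
#' significance call (as in the pilot analysis); Benjamini-Hochberg
#' adjusted values are reported alongside.
#'
#' @param similarity Square Pearson similarity matrix over annotated
#'   compounds (row/column names are compound ids).
#' @param classes Class annotation: data.frame with `compound_id`, `class`
#'   columns (a compound may appear under several classes), or a named
#'   list class -> member ids.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @return data.frame of class `class_enrichment`: `class`, `n_members`,
#'   `ks_stat`, `p_value`, `neg_log10_p`, `p_adjusted`, `significant`;
#'   the fraction of significant classes is in the `fraction_significant`
#'   attribute.
#' @export
ks_class_enrichment <- function(similarity, classes, alpha = 0.05) {
  s <- as.matrix(similarity)
  cls <- normalize_classes(classes)
  rows <- list()
  for (label in names(cls)) {
    members <- intersect(cls[[label]], rownames(s))
    if (length(members) < 2) {
      cp_log("warn", "class ", label, " has fewer than 2 annotated members; skipped")
      next
    }
    others <- setdiff(rownames(s), members)
    ms <- s[members, members, drop = FALSE]
    in_class <- ms[upper.tri(ms)]
    out_class <- as.vector(s[members, others, drop = FALSE])
    in_class <- in_class[!is.na(in_class)]
    out_class <- out_class[!is.na(out_class)]
    if (!length(in_class) || !length(out_class)) next
    kt <- suppressWarnings(stats::ks.test(in_class, out_class,
                                          alternative = "less"))
    rows[[label]] <- data.frame(
      class = label, n_members = length(members),
      ks_stat = unname(kt$statistic), p_value = kt$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no class with at least 2 annotated members in the similarity matrix")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_value <- pmin(pmax(out$p_value, .Machine$double.xmin), 1)
  out$neg_log10_p <- -log10(out$p_value)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  attr(out, "alpha") <- alpha
  attr(out, "fraction_significant") <- mean(out$significant)
  class(out) <- c("class_enrichment", "data.frame")
  out
}

#' Shannon entropy of a label distribution
#'
#' Base-2 entropy of the empirical distribution of `labels`; 0 iff all
#' labels agree, at most `log2(length(labels))`.
#'
#' @param labels Vector of cluster labels.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Class-consolidation entropy between conditions
#'
#' Quantifies how tightly a target class clusters in each condition as the
#' Shannon entropy (bits) of its members' distribution across phenotypic
#' cluster labels. Noise points (label -1) do not form a shared group:
#' each noise member counts as its own singleton label. A negative delta
#' (activated minus resting) means the class consolidated under
#' activation. Cluster labels are injected (typically from
#' [cluster_hdbscan()] on pairwise Euclidean distances of the active
#' compounds), so alternative groupings can be swapped in without touching
#' callers.
#'
#' @param classes Class annotation (see [ks_class_enrichment()]).
#' @param labels_resting,labels_activated Named cluster-label vectors
#'   (names are compound ids; -1 = noise).
#' @param min_members Classes need at least this many members with labels
#'   in both conditions (default 2); others are skipped with a warning.
#' @return data.frame of class `class_entropy`: `class`, `n_members`,
#'   `entropy_resting`, `entropy_activated`, `delta`.
#' @export
entropy_consolidation <- function(classes, labels_resting, labels_activated,
                                  min_members = 2L) {
  cls <- normalize_classes(classes)
  rows <- list()
  for (label in names(cls)) {
    members_r <- intersect(cls[[label]], names(labels_resting))
    members_a <- intersect(cls[[label]], names(labels_activated))
    members <- intersect(members_r, members_a)
    if (length(members) < min_members) {
      cp_log("warn", "class ", label,
             " lacks clustered members in both conditions; skipped")
      next
    }
    h <- function(lab) {
      lab <- lab[members]
      noise <- lab == -1
      lab <- as.character(lab)
      lab[noise] <- paste0("noise_", members[noise])
      shannon_entropy(lab)
    }
    hr <- h(labels_resting); ha <- h(labels_activated)
    rows[[label]] <- data.frame(class = label, n_members = length(members),
                                entropy_resting = hr, entropy_activated = ha,
                                delta = ha - hr, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), n_members = integer(),
               entropy_resting = numeric(), entropy_activated = numeric(),
               delta = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("class_entropy", "data.frame")
  out
}

#' Consolidation scatter table
#'
#' Per-class plotting record for the entropy comparison: resting entropy
#' on x, activated entropy on y, marker size proportional to class
#' membership, and a direction flag (`consolidated` above the diagonal
#' semantics: activated entropy strictly lower; `fragmented` higher;
#' `unchanged` equal).
#'
#' @param results A `class_entropy` data.frame.
#' @return data.frame `class`, `x`, `y`, `size`, `direction`.
#' @export
consolidation_scatter <- function(results) {
  if (nrow(results) == 0) {
    return(data.frame(class = character(), x = numeric(), y = numeric(),
                      size = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    class = results$class,
    x = results$entropy_resting,
    y = results$entropy_activated,
    size = results$n_members,
    direction = ifelse(results$delta < 0, "consolidated",
                       ifelse(results$delta > 0, "fragmented", "unchanged")),
    stringsAsFactors = FALSE)
}
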