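# CP Activity Score and the three activity-threshold rules (IQR, FDR,
# elbow), cytotoxicity flags, and the illuminated/dark Venn summary.

#' CP Activity Score of a fingerprint
#'
#' The mean of the squared per-feature HistDiff scores,
#' \eqn{\mathrm{CPscore} = \sum_i x_i^2 / n}, the aggregate strength of a
#' well's phenotypic fingerprint. Missing features (empty-well flags) are
#' excluded from both the numerator and `n`, with the exclusion logged. No
#' further screen-level rescaling is applied.
#'
#' @param fingerprint Numeric vector of HistDiff scores, or a fingerprint
#'   matrix (scored row-wise).
#' @return A non-negative score (or named vector of scores for a matrix).
#' @export
cp_activity_score <- function(fingerprint) {
  if (is.matrix(fingerprint)) {
    return(apply(unclass(fingerprint), 1, cp_activity_score_vec))
  }
  cp_activity_score_vec(fingerprint)
}

cp_activity_score_vec <- function(x) {
  miss <- is.na(x)
  if (all(miss)) stop("all-missing fingerprint: CP Activity Score undefined")
  if (any(miss)) {
    cp_log("debug", sum(miss), " missing feature(s) excluded from CP score")
  }
  mean(x[!miss]^2)
}

new_threshold <- function(method, value, provenance) {
  structure(list(method = method, value = value, provenance = provenance),
            class = "cp_threshold")
}

#' @export
print.cp_threshold <- function(x, ...) {
  cat(sprintf("CP Activity threshold (%s): %g\n", x$method, x$value))
  invisible(x)
}

#' IQR activity threshold
#'
#' Control scores above the third quartile are treated as outliers (they do
#' not conform to the control distribution); the highest-scoring control at
#' or below Q3 becomes the threshold. Quartiles use linear interpolation
#' (type-7 convention), recorded in the provenance. A conventional
#' Q3 + 1.5 IQR fence is available via `fence = TRUE` for sensitivity
#' analysis.
#'
#' @param control_scores Numeric vector of reference-control CP scores
#'   (at least 4).
#' @param fence If `TRUE`, outliers start at Q3 + 1.5 IQR instead of Q3.
#' @return A `cp_threshold` object.
#' @export
threshold_iqr <- function(control_scores, fence = FALSE) {
  if (length(control_scores) < 4) stop("need at least 4 control scores")
  q <- stats::quantile(control_scores, c(0.25, 0.75), type = 7, names = FALSE)
  cut <- if (fence) q[2] + 1.5 * (q[2] - q[1]) else q[2]
  keep <- control_scores[control_scores <= cut]
  if (!length(keep)) stop("no control scores at or below the outlier cut")
  new_threshold("iqr", max(keep),
                list(q3 = q[2], cut = cut, fence = fence,
                     quantile_type = 7L, n_controls = length(control_scores)))
}

#' FDR activity threshold
#'
#' Excludes the top `q` fraction of control scores as outliers (exactly
#' `ceiling(q * N)` scores, descending, stable index tie-break) and takes
#' the maximum of the remainder. With fewer than `1/q` controls the
#' exclusion would be empty; the maximum control is used and a warning
#' logged.
#'
#' @param control_scores Numeric vector of reference-control CP scores.
#' @param q Outlier fraction (default 0.05).
#' @return A `cp_threshold` object.
#' @export
threshold_fdr <- function(control_scores, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  n <- length(control_scores)
  if (n < 1) stop("need at least 1 control score")
  n_excl <- ceiling(q * n)
  if (n_excl >= n) {
    cp_log("warn", "too few controls for a non-empty remainder; using max control")
    n_excl <- n - 1L
  }
  ord <- order(control_scores, decreasing = TRUE)
  keep <- control_scores[-ord[seq_len(n_excl)]]
  new_threshold("fdr5", max(keep),
                list(q = q, n_excluded = n_excl, n_controls = n))
}

#' Elbow (knee) activity threshold
#'
#' Sorts all scores ascending and finds the inflection of the resulting
#' elbow curve as the index maximizing the perpendicular distance to the
#' chord joining the first and last point; the score at the knee is the
#' threshold. Both axes are rescaled to the unit square first, so the knee
#' is invariant under affine rescaling of the scores.
#'
#' @param all_scores Numeric vector (at least 10 values).
#' @param tolerance Relative distance below which the curve is considered
#'   exactly collinear (degenerate).
#' @return A `cp_threshold` object with the knee index in the provenance.
#' @export
threshold_elbow <- function(all_scores, tolerance = 1e-9) {
  n <- length(all_scores)
  if (n < 10) stop("need at least 10 scores for an elbow fit")
  y <- sort(all_scores)
  if (y[n] == y[1]) stop("degenerate elbow curve: all scores identical")
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  # perpendicular distance to the chord from (0,0) to (1,1)
  d <- abs(xs - ys) / sqrt(2)
  if (max(d) < tolerance) {
    stop("degenerate elbow curve: scores are exactly collinear")
  }
  knee <- which.max(d)
  new_threshold("elbow", y[knee],
                list(knee_index = knee, n = n, max_distance = max(d)))
}

#' Establish an activity threshold
#'
#' Dispatcher over the three rules. `"iqr"` and `"fdr5"` use control
#' scores only; `"elbow"` uses all scores when supplied, else controls.
#'
#' @param control_scores Reference-control CP scores.
#' @param method `"iqr"`, `"fdr5"` or `"elbow"`.
#' @param all_scores Full score vector for the elbow method.
#' @param ... Passed to the underlying rule.
#' @return A `cp_threshold` object.
#' @export
activity_threshold <- function(control_scores, method = c("iqr", "fdr5", "elbow"),
                               all_scores = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         iqr = threshold_iqr(control_scores, ...),
         fdr5 = threshold_fdr(control_scores, ...),
         elbow = threshold_elbow(if (is.null(all_scores)) control_scores
                                 else all_scores, ...))
}

#' Flag cytotoxic wells by cell count
#'
#' A well is cytotoxic when its cell count falls strictly below 50% of the
#' mean control-well cell count.
#'
#' @param n_cells Integer vector of per-well cell counts.
#' @param control_cell_counts Cell counts of the plate's control wells.
#' @param fraction Cytotoxicity cut as a fraction of the control mean.
#' @return Logical vector parallel to `n_cells`.
#' @export
flag_cytotoxic <- function(n_cells, control_cell_counts, fraction = 0.5) {
  if (!length(control_cell_counts)) stop("need at least one control cell count")
  n_cells < fraction * mean(control_cell_counts)
}

#' Per-well activity table for one condition
#'
#' Joins fingerprints, plate annotations, the activity threshold and cell
#' counts into the per-well record downstream stages consume. The active
#' call is strictly `cp_score > threshold`, and the threshold used is
#' recorded in the `threshold` attribute.
#'
#' @param fingerprints A [fingerprint_matrix()].
#' @param platemap The matching [plate_map()].
#' @param threshold A `cp_threshold` object (or bare number).
#' @param n_cells Optional named per-well cell counts (defaults to the
#'   fingerprint matrix's flags).
#' @return data.frame of class `activity_table`: `well`, `role`,
#'   `compound_id`, `dose_uM`, `condition`, `cp_score`, `active`,
#'   `cytotoxic`, `n_cells`.
#' @export
activity_table <- function(fingerprints, platemap, threshold,
                           n_cells = NULL) {
  thr <- if (inherits(threshold, "cp_threshold")) threshold$value else threshold
  wells <- rownames(fingerprints)
  pm <- as.data.frame(platemap)
  idx <- match(wells, pm$well)
  if (anyNA(idx)) stop("fingerprint wells missing from plate map: ",
                       paste(wells[is.na(idx)], collapse = ", "))
  if (is.null(n_cells)) {
    fl <- attr(fingerprints, "flags")
    n_cells <- if (!is.null(fl)) fl$n_cells[match(wells, fl$well)] else NA_integer_
  } else {
    n_cells <- n_cells[wells]
  }
  scores <- vapply(seq_along(wells), function(i) {
    x <- unclass(fingerprints)[i, ]
    if (all(is.na(x))) NA_real_ else mean(x[!is.na(x)]^2)
  }, 0)
  ctrl <- pm$well[idx] %in% pm$well[pm$role == "reference_control"]
  cyto <- if (all(is.na(n_cells))) rep(NA, length(wells)) else
    flag_cytotoxic(n_cells, n_cells[ctrl])
  out <- data.frame(
    well = wells, role = pm$role[idx], compound_id = pm$compound_id[idx],
    dose_uM = pm$dose_uM[idx], condition = pm$condition[idx],
    cp_score = scores, active = !is.na(scores) & scores > thr,
    cytotoxic = cyto, n_cells = n_cells,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("activity_table", "data.frame"))
}

#' Illumination (Venn) summary across the two activation conditions
#'
#' Partitions compounds into active-in-both, activated-only, resting-only
#' and dark categories from their per-condition active calls, with counts
#' and percentages. Compounds appearing in several wells count as active in
#' a condition if any of their wells is active.
#'
#' @param activity_resting,activity_activated `activity_table`s (or any
#'   data.frames with `compound_id` and `active`) over the same compounds.
#' @return List of class `illumination_summary` with `counts`,
#'   `percentages` (named: both, activated_only, resting_only, dark),
#'   `n_compounds` and the per-compound `categories` data.frame.
#' @export
illumination_summary <- function(activity_resting, activity_activated) {
  agg <- function(tab) {
    tab <- tab[!is.na(tab$compound_id), , drop = FALSE]
    tapply(tab$active, tab$compound_id, any)
  }
  r <- agg(activity_resting); a <- agg(activity_activated)
  only_r <- setdiff(names(r), names(a)); only_a <- setdiff(names(a), names(r))
  if (length(only_r) || length(only_a)) {
    stop("compound keys differ between conditions; resting-only: ",
         paste(utils::head(only_r, 5), collapse = ", "), "; activated-only: ",
         paste(utils::head(only_a, 5), collapse = ", "))
  }
  a <- a[names(r)]
  category <- ifelse(r & a, "both",
                     ifelse(a, "activated_only",
                            ifelse(r, "resting_only", "dark")))
  lv <- c("both", "activated_only", "resting_only", "dark")
  counts <- table(factor(category, levels = lv))
  structure(list(
    counts = counts,
    percentages = stats::setNames(100 * as.vector(counts) / sum(counts), lv),
    n_compounds = length(category),
    categories = data.frame(compound_id = names(r), category = category,
                            active_resting = as.vector(r),
                            active_activated = as.vector(a),
                            row.names = NULL, stringsAsFactors = FALSE)
  ), class = "illumination_summary")
}

#' @export
print.illumination_summary <- function(x, ...) {
  cat("Illuminated phenotypic space (", x$n_compounds, " compounds )\n")
  lv <- names(x$counts)
  for (i in seq_along(lv)) {
    cat(sprintf("  %-15s %5d  (%.1f%%)\n", lv[i], x$counts[[i]],
                x$percentages[i]))
  }
  invisible(x)
}
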