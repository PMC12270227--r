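# Quality-control checkpoints: the brightfield activation gate (ChP2), the
# paired-condition score comparison (ChP4), the control-anomaly decision
# rules (ChP5), and replicate-control reproducibility.

qc_decision <- function(plate_id, checkpoint, verdict, evidence) {
  structure(list(plate_id = plate_id, checkpoint = checkpoint,
                 verdict = verdict, evidence = evidence),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf("QC %s [%s]: %s\n", x$checkpoint,
              if (is.null(x$plate_id)) "plate" else x$plate_id, x$verdict))
  ev <- unlist(x$evidence)
  for (n in names(ev)) cat(sprintf("  %-28s %s\n", n, ev[[n]]))
  invisible(x)
}

# ---- ChP2: brightfield activation gate ---------------------------------

#' Pre-filter putative brightfield cells
#'
#' Removes objects too big to be cells (area strictly greater than 2000
#' square microns) or too dark (brightfield intensity mean strictly below
#' 10000); removal counts are logged. A cell with area exactly 2000 is
#' retained.
#'
#' @param table A `brightfield_cell_table`.
#' @param max_area,min_mean Filter bounds.
#' @return The filtered table; removal counts in the `removed` attribute.
#' @export
prefilter_cells <- function(table, max_area = 2000, min_mean = 10000) {
  too_big <- table$area > max_area
  too_dark <- table$int_mean < min_mean
  keep <- !(too_big | too_dark)
  if (any(!keep)) {
    cp_log("info", sum(too_big), " oversized and ", sum(too_dark),
           " dark object(s) removed by the brightfield prefilter")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(oversized = sum(too_big), dark = sum(too_dark))
  class(out) <- class(table)
  out
}

#' Train the linear activation classifier
#'
#' Fits a linear decision boundary on the 23 brightfield features
#' separating resting from activated cells, mirroring the checkpoint's
#' machine-learning step (train on the cells of a few wells of known
#' state, then apply to every well of every later plate). Linear
#' discriminant analysis provides the linear rule; the contract is the
#' decision interface, not a specific weight vector.
#'
#' @param train A prefiltered `brightfield_cell_table` with a `label`
#'   column (or `true_label`) containing both `"resting"` and
#'   `"activated"`.
#' @param features Feature set (defaults to [bf_classifier_features()]).
#' @return Object of class `activation_classifier` with the fitted model,
#'   feature list and training accuracy.
#' @export
train_activation_classifier <- function(train,
                                        features = bf_classifier_features()) {
  lab_col <- if ("label" %in% names(train)) "label" else "true_label"
  labels <- factor(train[[lab_col]], levels = c("resting", "activated"))
  if (anyNA(labels)) stop("labels must be 'resting' or 'activated'")
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set contains a single class; need both phenotypes")
  }
  x <- as.matrix(train[features])
  fit <- MASS::lda(x, grouping = labels)
  pred <- stats::predict(fit, x)$class
  acc <- mean(pred == labels)
  cp_log("info", sprintf("activation classifier trained on %d cells; training accuracy %.1f%%",
                         nrow(x), 100 * acc))
  structure(list(fit = fit, features = features, training_accuracy = acc,
                 n_train = nrow(x)),
            class = "activation_classifier")
}

#' @export
print.activation_classifier <- function(x, ...) {
  cat(sprintf("Brightfield activation classifier: %d features, %d training cells, training accuracy %.1f%%\n",
              length(x$features), x$n_train, 100 * x$training_accuracy))
  invisible(x)
}

#' Classify cells as activated or resting
#' @param model An `activation_classifier`.
#' @param cells A prefiltered `brightfield_cell_table`.
#' @return Factor of predicted labels.
#' @export
predict_activation <- function(model, cells) {
  stats::predict(model$fit, as.matrix(cells[model$features]))$class
}

#' Percent of a well's cells classified as activated
#'
#' `100 * a / (a + b)` with `a` the predicted-activated and `b` the
#' predicted-resting cell count. A well with zero retained cells yields
#' `NA` (flagged by the caller).
#'
#' @param model An `activation_classifier`.
#' @param well_cells Prefiltered cells of one well.
#' @return Percentage in `[0, 100]`, or `NA` for an empty well.
#' @export
percent_activated <- function(model, well_cells) {
  if (nrow(well_cells) == 0) {
    cp_log("warn", "well with zero retained cells: percent activated undefined")
    return(NA_real_)
  }
  pred <- predict_activation(model, well_cells)
  a <- sum(pred == "activated")
  100 * a / length(pred)
}

#' ChP2 plate gate on control-well activation levels
#'
#' A plate passes when at most `max_offending` resting (noPMA) control
#' wells have strictly more than 15% of cells classified activated, and at
#' most `max_offending` activated (PMA) control wells have strictly less
#' than 30% activated; otherwise it is flagged for rescreening. A well at
#' exactly 15% (or 30%) does not offend.
#'
#' @param percent_by_well Named numeric vector of per-well percent
#'   activated (control wells).
#' @param condition_by_well Named character vector (`"resting"` /
#'   `"activated"`) parallel to `percent_by_well`.
#' @param max_offending Allowed offending wells per condition (default 2).
#' @param resting_limit,activated_limit The 15% / 30% rule bounds.
#' @param plate_id Optional identifier for the report.
#' @return A `qc_decision` (`pass` or `rescreen`) with offending counts.
#' @export
chp2_gate <- function(percent_by_well, condition_by_well,
                      max_offending = 2L, resting_limit = 15,
                      activated_limit = 30, plate_id = NULL) {
  condition_by_well <- condition_by_well[names(percent_by_well)]
  rest <- percent_by_well[condition_by_well == "resting"]
  act <- percent_by_well[condition_by_well == "activated"]
  n_rest_off <- sum(rest > resting_limit, na.rm = TRUE)
  n_act_off <- sum(act < activated_limit, na.rm = TRUE)
  verdict <- if (n_rest_off <= max_offending && n_act_off <= max_offending)
    "pass" else "rescreen"
  qc_decision(plate_id, "ChP2", verdict,
              list(n_resting_offending = n_rest_off,
                   n_activated_offending = n_act_off,
                   max_offending = max_offending))
}

# ---- ChP5: control-anomaly decisions -----------------------------------

#' ChP5 decision kernel on abnormal-control counts
#'
#' Pure decision function behind [chp5_gate()]: a plate with more than 22%
#' abnormal controls at the outset is repeated outright; with more than 3
#' abnormal wells (roughly 10% of the control set) the abnormal controls
#' are dropped and plate normalization recomputed, after which 3 or more
#' remaining abnormal wells send the plate to rescreening; otherwise the
#' plate passes (verdict `renormalize` records that recomputation was
#' needed).
#'
#' @param n_controls Number of control wells.
#' @param n_abnormal Abnormal controls at the outset.
#' @param n_abnormal_after Abnormal controls after renormalization (only
#'   consulted when renormalization is triggered; default 0).
#' @param repeat_fraction,renorm_wells,rescreen_wells Rule parameters.
#' @return Verdict string: `pass`, `renormalize`, `rescreen` or `repeat`.
#' @export
chp5_decision <- function(n_controls, n_abnormal, n_abnormal_after = 0L,
                          repeat_fraction = 0.22, renorm_wells = 3L,
                          rescreen_wells = 3L) {
  stopifnot(n_controls >= 1, n_abnormal >= 0, n_abnormal <= n_controls)
  if (n_abnormal / n_controls > repeat_fraction) return("repeat")
  if (n_abnormal > renorm_wells) {
    if (n_abnormal_after >= rescreen_wells) return("rescreen")
    return("renormalize")
  }
  "pass"
}

#' ChP5 gate on control CP Activity Scores
#'
#' A control well is abnormal when a reference control scores active
#' (strictly above the threshold) or a positive (activator/JUMP) control
#' scores inactive. Applies [chp5_decision()]; when renormalization is
#' triggered and `rescore` is supplied, it is called with the abnormal well
#' labels and must return the recomputed control scores (named) for the
#' post-renormalization count. Without `rescore`, dropping the abnormal
#' controls is assumed to resolve them.
#'
#' @param control_scores Named CP scores of the plate's control wells.
#' @param threshold `cp_threshold` or number.
#' @param roles Named roles parallel to `control_scores`
#'   (`reference_control` / `activator_control` / `jump_control`).
#' @param rescore Optional `function(dropped_wells)` returning new named
#'   control scores.
#' @param plate_id Optional identifier.
#' @param ... Rule parameters passed to [chp5_decision()].
#' @return A `qc_decision` with abnormal counts in the evidence.
#' @export
chp5_gate <- function(control_scores, threshold, roles, rescore = NULL,
                      plate_id = NULL, ...) {
  if (!length(control_scores)) stop("no control wells to evaluate")
  thr <- if (inherits(threshold, "cp_threshold")) threshold$value else threshold
  roles <- roles[names(control_scores)]
  abnormal <- abnormal_controls(control_scores, thr, roles)
  n_after <- 0L
  if (sum(abnormal) > list(...)$renorm_wells %||% 3L && !is.null(rescore)) {
    new_scores <- rescore(names(control_scores)[abnormal])
    new_roles <- roles[names(new_scores)]
    n_after <- sum(abnormal_controls(new_scores, thr, new_roles))
  }
  verdict <- chp5_decision(length(control_scores), sum(abnormal),
                           n_abnormal_after = n_after, ...)
  qc_decision(plate_id, "ChP5", verdict,
              list(n_controls = length(control_scores),
                   n_abnormal = sum(abnormal),
                   n_abnormal_after = n_after,
                   abnormal_wells = paste(names(control_scores)[abnormal],
                                          collapse = ",")))
}

abnormal_controls <- function(scores, thr, roles) {
  (roles == "reference_control" & scores > thr) |
    (roles %in% c("activator_control", "jump_control") & scores <= thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ChP4: paired-condition comparison ---------------------------------

#' Paired-condition CP score table (QC scatter input)
#'
#' Pairs each well's CP Activity Score in the resting condition (x) with
#' its score in the activated condition (y) and assigns the quadrant by
#' strict comparison against the threshold on each axis. The axis
#' convention (x = resting, y = activated) is recorded in the output
#' attributes.
#'
#' @param activity_resting,activity_activated `activity_table`s with
#'   matched wells.
#' @param threshold `cp_threshold` or number.
#' @return data.frame `well`, `role`, `compound_id`, `x`, `y`, `quadrant`
#'   (`dark`, `resting_only`, `activated_only`, `both`).
#' @export
paired_condition_table <- function(activity_resting, activity_activated,
                                   threshold) {
  thr <- if (inherits(threshold, "cp_threshold")) threshold$value else threshold
  if (!setequal(activity_resting$well, activity_activated$well)) {
    stop("unmatched wells between conditions: ",
         paste(utils::head(c(setdiff(activity_resting$well, activity_activated$well),
                             setdiff(activity_activated$well, activity_resting$well)), 10),
               collapse = ", "))
  }
  a <- activity_activated[match(activity_resting$well, activity_activated$well), ]
  x <- activity_resting$cp_score
  y <- a$cp_score
  quadrant <- ifelse(x > thr & y > thr, "both",
                     ifelse(y > thr, "activated_only",
                            ifelse(x > thr, "resting_only", "dark")))
  out <- data.frame(well = activity_resting$well, role = activity_resting$role,
                    compound_id = activity_resting$compound_id,
                    x = x, y = y, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  attr(out, "axes") <- c(x = "resting", y = "activated")
  attr(out, "threshold") <- thr
  out
}

# ---- JUMP-control reproducibility --------------------------------------

#' Pairwise replicate-control similarity distributions
#'
#' For each replicated control compound, computes all pairwise Pearson
#' correlations between replicate fingerprints at the requested grouping
#' level (within the same plate, between plates of the same batch, or
#' between batches), in long format for violin plotting. Singleton groups
#' are skipped with a warning.
#'
#' @param fingerprints Fingerprint matrix whose rows are replicate wells.
#' @param metadata data.frame with one row per fingerprint row: `compound_id`,
#'   `plate_id`, and optionally `batch` (defaults to one batch).
#' @param grouping `"within_plate"`, `"between_plate"` or `"between_batch"`.
#' @return data.frame `compound_id`, `grouping`, `correlation` (one row per
#'   replicate pair).
#' @export
jump_reproducibility <- function(fingerprints, metadata,
                                 grouping = c("within_plate", "between_plate",
                                              "between_batch")) {
  grouping <- match.arg(grouping)
  m <- unclass(fingerprints)
  stopifnot(nrow(m) == nrow(metadata))
  if (!"batch" %in% names(metadata)) metadata$batch <- "batch1"
  res <- list()
  for (cmp in unique(metadata$compound_id)) {
    idx <- which(metadata$compound_id == cmp)
    if (length(idx) < 2) {
      cp_log("warn", "compound ", cmp, " has a single replicate; skipped")
      next
    }
    pairs <- utils::combn(idx, 2)
    same_plate <- metadata$plate_id[pairs[1, ]] == metadata$plate_id[pairs[2, ]]
    same_batch <- metadata$batch[pairs[1, ]] == metadata$batch[pairs[2, ]]
    keep <- switch(grouping,
                   within_plate = same_plate,
                   between_plate = !same_plate & same_batch,
                   between_batch = !same_batch)
    if (!any(keep)) next
    cors <- apply(pairs[, keep, drop = FALSE], 2, function(p) {
      stats::cor(m[p[1], ], m[p[2], ])
    })
    res[[cmp]] <- data.frame(compound_id = cmp, grouping = grouping,
                             correlation = cors, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(compound_id = character(), grouping = character(),
               correlation = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
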