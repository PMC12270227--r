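# Screen-level driver: simulate and fingerprint every plate of one
# condition and collect per-well CP Activity Scores.

#' Simulate and score one condition of a synthetic screen
#'
#' Runs [generate_platemap()], [simulate_single_cells()] and
#' [fingerprint_plate()] for every plate of the design under one activation
#' condition and returns the per-well CP Activity Scores with their plate
#' annotations. This is the unit both the activity-threshold stage and the
#' illumination summary consume.
#'
#' @param design A [screen_design()].
#' @param condition `"resting"` or `"activated"`.
#' @param seed Base seed; each plate derives its own stream from it.
#' @param bins,min_cells Passed to [fingerprint_plate()].
#' @return data.frame `plate`, `well`, `role`, `compound_id`, `cp_score`,
#'   `n_cells`, `active` (filled by the caller once a threshold exists).
#' @export
screen_scores <- function(design, condition, seed, bins = 20L,
                          min_cells = 10L) {
  res <- vector("list", design$n_plates)
  for (p in seq_len(design$n_plates)) {
    pm <- generate_platemap(design, p, condition)
    cells <- simulate_single_cells(design, pm, condition,
                                   seed = derive_seed(seed, 37L * p))
    fp <- fingerprint_plate(cells, pm, bins = bins, min_cells = min_cells)
    flags <- attr(fp, "flags")
    wells <- rownames(fp)
    idx <- match(wells, pm$well)
    res[[p]] <- data.frame(
      plate = p, well = wells, role = pm$role[idx],
      compound_id = pm$compound_id[idx],
      cp_score = cp_activity_score(fp),
      n_cells = flags$n_cells[match(wells, flags$well)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Recover the illumination partition of a planted screen
#'
#' Scores both conditions of a planted design, derives the FDR activity
#' threshold from the pooled reference-control scores of the whole screen
#' (both conditions combined, as with a screen-wide DMSO control pool),
#' and partitions every compound into the illumination categories.
#'
#' @param design A planted [screen_design()] (e.g.
#'   [planted_screen_design()]).
#' @param seed Seed for the simulated screen.
#' @param q FDR outlier fraction for [threshold_fdr()].
#' @return List with `truth` (the [effect_truth()] table joined with
#'   per-condition active calls and the assigned `category`), `summary`
#'   (the [illumination_summary()]), `threshold`, and the per-condition
#'   score tables.
#' @export
screen_recovery <- function(design, seed, q = 0.05) {
  sc <- list(resting = screen_scores(design, "resting", seed),
             activated = screen_scores(design, "activated",
                                       derive_seed(seed, 101L)))
  refs <- unlist(lapply(sc, function(s) {
    s$cp_score[s$role == "reference_control" & !is.na(s$cp_score)]
  }))
  thr <- threshold_fdr(refs, q = q)
  tabs <- lapply(sc, function(s) {
    e <- s[s$role == "experimental" & !is.na(s$compound_id), ]
    data.frame(compound_id = e$compound_id,
               active = !is.na(e$cp_score) & e$cp_score > thr$value,
               stringsAsFactors = FALSE)
  })
  venn <- illumination_summary(tabs$resting, tabs$activated)
  truth <- effect_truth(design)
  cat_map <- stats::setNames(venn$categories$category,
                             venn$categories$compound_id)
  truth$category <- unname(cat_map[truth$compound_id])
  truth$planted_category <- c(both = "both", activated_only = "activated_only",
                              resting_only = "resting_only", none = "dark")[
                                truth$specificity]
  list(truth = truth, summary = venn, threshold = thr, scores = sc)
}
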