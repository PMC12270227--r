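# Glucocorticoid-receptor nuclear-translocation scoring: a six-criterion
# ratio classifier over per-cell nuclear/cytoplasmic intensity records,
# summarized as percent nuclear-enriched per well.

#' Six-criterion nuclear-enrichment classification of GR cells
#'
#' A cell is nuclear-enriched if and only if ALL six ratio criteria hold
#' strictly:
#' \itemize{
#'   \item GR nuclear sum / Hoechst nuclear sum > 0.35
#'   \item GR nuclear sum / GR cytoplasmic sum > 0.25
#'   \item GR nuclear mean / GR cytoplasmic mean > 1.7
#'   \item GR nuclear median / GR cytoplasmic median > 1.7
#'   \item GR nuclear quantile / GR cytoplasmic quantile > 1.7
#'   \item GR nuclear contrast / GR cytoplasmic contrast > 0.3
#' }
#' Cells on any boundary fail (strict inequalities). Cells with a
#' non-positive denominator cannot be evaluated and are excluded (`NA`),
#' dropping out of both the numerator and denominator of the well summary.
#'
#' @param cells data.frame with columns `hoechst_nuc_sum`, `gr_nuc_mean`,
#'   `gr_nuc_median`, `gr_nuc_sum`, `gr_nuc_quantile`, `gr_nuc_contrast`,
#'   `gr_cyto_mean`, `gr_cyto_median`, `gr_cyto_sum`, `gr_cyto_quantile`,
#'   `gr_cyto_contrast`.
#' @return Logical vector: `TRUE` (enriched), `FALSE`, or `NA` (excluded).
#' @export
classify_nuclear_enriched <- function(cells) {
  denoms <- cbind(cells$hoechst_nuc_sum, cells$gr_cyto_sum,
                  cells$gr_cyto_mean, cells$gr_cyto_median,
                  cells$gr_cyto_quantile, cells$gr_cyto_contrast)
  valid <- apply(denoms > 0, 1, all)
  if (any(!valid, na.rm = TRUE)) {
    cp_log("info", sum(!valid), " cell(s) excluded for non-positive denominators")
  }
  thr <- gr_criteria()
  pass <- cells$gr_nuc_sum / cells$hoechst_nuc_sum > thr[["sum_vs_hoechst"]] &
    cells$gr_nuc_sum / cells$gr_cyto_sum > thr[["sum_ratio"]] &
    cells$gr_nuc_mean / cells$gr_cyto_mean > thr[["mean_ratio"]] &
    cells$gr_nuc_median / cells$gr_cyto_median > thr[["median_ratio"]] &
    cells$gr_nuc_quantile / cells$gr_cyto_quantile > thr[["quantile_ratio"]] &
    cells$gr_nuc_contrast / cells$gr_cyto_contrast > thr[["contrast_ratio"]]
  pass[!valid | is.na(valid)] <- NA
  pass
}

#' Percent of cells with nuclear-enriched GR signal
#'
#' `100 * enriched / valid` over the supplied cells, after excluding cells
#' with non-evaluable ratios. With a `field` grouping and
#' `aggregate = "per_field"`, per-field percentages are computed first and
#' averaged (the acquisition-time convention); the default pools all cells.
#'
#' @param cells GR cell records (see [classify_nuclear_enriched()]).
#' @param field Optional per-cell field-of-view identifier.
#' @param aggregate `"pooled"` (default) or `"per_field"`.
#' @return Percentage in `[0, 100]`, or `NA` (flagged) when no valid cell
#'   remains.
#' @export
percent_nuclear <- function(cells, field = NULL,
                            aggregate = c("pooled", "per_field")) {
  aggregate <- match.arg(aggregate)
  enriched <- classify_nuclear_enriched(cells)
  if (aggregate == "per_field" && !is.null(field)) {
    per <- tapply(enriched, field, function(e) {
      e <- e[!is.na(e)]
      if (!length(e)) NA_real_ else 100 * mean(e)
    })
    per <- per[!is.na(per)]
    if (!length(per)) {
      cp_log("warn", "no field with valid cells: percent nuclear undefined")
      return(NA_real_)
    }
    return(mean(per))
  }
  e <- enriched[!is.na(enriched)]
  if (!length(e)) {
    cp_log("warn", "no valid cells: percent nuclear undefined")
    return(NA_real_)
  }
  100 * mean(e)
}

#' Per-well GR translocation summary
#'
#' @param cells GR cell records with a `well` column.
#' @param aggregate Passed to [percent_nuclear()].
#' @return data.frame `well`, `percent_nuclear`, `n_valid`, `n_excluded`.
#' @export
gr_well_summary <- function(cells, aggregate = c("pooled", "per_field")) {
  aggregate <- match.arg(aggregate)
  wells <- unique(cells$well)
  res <- lapply(wells, function(w) {
    sub <- cells[cells$well == w, , drop = FALSE]
    enriched <- classify_nuclear_enriched(sub)
    data.frame(well = w,
               percent_nuclear = percent_nuclear(
                 sub, field = sub$field, aggregate = aggregate),
               n_valid = sum(!is.na(enriched)),
               n_excluded = sum(is.na(enriched)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
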