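# HistDiff: per-feature, per-well histogram-difference scores against the
# plate's pooled reference-control population.
#
# The comparison statistic is a documented reconstruction (the published
# description names the steps -- bin, smooth, normalize, compare -- without
# a formula): score = sign * sum_b (T_b - R_b)^2, where T and R are the
# smoothed, unit-sum treatment and reference densities over shared bins and
# the sign is +1 when the treatment histogram mean (bin-midpoint weighted)
# exceeds the reference mean. It is 0 for identical histograms, bounded by
# 2 in absolute value, and swappable behind histdiff_score().

smooth_kernel <- c(0.25, 0.5, 0.25)

smooth_counts <- function(counts) {
  n <- length(counts)
  if (n < 2) return(counts)
  padded <- c(0, counts, 0)
  smooth_kernel[1] * padded[seq_len(n)] +
    smooth_kernel[2] * padded[seq_len(n) + 1L] +
    smooth_kernel[3] * padded[seq_len(n) + 2L]
}

#' Bin edges covering a pooled value range
#'
#' `bins` equal-width bins spanning `[min(values), max(values)]`. A
#' degenerate (constant) feature falls back to the unit interval around the
#' constant so that identical-constant wells score 0.
#'
#' @param values Numeric vector (pooled treatment and reference values).
#' @param bins Number of bins (default 20).
#' @return Numeric vector of `bins + 1` strictly increasing edges.
#' @export
histogram_edges <- function(values, bins = 20L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to derive bin edges from")
  lo <- min(values); hi <- max(values)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  seq(lo, hi, length.out = bins + 1L)
}

bin_index <- function(values, bin_edges) {
  b <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), b)  # clamp: edges are required to cover the range
}

#' Build a smoothed, normalized feature histogram
#'
#' Counts cell values into half-open bins (the last bin is closed so a
#' value exactly on the maximum edge is counted), applies one pass of the
#' 3-tap smoothing kernel (0.25, 0.5, 0.25), and normalizes to unit sum.
#'
#' @param values Numeric vector of per-cell feature values (non-empty).
#' @param bin_edges Strictly increasing edges covering the pooled range.
#' @return Object of class `feature_histogram`: list with `bin_edges`,
#'   `density` (unit sum), `n` (cell count).
#' @export
build_histogram <- function(values, bin_edges) {
  if (!length(values)) stop("empty well: no values to build a histogram from")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  counts <- tabulate(bin_index(values, bin_edges),
                     nbins = length(bin_edges) - 1L)
  sm <- smooth_counts(counts)
  structure(list(bin_edges = bin_edges, density = sm / sum(sm),
                 n = length(values)),
            class = "feature_histogram")
}

hist_mean <- function(h) {
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  sum(mids * h$density)
}

#' HistDiff score of a treatment histogram against a reference
#'
#' Signed sum of squared density differences over shared bins; the sign is
#' taken from the displacement of the treatment histogram mean relative to
#' the reference. Identical histograms score exactly 0, and
#' `|score| <= 2` for unit-normalized histograms.
#'
#' @param treatment,reference `feature_histogram` objects with identical
#'   bin edges.
#' @return A single dimensionless score.
#' @export
histdiff_score <- function(treatment, reference) {
  if (!isTRUE(all.equal(treatment$bin_edges, reference$bin_edges,
                        tolerance = 0))) {
    stop("treatment and reference histograms have mismatched bin edges")
  }
  ss <- sum((treatment$density - reference$density)^2)
  if (ss == 0) return(0)
  sign_val <- if (hist_mean(treatment) >= hist_mean(reference)) 1 else -1
  sign_val * ss
}

# Vectorized core: counts matrix (wells x bins) -> smoothed densities.
densify <- function(counts) {
  n <- ncol(counts)
  sm <- 0.5 * counts
  sm[, 1:(n - 1)] <- sm[, 1:(n - 1)] + 0.25 * counts[, 2:n, drop = FALSE]
  sm[, 2:n] <- sm[, 2:n] + 0.25 * counts[, 1:(n - 1), drop = FALSE]
  sm / rowSums(sm)
}

#' HistDiff fingerprints for one plate
#'
#' For every feature, builds a histogram per well over bins spanning the
#' plate's pooled value range, builds the reference histogram from the
#' pooled cells of all reference-control wells on the same plate, and
#' scores each non-dye well against it. Reference wells themselves are
#' scored against the leave-one-out reference pool (their own cells
#' removed), so that control scores are exchangeable with the null scores
#' of treated wells and thresholds derived from them are unbiased. Wells
#' with no cells yield an all-missing fingerprint, and wells below
#' `min_cells` are flagged; both flags are recorded in the matrix's
#' `flags` attribute for the QC stage (never silently zeroed).
#'
#' @param table A [single_cell_table()] for the plate.
#' @param platemap The plate's [plate_map()].
#' @param bins Histogram bin count (default 20).
#' @param min_cells Wells with fewer cells are flagged low-count.
#' @return A [fingerprint_matrix()] (wells x features) with a `flags`
#'   attribute and a `reference_n` attribute (reference pool cell count).
#' @export
fingerprint_plate <- function(table, platemap, bins = 20L, min_cells = 10L) {
  stopifnot(inherits(table, "single_cell_table"), inherits(platemap, "plate_map"))
  fn <- feature_names(table)
  target <- platemap$well[platemap$role != "dye_control"]
  ref_wells <- platemap$well[platemap$role == "reference_control"]
  is_ref_cell <- table$well %in% ref_wells
  if (!any(is_ref_cell)) {
    stop("no cells in any reference_control well; cannot build reference histograms")
  }
  wf <- factor(table$well, levels = target)
  in_plate <- !is.na(wf)
  wi <- as.integer(wf[in_plate])
  nw <- length(target)
  scores <- matrix(NA_real_, nw, length(fn),
                   dimnames = list(target, fn))
  ref_rows <- which(target %in% ref_wells)
  for (j in seq_along(fn)) {
    v <- table[[fn[j]]][in_plate]
    edges <- histogram_edges(v, bins)
    bi <- bin_index(v, edges)
    counts <- matrix(tabulate((wi - 1L) * bins + bi, nbins = nw * bins),
                     nw, bins, byrow = TRUE)
    n_cells <- rowSums(counts)
    ref_counts <- colSums(counts[ref_rows, , drop = FALSE])
    dens <- densify(counts)
    rdens <- smooth_counts(ref_counts)
    rdens <- rdens / sum(rdens)
    diff <- sweep(dens, 2, rdens, `-`)
    ss <- rowSums(diff^2)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    tmean <- as.vector(dens %*% mids)
    rmean_vec <- rep(sum(mids * rdens), nw)
    # reference wells score against the leave-one-out reference pool, so
    # control scores stay exchangeable with treated-well null scores
    if (length(ref_rows) > 1) {
      for (i in ref_rows) {
        c_loo <- ref_counts - counts[i, ]
        if (sum(c_loo) > 0) {
          rl <- smooth_counts(c_loo)
          rl <- rl / sum(rl)
          di <- dens[i, ] - rl
          ss[i] <- sum(di^2)
          rmean_vec[i] <- sum(mids * rl)
        }
      }
    }
    s <- ifelse(tmean >= rmean_vec, 1, -1) * ss
    s[ss == 0] <- 0
    s[n_cells == 0] <- NA_real_
    scores[, j] <- s
  }
  well_n <- tabulate(wi, nbins = nw)
  flags <- data.frame(well = target, n_cells = well_n,
                      flag = ifelse(well_n == 0, "empty",
                                    ifelse(well_n < min_cells, "low_count", "ok")),
                      stringsAsFactors = FALSE)
  n_flagged <- sum(flags$flag != "ok")
  if (n_flagged) {
    cp_log("warn", n_flagged, " well(s) empty or below ", min_cells,
           " cells; fingerprints flagged")
  }
  out <- fingerprint_matrix(scores, flags = flags)
  attr(out, "reference_n") <- sum(is_ref_cell)
  out
}

#' Block-normalized HistDiff fingerprints
#'
#' Splits the plate into row blocks (e.g. the brighter-stained stripe rows
#' vs the rest), runs [fingerprint_plate()] independently within each block
#' using only that block's reference wells, then concatenates the per-block
#' rows into one plate matrix. With the trivial single-block partition this
#' reduces exactly to [fingerprint_plate()].
#'
#' @param table A [single_cell_table()].
#' @param platemap A [plate_map()].
#' @param blocks List of character vectors of plate-row letters forming a
#'   partition (disjoint; jointly covering rows A-P).
#' @inheritParams fingerprint_plate
#' @return A [fingerprint_matrix()] covering every non-dye well exactly once.
#' @export
fingerprint_plate_blocked <- function(table, platemap, blocks, bins = 20L,
                                      min_cells = 10L) {
  rows_given <- unlist(blocks)
  if (anyDuplicated(rows_given)) {
    stop("blocks overlap on row(s): ",
         paste(unique(rows_given[duplicated(rows_given)]), collapse = ", "))
  }
  if (!setequal(rows_given, plate_rows)) {
    stop("blocks must partition plate rows A-P; missing: ",
         paste(setdiff(plate_rows, rows_given), collapse = ", "))
  }
  pieces <- vector("list", length(blocks))
  flags <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows_b <- blocks[[b]]
    pm_rows <- well_row(platemap$well) %in% rows_b
    if (!any(platemap$role[pm_rows] == "reference_control")) {
      stop("block ", b, " (rows ", paste(rows_b, collapse = ""),
           ") contains no reference_control wells")
    }
    sub_pm <- as.data.frame(platemap[pm_rows, , drop = FALSE])
    sub_tab <- table[well_row(table$well) %in% rows_b, , drop = FALSE]
    class(sub_tab) <- class(table)
    attr(sub_tab, "feature_names") <- feature_names(table)
    fp <- fingerprint_plate_core(sub_tab,
                                 target = sub_pm$well[sub_pm$role != "dye_control"],
                                 ref_wells = sub_pm$well[sub_pm$role == "reference_control"],
                                 bins, min_cells)
    pieces[[b]] <- fp
    flags[[b]] <- attr(fp, "flags")
  }
  m <- do.call(rbind, lapply(pieces, unclass))
  keep_order <- intersect(platemap$well, rownames(m))
  m <- m[keep_order, , drop = FALSE]
  fl <- do.call(rbind, flags)
  fl <- fl[match(keep_order, fl$well), , drop = FALSE]
  rownames(fl) <- NULL
  fingerprint_matrix(m, flags = fl)
}

# fingerprint_plate without the full-plate platemap validation: used on
# row-subset blocks.
fingerprint_plate_core <- function(table, target, ref_wells, bins, min_cells) {
  pm <- data.frame(well = target,
                   role = ifelse(target %in% ref_wells,
                                 "reference_control", "experimental"),
                   stringsAsFactors = FALSE)
  # reuse the main implementation through a duck-typed plate map
  pm_obj <- structure(pm, class = c("plate_map", "data.frame"))
  fingerprint_plate(table, pm_obj, bins = bins, min_cells = min_cells)
}
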