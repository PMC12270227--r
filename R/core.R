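#' @keywords internal
"_PACKAGE"

# ---- logging -----------------------------------------------------------

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Emit a structured log line
#'
#' Lightweight logger used throughout the pipeline. Messages go to stderr
#' (via [message()]) and, when `options(cpscreen.log_file=)` is set, are
#' appended to that file as well. The minimum level is controlled by
#' `options(cpscreen.log_level=)` (default `"info"`).
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Character fragments pasted into the message.
#' @return Invisibly, the formatted line.
#' @export
cp_log <- function(level = "info", ...) {
  level <- match.arg(level, names(log_levels))
  min_level <- getOption("cpscreen.log_level", "info")
  line <- sprintf("[cpscreen %s] %s", toupper(level), paste0(...))
  if (log_levels[[level]] >= log_levels[[min_level]]) message(line)
  log_file <- getOption("cpscreen.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE, sep = "")
  invisible(line)
}

# ---- well addresses ----------------------------------------------------

plate_rows <- LETTERS[1:16]

#' Well-name helpers for 384-well plates
#'
#' Wells are named letter + zero-padded column ("A01" ... "P24"), the
#' convention used by plate-reader exports.
#'
#' @param row Row letter(s), `"A"`-`"P"`.
#' @param column Column number(s), 1-24.
#' @return `well_name()` returns the well label; `well_row()` / `well_col()`
#'   decompose a label; `all_wells()` lists the full 384-well plate in
#'   row-major order.
#' @export
well_name <- function(row, column) {
  stopifnot(all(row %in% plate_rows), all(column %in% 1:24))
  sprintf("%s%02d", row, as.integer(column))
}

#' @rdname well_name
#' @param well Well label(s) such as `"B07"`.
#' @export
well_row <- function(well) substr(well, 1, 1)

#' @rdname well_name
#' @export
well_col <- function(well) as.integer(substr(well, 2, 3))

#' @rdname well_name
#' @export
all_wells <- function() {
  as.vector(t(outer(plate_rows, 1:24, well_name)))
}

is_valid_well <- function(well) {
  grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", well)
}

well_roles <- c("reference_control", "activator_control", "jump_control",
                "experimental", "dye_control")

# ---- plate maps --------------------------------------------------------

#' Construct and validate a plate map
#'
#' A plate map annotates every well of a 384-well plate with its role
#' (reference control, activator/positive control, JUMP replicate control,
#' experimental, or dye dispensing control), compound, dose and activation
#' condition. Reference-control wells are carrier-only and anchor all
#' HistDiff normalization; dye wells are excluded from all statistics.
#'
#' @param wells data.frame with columns `well`, `role`, `compound_id`,
#'   `dose_uM`, `condition`. `compound_id` may be `NA` for untreated wells.
#' @param plate_id Optional plate identifier stored as an attribute.
#' @return An object of class `plate_map` (a data.frame) with a
#'   `control_counts` attribute (named role-count vector).
#' @export
plate_map <- function(wells, plate_id = NULL) {
  req <- c("well", "role", "compound_id", "dose_uM", "condition")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    stop("plate map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  wells <- as.data.frame(wells)[req]
  wells$well <- as.character(wells$well)
  wells$compound_id <- as.character(wells$compound_id)
  wells$dose_uM <- as.numeric(wells$dose_uM)
  bad_well <- !is_valid_well(wells$well)
  if (any(bad_well)) {
    stop("invalid well label(s): ", paste(unique(wells$well[bad_well]), collapse = ", "))
  }
  bad_role <- !(wells$role %in% well_roles)
  if (any(bad_role)) {
    stop("unknown role(s) at row(s) ", paste(which(bad_role), collapse = ", "),
         ": ", paste(unique(wells$role[bad_role]), collapse = ", "))
  }
  if (anyDuplicated(wells$well)) {
    stop("duplicated well(s): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  }
  absent <- setdiff(all_wells(), wells$well)
  if (length(absent)) {
    stop("plate map does not cover the full plate; missing: ",
         paste(absent, collapse = ", "))
  }
  if (!any(wells$role == "reference_control")) {
    stop("plate map has no reference_control wells; HistDiff needs a reference population")
  }
  ref_with_compound <- wells$role == "reference_control" & !is.na(wells$compound_id)
  if (any(ref_with_compound)) {
    stop("reference_control wells must be carrier-only (compound_id NA): ",
         paste(wells$well[ref_with_compound], collapse = ", "))
  }
  if (any(!is.na(wells$dose_uM) & wells$dose_uM < 0)) stop("dose_uM must be >= 0")
  bad_cond <- !(wells$condition %in% c("resting", "activated"))
  if (any(bad_cond)) {
    stop("condition must be 'resting' or 'activated' at row(s) ",
         paste(which(bad_cond), collapse = ", "))
  }
  wells <- wells[order(match(wells$well, all_wells())), , drop = FALSE]
  rownames(wells) <- NULL
  structure(wells,
            control_counts = table(factor(wells$role, levels = well_roles)),
            plate_id = plate_id,
            class = c("plate_map", "data.frame"))
}

#' @export
print.plate_map <- function(x, ...) {
  cc <- attr(x, "control_counts")
  cat("cpscreen plate map", if (!is.null(attr(x, "plate_id")))
    paste0("(", attr(x, "plate_id"), ")"), "\n")
  cat("  wells:", nrow(x), "\n")
  for (r in names(cc)) if (cc[[r]] > 0) cat(sprintf("  %-18s %d\n", r, cc[[r]]))
  invisible(x)
}

#' Read a plate map from CSV
#'
#' Expects columns `well,role,compound_id,dose_uM,condition`; empty
#' `compound_id` fields become `NA`. Validation errors (missing wells, role
#' typos, no reference controls) name the offending rows.
#'
#' @param path Path to a CSV file.
#' @param plate_id Optional plate identifier.
#' @return A [plate_map()].
#' @export
read_platemap <- function(path, plate_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  plate_map(df, plate_id = plate_id)
}

#' Write a plate map to CSV
#' @param pm A [plate_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_platemap <- function(pm, path) {
  utils::write.csv(as.data.frame(pm), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Roles treated as plate controls
#'
#' Everything that is not an experimental or dye well: reference controls,
#' activator (positive) controls, and JUMP replicate controls.
#' @param pm A [plate_map()].
#' @return Character vector of control well labels.
#' @export
control_wells <- function(pm) {
  pm$well[pm$role %in% c("reference_control", "activator_control", "jump_control")]
}

# ---- single-cell tables ------------------------------------------------

#' Construct a single-cell feature table
#'
#' One row per segmented cell: a `well` label, a `cell` index within the
#' well, and `F` real-valued morphology/intensity/texture features. Rows
#' with missing feature values are dropped at construction (and logged), as
#' the fingerprinting stage requires complete vectors.
#'
#' @param well Character vector of well labels.
#' @param features Numeric matrix or data.frame of per-cell feature values
#'   with unique column names.
#' @param cell Optional integer cell index (default: running index per well).
#' @return A `single_cell_table`: data.frame with columns `well`, `cell`,
#'   then one column per feature; `feature_names` attribute records the
#'   feature axis order.
#' @export
single_cell_table <- function(well, features, cell = NULL) {
  features <- as.data.frame(features, optional = TRUE)
  fn <- names(features)
  if (is.null(fn) || any(!nzchar(fn))) stop("features must be named")
  if (anyDuplicated(fn)) {
    stop("duplicated feature name(s): ", paste(unique(fn[duplicated(fn)]), collapse = ", "))
  }
  if (fn[1] %in% c("well", "cell")) stop("feature names may not be 'well' or 'cell'")
  well <- as.character(well)
  bad <- !is_valid_well(well)
  if (any(bad)) {
    stop("unknown well label(s): ", paste(unique(well[bad]), collapse = ", "))
  }
  if (length(well) != nrow(features)) stop("well and features disagree on row count")
  keep <- stats::complete.cases(features)
  if (!all(keep)) {
    cp_log("warn", sum(!keep), " cell(s) dropped at ingest for missing feature values")
    well <- well[keep]
    features <- features[keep, , drop = FALSE]
    if (!is.null(cell)) cell <- cell[keep]
  }
  if (is.null(cell)) {
    cell <- stats::ave(seq_along(well), well, FUN = seq_along)
  }
  out <- data.frame(well = well, cell = as.integer(cell), features,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, feature_names = fn, class = c("single_cell_table", "data.frame"))
}

#' @export
print.single_cell_table <- function(x, ...) {
  cat("cpscreen single-cell table:", nrow(x), "cells,",
      length(feature_names(x)), "features,",
      length(unique(x$well)), "wells\n")
  invisible(x)
}

#' Feature axis of a table or fingerprint matrix
#' @param x A `single_cell_table` or fingerprint matrix.
#' @return Character vector of feature names in stable order.
#' @export
feature_names <- function(x) {
  fn <- attr(x, "feature_names")
  if (is.null(fn) && is.matrix(x)) fn <- colnames(x)
  fn
}

#' Read a per-cell feature table from delimited text
#'
#' Accepts CSV or TSV (by extension, or `sep`). The header must contain a
#' `well` column (and optionally `cell`); every remaining column is a
#' feature. Duplicate feature columns and unknown well labels are hard
#' errors; rows with missing feature values are dropped and logged with
#' their line numbers.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A [single_cell_table()].
#' @export
read_single_cell_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (!"well" %in% names(df)) stop("file has no 'well' column: ", path)
  meta <- intersect(c("well", "cell"), names(df))
  feat <- setdiff(names(df), meta)
  if (!length(feat)) stop("file has no feature columns: ", path)
  bad_rows <- which(!stats::complete.cases(df[feat]))
  if (length(bad_rows)) {
    cp_log("warn", "malformed rows dropped at ingest (file line numbers): ",
           paste(utils::head(bad_rows + 1L, 20), collapse = ", "))
  }
  single_cell_table(df$well, df[feat],
                    cell = if ("cell" %in% meta) df$cell else NULL)
}

#' Write a per-cell feature table to delimited text
#'
#' Full-precision (17 significant digit) output so that a write/read round
#' trip reproduces values bit-exactly.
#'
#' @param table A [single_cell_table()].
#' @param path Output path (`.tsv`/`.txt` gives tab separation, else comma).
#' @return Invisibly, `path`.
#' @export
write_single_cell_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- as.data.frame(table)
  for (f in feature_names(table)) df[[f]] <- format_full(df[[f]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

# ---- fingerprint matrices ----------------------------------------------

#' Construct a fingerprint matrix
#'
#' Rows are wells (or compound-dose-condition keys), columns are features,
#' entries are dimensionless HistDiff scores. `NA` rows are permitted only
#' as the documented empty-well flag propagated from fingerprinting.
#'
#' @param x Numeric matrix with row and column names.
#' @param flags Optional data.frame of per-well QC flags (`well`, `flag`).
#' @return A numeric matrix of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(x, flags = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || (nrow(x) > 0 && is.null(rownames(x)))) {
    stop("fingerprint matrix needs row (well) and column (feature) names")
  }
  if (anyDuplicated(colnames(x))) stop("duplicated feature names")
  structure(x, flags = flags, class = c("fingerprint_matrix", class(x)))
}

#' Write a fingerprint matrix as tab-delimited text
#'
#' Wells as rows, features as columns, full precision; the feature order is
#' persisted with the matrix.
#'
#' @param matrix A fingerprint matrix (wells x features).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fingerprints <- function(matrix, path) {
  m <- unclass(matrix)
  df <- data.frame(well = rownames(m), check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- format_full(m[, j])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprints()]
#' @param path Path to the TSV file.
#' @return A [fingerprint_matrix()].
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[setdiff(names(df), "well")])
  rownames(m) <- df$well
  fingerprint_matrix(m)
}

# ---- config ------------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are kept (stages may define their own); missing keys fall
#' back to the defaults returned by `default_config()`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_plates = 1L,
    n_features = 482L,
    cells_per_well_mean = 400,
    cells_per_well_dispersion = 10,
    bins = 20L,
    min_cells = 10L,
    threshold_method = "iqr",
    fdr_q = 0.05,
    collinearity_cut = 0.8,
    embed_components = 100L,
    min_cluster_size = 5L,
    alpha = 0.05
  )
}

#' Persist the effective configuration of a run
#' @param config Named list.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
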