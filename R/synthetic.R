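# Synthetic activated Cell Painting screen with planted ground truth.
# Every stochastic generator takes an explicit seed; identical seeds give
# identical output. Planted truth (compound effects, cell labels) always
# travels with the generated data so downstream recovery is measurable.

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 100003 + salt) %% 2147483629)
}

#' Declare the planted effect of one compound
#'
#' Effects are expressed in reference-population units: `shift` moves the
#' affected features by that many control standard deviations, `scale`
#' multiplies their spread. `specificity` states in which activation
#' condition the phenotype appears; `cytotoxicity` is the fractional
#' reduction of the well's expected cell count whenever the effect is
#' active.
#'
#' @param compound_id Compound identifier.
#' @param features Character vector of affected feature names (may be empty).
#' @param shift Location shift in control-SD units.
#' @param scale SD multiplier for affected features.
#' @param specificity One of `"both"`, `"activated_only"`, `"resting_only"`,
#'   `"none"`. `"none"` requires a zero shift and unit scale.
#' @param cytotoxicity Fraction in `[0, 1]` by which the expected cell count
#'   is reduced.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(compound_id, features = character(), shift = 0,
                         scale = 1, specificity = "both", cytotoxicity = 0) {
  specificity <- match.arg(specificity,
                           c("both", "activated_only", "resting_only", "none"))
  stopifnot(is.finite(shift), is.finite(scale), scale > 0,
            cytotoxicity >= 0, cytotoxicity <= 1)
  if (specificity == "none" && (shift != 0 || scale != 1)) {
    stop("specificity 'none' requires shift = 0 and scale = 1")
  }
  structure(list(compound_id = compound_id, features = features,
                 shift = shift, scale = scale, specificity = specificity,
                 cytotoxicity = cytotoxicity),
            class = "effect_model")
}

effect_applies <- function(effect, condition) {
  switch(effect$specificity,
         both = TRUE,
         activated_only = condition == "activated",
         resting_only = condition == "resting",
         none = FALSE)
}

#' Default compartment-prefixed feature names
#'
#' Feature axis used by generated screens: names cycle through the stained
#' compartment prefixes `ER_`, `Nuc_`, `Mito_`, `AGP_`, `RNA_`.
#' @param n_features Number of features.
#' @return Character vector of feature names.
#' @export
default_feature_names <- function(n_features) {
  prefixes <- c("ER_", "Nuc_", "Mito_", "AGP_", "RNA_")
  sprintf("%sf%04d", prefixes[(seq_len(n_features) - 1L) %% 5L + 1L],
          seq_len(n_features))
}

#' Define a synthetic screen
#'
#' Fixes everything a screen needs to be simulated reproducibly: plate
#' count, the feature axis (default 482 features named by stained
#' compartment: ER_, Nuc_, Mito_, AGP_, RNA_), per-feature base
#' distributions (drawn once from the design seed), the control layout of
#' each 384-well plate, the compound list with planted [effect_model()]s,
#' target-class assignments, the global activation signature, and the
#' cells-per-well distribution (negative binomial, mean 400, dispersion 10
#' by default, so counts are over-dispersed as in real plates).
#'
#' The activation signature is a fixed +1 SD shift applied to a fixed 30%
#' of features in every activated well (echoing a broad PKC-agonist
#' response across all stained compartments). Activator-control wells have
#' their activation state flipped relative to the plate's condition, which
#' reproduces the screen's positive-control design (activator in wells of
#' the resting plate and vice versa).
#'
#' @param n_plates Number of plates per condition.
#' @param n_features Number of morphology features (default 482).
#' @param compounds Optional data.frame with columns `compound_id` and
#'   (optionally) `class`. Defaults to enough inert compounds to fill the
#'   experimental wells.
#' @param effects Named list of [effect_model()]s, keyed by compound id.
#'   Compounds without an entry are inert.
#' @param cells_per_well_mean,cells_per_well_dispersion Negative-binomial
#'   cell-count parameters (mean, size).
#' @param n_reference,n_jump,n_activator Control-template counts per plate
#'   (reference/carrier, JUMP replicate, activator-flipped positive). The
#'   default 32 + 24 + 8 gives 64 control wells, 318 experimental wells and
#'   2 dye wells per plate.
#' @param activation_fraction Fraction of features carrying the activation
#'   signature.
#' @param activation_shift Activation signature magnitude in SD units.
#' @param base_dist `"normal"` or `"lognormal"` per-feature null
#'   distribution (log-normal models intensity-like skew).
#' @param dose_uM Dose annotated on experimental wells.
#' @param seed Screen-level seed; fixes the feature axis, base
#'   distributions and activation signature.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(n_plates = 1L, n_features = 482L, compounds = NULL,
                          effects = list(),
                          cells_per_well_mean = 400,
                          cells_per_well_dispersion = 10,
                          n_reference = 32L, n_jump = 24L, n_activator = 8L,
                          activation_fraction = 0.3, activation_shift = 1,
                          base_dist = c("normal", "lognormal"),
                          dose_uM = 10, seed = 1L) {
  base_dist <- match.arg(base_dist)
  stopifnot(n_features >= 1, n_plates >= 1, n_reference >= 0,
            n_jump %% 3L == 0L || n_jump == 0L)
  feature_names <- default_feature_names(n_features)
  n_exp <- 384L - 2L - n_reference - n_jump - n_activator
  if (n_exp <= 0) stop("control template leaves no experimental wells")
  if (is.null(compounds)) {
    compounds <- data.frame(
      compound_id = sprintf("CMP%05d", seq_len(n_exp * n_plates)),
      class = NA_character_, stringsAsFactors = FALSE)
    # auto-generated filler compounds are inert by construction
    inert <- setdiff(compounds$compound_id, names(effects))
    effects[inert] <- lapply(inert, function(id) {
      effect_model(id, specificity = "none")
    })
  }
  compounds <- as.data.frame(compounds)
  if (!"class" %in% names(compounds)) compounds$class <- NA_character_
  if (anyDuplicated(compounds$compound_id)) stop("duplicated compound ids")
  if (nrow(compounds) > n_exp * n_plates) {
    stop("more compounds (", nrow(compounds), ") than experimental wells (",
         n_exp * n_plates, ")")
  }
  jump_ids <- if (n_jump > 0) sprintf("JUMP%02d", seq_len(n_jump %/% 3L)) else character()
  set.seed(derive_seed(seed, 1L))
  mu <- stats::runif(n_features, 100, 1000)
  sigma <- stats::runif(n_features, 10, 100)
  n_act <- max(1L, round(activation_fraction * n_features))
  activation_features <- sort(sample.int(n_features, n_act))
  # JUMP replicate controls carry distinctive, reproducible phenotypes
  jump_effects <- lapply(seq_along(jump_ids), function(i) {
    effect_model(jump_ids[i],
                 features = feature_names[sort(sample.int(n_features,
                                                          max(5L, n_features %/% 25L)))],
                 shift = 2, specificity = "both")
  })
  names(jump_effects) <- jump_ids
  names(mu) <- names(sigma) <- feature_names
  structure(list(
    n_plates = as.integer(n_plates),
    feature_names = feature_names,
    mu = mu, sigma = sigma, base_dist = base_dist,
    activation_features = feature_names[activation_features],
    activation_shift = activation_shift,
    cells_per_well_mean = cells_per_well_mean,
    cells_per_well_dispersion = cells_per_well_dispersion,
    n_reference = as.integer(n_reference), n_jump = as.integer(n_jump),
    n_activator = as.integer(n_activator), n_experimental = n_exp,
    compounds = compounds, effects = effects, jump_ids = jump_ids,
    jump_effects = jump_effects, dose_uM = dose_uM, seed = as.integer(seed)
  ), class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("cpscreen synthetic screen design\n")
  cat("  plates:", x$n_plates, " features:", length(x$feature_names), "\n")
  cat("  wells/plate: ", x$n_reference, " reference + ", x$n_jump, " JUMP + ",
      x$n_activator, " activator controls, ", x$n_experimental,
      " experimental, 2 dye\n", sep = "")
  cat("  compounds:", nrow(x$compounds), "(", length(x$effects), "with planted effects )\n")
  invisible(x)
}

#' Planted-truth table of a design
#'
#' One row per compound with its planted effect parameters; the ground
#' truth downstream recovery is measured against.
#'
#' @param design A [screen_design()].
#' @return data.frame with columns `compound_id`, `class`, `specificity`,
#'   `shift`, `scale`, `cytotoxicity`, `n_affected`.
#' @export
effect_truth <- function(design) {
  eff <- design$effects
  get <- function(id, field, default) {
    if (!is.null(eff[[id]])) eff[[id]][[field]] else default
  }
  data.frame(
    compound_id = design$compounds$compound_id,
    class = design$compounds$class,
    specificity = vapply(design$compounds$compound_id, get, "", field = "specificity",
                         default = "none"),
    shift = vapply(design$compounds$compound_id, get, 0, field = "shift", default = 0),
    scale = vapply(design$compounds$compound_id, get, 0, field = "scale", default = 1),
    cytotoxicity = vapply(design$compounds$compound_id, get, 0,
                          field = "cytotoxicity", default = 0),
    n_affected = vapply(design$compounds$compound_id,
                        function(id) length(get(id, "features", character())), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen design with the standard planted composition
#'
#' Convenience constructor for the benchmark synthetic screen used
#' throughout the test suite: compounds active in both conditions, only
#' under activation, only at rest, plus inert filler, each active compound
#' shifting a random feature subset by a fixed number of control SDs.
#'
#' @param n_both,n_activated_only,n_resting_only,n_inert Category sizes
#'   (defaults 50 / 30 / 20 / 900).
#' @param shift Planted effect size in SD units (default 1.5).
#' @param n_affected Number of affected features per active compound
#'   (default 20).
#' @param n_cytotoxic How many of the `both`-active compounds additionally
#'   get a 0.6 cytotoxic cell-count reduction.
#' @param classes Optional integer: organise active compounds into target
#'   classes of this size (members share their affected features).
#' @param ... Passed on to [screen_design()].
#' @return A [screen_design()].
#' @export
planted_screen_design <- function(n_both = 50L, n_activated_only = 30L,
                                  n_resting_only = 20L, n_inert = 900L,
                                  shift = 1.5, n_affected = 20L,
                                  n_cytotoxic = 0L, classes = NULL, ...) {
  args <- list(...)
  seed <- if (!is.null(args$seed)) args$seed else 1L
  n_features <- if (!is.null(args$n_features)) args$n_features else 482L
  spec <- c(rep("both", n_both), rep("activated_only", n_activated_only),
            rep("resting_only", n_resting_only), rep("none", n_inert))
  n <- length(spec)
  ids <- sprintf("CMP%05d", seq_len(n))
  cls <- rep(NA_character_, n)
  fn <- default_feature_names(n_features)
  set.seed(derive_seed(seed, 2L))
  active <- which(spec != "none")
  effects <- list()
  class_features <- NULL
  for (k in seq_along(active)) {
    i <- active[k]
    if (!is.null(classes)) {
      cls_idx <- (k - 1L) %/% classes + 1L
      cls[i] <- sprintf("class%03d", cls_idx)
      if ((k - 1L) %% classes == 0L) {
        class_features <- fn[sort(sample.int(n_features, n_affected))]
      }
      feats <- class_features
    } else {
      feats <- fn[sort(sample.int(n_features, n_affected))]
    }
    effects[[ids[i]]] <- effect_model(
      ids[i], features = feats, shift = shift, specificity = spec[i],
      cytotoxicity = if (k <= n_cytotoxic) 0.6 else 0)
  }
  for (i in which(spec == "none")) {
    effects[[ids[i]]] <- effect_model(ids[i], specificity = "none")
  }
  compounds <- data.frame(compound_id = ids, class = cls,
                          stringsAsFactors = FALSE)
  n_plates <- if (!is.null(args$n_plates)) args$n_plates else
    ceiling(n / (384L - 2L - 64L))
  args$n_plates <- n_plates
  do.call(screen_design,
          c(list(compounds = compounds, effects = effects), args))
}

#' Generate a randomized plate map from a design
#'
#' Dye dispensing controls sit at A01 and P24; all other roles are placed
#' at randomized positions (a seeded shuffle stands in for the study's MILP
#' plate-randomization program). JUMP controls are laid out as three
#' replicate wells per JUMP compound. Experimental wells receive the
#' design's compounds in plate-sized chunks; surplus wells are annotated as
#' untreated experimental wells.
#'
#' @param design A [screen_design()].
#' @param plate_index 1-based plate number; determinism is per
#'   `(design seed, plate_index)`.
#' @param condition Plate activation condition annotation.
#' @return A [plate_map()].
#' @export
generate_platemap <- function(design, plate_index, condition = "resting") {
  stopifnot(inherits(design, "screen_design"),
            plate_index >= 1, plate_index <= design$n_plates)
  if (design$n_reference < 1) {
    stop("control template has no reference_control wells")
  }
  set.seed(derive_seed(design$seed, 1000L + plate_index))
  wells <- all_wells()
  dye <- c("A01", "P24")
  open <- setdiff(wells, dye)
  n_ctrl <- design$n_reference + design$n_jump + design$n_activator
  ctrl_pos <- sample(open, n_ctrl)
  ref_pos <- ctrl_pos[seq_len(design$n_reference)]
  jump_pos <- ctrl_pos[design$n_reference + seq_len(design$n_jump)]
  act_pos <- ctrl_pos[design$n_reference + design$n_jump +
                        seq_len(design$n_activator)]
  exp_pos <- sample(setdiff(open, ctrl_pos))
  i0 <- (plate_index - 1L) * design$n_experimental
  idx <- i0 + seq_len(design$n_experimental)
  cmp <- design$compounds$compound_id[idx[idx <= nrow(design$compounds)]]
  cmp <- c(cmp, rep(NA_character_, design$n_experimental - length(cmp)))
  jump_cmp <- if (design$n_jump > 0) {
    sample(rep(design$jump_ids, each = 3L))
  } else character()
  df <- data.frame(well = wells, role = "experimental",
                   compound_id = NA_character_, dose_uM = design$dose_uM,
                   condition = condition, stringsAsFactors = FALSE)
  rownames(df) <- df$well
  df[dye, "role"] <- "dye_control"
  df[dye, "dose_uM"] <- 0
  df[ref_pos, "role"] <- "reference_control"
  df[ref_pos, "dose_uM"] <- 0
  df[act_pos, "role"] <- "activator_control"
  df[act_pos, "dose_uM"] <- 0
  if (length(jump_pos)) {
    df[jump_pos, "role"] <- "jump_control"
    df[jump_pos, "compound_id"] <- jump_cmp
  }
  df[exp_pos, "compound_id"] <- cmp
  plate_map(df, plate_id = sprintf("P%02d_%s", plate_index, condition))
}

#' Simulate the single-cell feature table of one plate
#'
#' Reference wells draw every feature from the design's base distribution.
#' Treated wells apply their compound's planted shift (in control-SD units)
#' and scale, honouring the effect's condition specificity. In the
#' activated condition the global activation signature (a fixed SD shift on
#' a fixed feature subset) is applied to all wells, so that same-plate
#' reference normalization cancels it; activator-control wells get the
#' signature in the opposite condition (the positive-control design). Cell
#' counts are negative-binomial, with the expectation reduced by the
#' compound's cytotoxicity fraction whenever its effect is active.
#'
#' @param design A [screen_design()].
#' @param platemap A [plate_map()] produced by [generate_platemap()].
#' @param condition `"resting"` or `"activated"`.
#' @param seed Seed for this plate's draw.
#' @return A [single_cell_table()].
#' @export
simulate_single_cells <- function(design, platemap, condition, seed) {
  condition <- match.arg(condition, c("resting", "activated"))
  stopifnot(inherits(design, "screen_design"), inherits(platemap, "plate_map"))
  set.seed(derive_seed(seed, 3L))
  nf <- length(design$feature_names)
  act_idx <- match(design$activation_features, design$feature_names)
  effects <- c(design$effects, design$jump_effects)
  out_well <- list(); out_mat <- list()
  for (i in seq_len(nrow(platemap))) {
    role <- platemap$role[i]
    if (role == "dye_control") next
    cmp <- platemap$compound_id[i]
    eff <- if (!is.na(cmp)) effects[[cmp]] else NULL
    if (!is.na(cmp) && is.null(eff) && role == "experimental") {
      stop("no effect model for compound ", cmp, " (well ", platemap$well[i], ")")
    }
    applies <- !is.null(eff) && effect_applies(eff, condition)
    cyto <- if (applies) eff$cytotoxicity else 0
    n <- stats::rnbinom(1, size = design$cells_per_well_dispersion,
                        mu = design$cells_per_well_mean * (1 - cyto))
    if (n == 0) next
    z <- matrix(stats::rnorm(n * nf), n, nf)
    if (applies && length(eff$features)) {
      j <- match(eff$features, design$feature_names)
      z[, j] <- eff$shift + eff$scale * z[, j, drop = FALSE]
    }
    activated_state <- (condition == "activated") != (role == "activator_control")
    if (activated_state && length(act_idx)) {
      z[, act_idx] <- z[, act_idx, drop = FALSE] + design$activation_shift
    }
    x <- if (design$base_dist == "normal") {
      sweep(sweep(z, 2, design$sigma, `*`), 2, design$mu, `+`)
    } else {
      exp(sweep(sweep(z, 2, design$sigma / design$mu, `*`), 2,
                log(design$mu), `+`))
    }
    out_well[[length(out_well) + 1L]] <- rep(platemap$well[i], n)
    out_mat[[length(out_mat) + 1L]] <- x
  }
  m <- do.call(rbind, out_mat)
  colnames(m) <- design$feature_names
  single_cell_table(unlist(out_well), m)
}

#' Add a staining-stripe artifact to selected plate rows
#'
#' Models the brighter-staining stripes occasionally seen across a plate:
#' every cell in the named rows has `offset` added to its features; other
#' cells are untouched.
#'
#' @param table A [single_cell_table()].
#' @param rows Plate-row letters (`"A"`-`"P"`), non-empty.
#' @param offset Either a single number applied to every feature or a named
#'   numeric vector of per-feature additive shifts (unnamed features are
#'   left alone).
#' @return The modified [single_cell_table()].
#' @export
inject_stripe_artifact <- function(table, rows, offset) {
  stopifnot(inherits(table, "single_cell_table"), length(rows) >= 1)
  bad <- setdiff(rows, plate_rows)
  if (length(bad)) stop("unknown plate row(s): ", paste(bad, collapse = ", "))
  fn <- feature_names(table)
  if (is.null(names(offset))) {
    off <- rep_len(offset, length(fn))
    names(off) <- fn
  } else {
    bad_f <- setdiff(names(offset), fn)
    if (length(bad_f)) stop("unknown feature(s) in offset: ",
                            paste(bad_f, collapse = ", "))
    off <- structure(rep(0, length(fn)), names = fn)
    off[names(offset)] <- offset
  }
  hit <- well_row(table$well) %in% rows
  for (f in fn[off != 0]) table[[f]][hit] <- table[[f]][hit] + off[[f]]
  table
}

# ---- brightfield (ChP2) generator --------------------------------------

bf_panel <- function() {
  morph <- c(area = 800, roundness = 0.9, perimeter = 120, width = 25,
             length = 35, width_length_ratio = 0.75)
  morph_sd <- c(200, 0.05, 20, 5, 7, 0.1)
  intens <- c(int_mean = 15000, int_sd = 2000, int_cv = 0.13,
              int_median = 14800, int_sum = 6e6, int_max = 22000,
              int_min = 11000, int_q50 = 14800, int_contrast = 0.25)
  intens_sd <- c(1200, 300, 0.02, 1200, 1e6, 2000, 800, 1200, 0.05)
  text <- c(ser_spot = 1, ser_hole = 1, ser_edge = 1, ser_ridge = 1,
            ser_valley = 1, ser_saddle = 1, ser_bright = 1, ser_dark = 1)
  text_sd <- rep(0.3, 8)
  list(mean = c(morph, intens, text),
       sd = c(morph_sd, intens_sd, text_sd),
       # features on which the two phenotypes actually differ: three
       # texture (dark, valley, edge) and four intensity (mean, median,
       # contrast, maximum) measurements
       discriminative = c("ser_dark", "ser_valley", "ser_edge",
                          "int_mean", "int_median", "int_contrast", "int_max"))
}

#' The 23-feature brightfield classifier panel
#'
#' Six morphology, nine intensity and eight texture features measured per
#' putative cell in the brightfield activation checkpoint.
#' @return Character vector of 23 feature names.
#' @export
bf_classifier_features <- function() names(bf_panel()$mean)

#' Simulate brightfield cell records for the activation checkpoint
#'
#' Draws per-cell records of the 23 classifier features from two
#' overlapping multivariate normal populations (resting vs activated; the
#' activated population is displaced by `separation` SDs on the
#' discriminative texture/intensity features). A configurable fraction of
#' junk objects is planted: oversized (area > 2000) or dark (brightfield
#' mean < 10000) putative cells that the prefilter should remove. The
#' ground-truth phenotype label and junk flag are stored with each cell.
#'
#' @param activation_fraction Numeric vector, one entry per well, of true
#'   activated-cell fractions; names are used as well labels (default
#'   `A03`, `A04`, ...).
#' @param n_cells Cells per well.
#' @param junk_rate Probability that a cell is replaced by a junk object.
#' @param separation Population separation in SD units on the
#'   discriminative features.
#' @param seed Seed.
#' @return data.frame of class `brightfield_cell_table` with columns
#'   `well`, the 23 features, `true_label`, `true_junk`.
#' @export
simulate_brightfield_cells <- function(activation_fraction, n_cells = 200L,
                                       junk_rate = 0, separation = 2,
                                       seed = 1L) {
  stopifnot(all(activation_fraction >= 0), all(activation_fraction <= 1))
  set.seed(derive_seed(seed, 4L))
  p <- bf_panel()
  wells <- names(activation_fraction)
  if (is.null(wells)) {
    wells <- all_wells()[2 + seq_along(activation_fraction)]
  }
  res <- list()
  for (w in seq_along(activation_fraction)) {
    lab <- ifelse(stats::runif(n_cells) < activation_fraction[w],
                  "activated", "resting")
    m <- matrix(stats::rnorm(n_cells * length(p$mean)), n_cells)
    m <- sweep(sweep(m, 2, p$sd, `*`), 2, p$mean, `+`)
    colnames(m) <- names(p$mean)
    act <- lab == "activated"
    for (f in p$discriminative) {
      m[act, f] <- m[act, f] + separation * p$sd[[match(f, names(p$mean))]]
    }
    junk <- stats::runif(n_cells) < junk_rate
    if (any(junk)) {
      oversized <- junk & stats::runif(n_cells) < 0.5
      dark <- junk & !oversized
      m[oversized, "area"] <- stats::runif(sum(oversized), 2100, 4000)
      m[dark, "int_mean"] <- stats::runif(sum(dark), 4000, 9500)
    }
    m[, "area"] <- pmax(m[, "area"], 101)
    res[[w]] <- data.frame(well = wells[w], m, true_label = lab,
                           true_junk = junk, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("brightfield_cell_table", "data.frame")
  out
}

# ---- GR assay generator ------------------------------------------------

gr_criteria <- function() {
  c(sum_vs_hoechst = 0.35, sum_ratio = 0.25, mean_ratio = 1.7,
    median_ratio = 1.7, quantile_ratio = 1.7, contrast_ratio = 0.3)
}

#' Simulate per-cell glucocorticoid-receptor assay records
#'
#' Each simulated cell is drawn from a "nuclear-enriched" regime (all six
#' classification ratios strictly above their thresholds) with probability
#' `nuclear_enriched_fraction`, otherwise from a regime violating at least
#' one criterion. The raw nuclear/cytoplasmic intensity fields are
#' reconstructed from the sampled ratios, and the ground-truth label is
#' stored.
#'
#' @param n_cells Number of cells.
#' @param nuclear_enriched_fraction Probability of the enriched regime.
#' @param seed Seed.
#' @return data.frame with the eleven intensity fields of a GR cell record
#'   plus `true_nuclear`.
#' @export
simulate_gr_cells <- function(n_cells, nuclear_enriched_fraction, seed = 1L) {
  stopifnot(nuclear_enriched_fraction >= 0, nuclear_enriched_fraction <= 1)
  set.seed(derive_seed(seed, 5L))
  thr <- gr_criteria()
  pass <- stats::runif(n_cells) < nuclear_enriched_fraction
  ratios <- matrix(NA_real_, n_cells, 6,
                   dimnames = list(NULL, names(thr)))
  for (j in 1:6) {
    ratios[, j] <- thr[j] * stats::runif(n_cells, 1.15, 2.0)
  }
  fail <- which(!pass)
  if (length(fail)) {
    # guarantee at least one violated criterion; others may fail too
    forced <- sample.int(6, length(fail), replace = TRUE)
    for (k in seq_along(fail)) {
      i <- fail[k]
      low <- stats::runif(6) < 0.35
      low[forced[k]] <- TRUE
      ratios[i, low] <- thr[low] * stats::runif(sum(low), 0.3, 0.9)
    }
  }
  gr_cyto_sum <- stats::runif(n_cells, 1e5, 1e6)
  gr_cyto_mean <- stats::runif(n_cells, 800, 1500)
  gr_cyto_median <- stats::runif(n_cells, 700, 1400)
  gr_cyto_quantile <- stats::runif(n_cells, 900, 1600)
  gr_cyto_contrast <- stats::runif(n_cells, 0.1, 0.5)
  gr_nuc_sum <- ratios[, "sum_ratio"] * gr_cyto_sum
  data.frame(
    hoechst_nuc_sum = gr_nuc_sum / ratios[, "sum_vs_hoechst"],
    gr_nuc_mean = ratios[, "mean_ratio"] * gr_cyto_mean,
    gr_nuc_median = ratios[, "median_ratio"] * gr_cyto_median,
    gr_nuc_sum = gr_nuc_sum,
    gr_nuc_quantile = ratios[, "quantile_ratio"] * gr_cyto_quantile,
    gr_nuc_contrast = ratios[, "contrast_ratio"] * gr_cyto_contrast,
    gr_cyto_mean = gr_cyto_mean, gr_cyto_median = gr_cyto_median,
    gr_cyto_sum = gr_cyto_sum, gr_cyto_quantile = gr_cyto_quantile,
    gr_cyto_contrast = gr_cyto_contrast,
    true_nuclear = pass, stringsAsFactors = FALSE)
}
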