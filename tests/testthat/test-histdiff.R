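make_hist <- function(density, edges = seq(0, length(density), by = 1)) {
  structure(list(bin_edges = edges, density = density, n = 100),
            class = "feature_histogram")
}

test_that("histogram construction respects binning and smoothing conventions", {
  edges <- seq(0, 10, length.out = 6)
  # all values in one bin: one-hot blurred by the 3-tap kernel
  h <- build_histogram(rep(0.5, 50), edges)
  expect_equal(h$density, c(2/3, 1/3, 0, 0, 0))
  # a value exactly on the max edge is counted in the last bin
  h2 <- build_histogram(c(10, 10, 10), edges)
  expect_equal(which.max(h2$density), 5)
  # uniform data: interior bins flat, edge bins lose kernel mass
  # (expected density 1/4.5 interior, 0.75/4.5 at the two edge bins)
  set.seed(1)
  h3 <- build_histogram(runif(40000, 0, 10), edges)
  expect_true(all(abs(h3$density - c(0.75, 1, 1, 1, 0.75) / 4.5) < 0.01))
  expect_equal(sum(h3$density), 1)
  expect_error(build_histogram(numeric(0), edges), "empty well")
})

test_that("the HistDiff score follows its signed squared-difference contract", {
  t0 <- make_hist(c(0.25, 0.25, 0.25, 0.25))
  expect_identical(histdiff_score(t0, t0), 0)
  # treatment shifted to higher bins scores positive
  expect_gt(histdiff_score(make_hist(c(0, 0.25, 0.25, 0.5)), t0), 0)
  # hand case: opposite halves, treatment mean lower -> -1.0 exactly
  tt <- make_hist(c(0.5, 0.5, 0, 0))
  rr <- make_hist(c(0, 0, 0.5, 0.5))
  expect_equal(histdiff_score(tt, rr), -1.0)
  expect_equal(histdiff_score(rr, tt), 1.0)
  # mismatched edges refuse to compare
  expect_error(histdiff_score(tt, make_hist(c(0, 0, 0.5, 0.5), edges = 0:4 * 2)),
               "mismatched")
})

test_that("the score is bounded by 2 for unit histograms", {
  set.seed(2)
  for (i in 1:200) {
    a <- runif(8); b <- runif(8)
    s <- histdiff_score(make_hist(a / sum(a), 0:8), make_hist(b / sum(b), 0:8))
    expect_lte(abs(s), 2)
  }
})

test_that("plate fingerprints recover planted feature shifts", {
  eff <- list(hit = effect_model("hit", features = default_feature_names(30)[1:10],
                                 shift = 2))
  d <- screen_design(n_plates = 1, n_features = 30,
                     compounds = data.frame(compound_id = "hit"),
                     effects = eff, cells_per_well_mean = 400,
                     n_jump = 0, n_activator = 0, seed = 20)
  pm <- generate_platemap(d, 1, "resting")
  tab <- simulate_single_cells(d, pm, "resting", seed = 21)
  fp <- fingerprint_plate(tab, pm)
  w <- pm$well[!is.na(pm$compound_id)]
  ranked <- names(sort(abs(fp[w, ]), decreasing = TRUE))
  expect_setequal(ranked[1:10], default_feature_names(30)[1:10])
  # planted upward shifts give positive scores on affected features
  expect_true(all(fp[w, default_feature_names(30)[1:10]] > 0))
})

test_that("identical wells produce identical fingerprints", {
  df <- full_plate_df(n_ref = 4)
  pm <- plate_map(df)
  set.seed(22)
  vals <- rnorm(40)
  tab <- single_cell_table(
    rep(c("A02", "A03", "A04", "A05", "B02", "B03"), each = 40),
    data.frame(f1 = c(rnorm(160), vals, vals)))
  fp <- fingerprint_plate(tab, pm)
  expect_identical(fp["B02", ], fp["B03", ])
})

test_that("null reference wells are calibrated around zero", {
  meds <- c(); pos <- c()
  for (s in 1:12) {
    d <- screen_design(n_plates = 1, n_features = 20,
                       cells_per_well_mean = 400, n_jump = 0,
                       n_activator = 0, seed = s)
    pm <- generate_platemap(d, 1, "resting")
    tab <- simulate_single_cells(d, pm, "resting", seed = 50 + s)
    fp <- fingerprint_plate(tab, pm)
    refw <- intersect(pm$well[pm$role == "reference_control"], rownames(fp))
    meds <- c(meds, median(fp[refw, ]))
    pos <- c(pos, mean(fp[refw, ] > 0))
  }
  expect_lt(abs(median(meds)), 0.05)
  expect_gt(mean(pos), 0.4)
  expect_lt(mean(pos), 0.6)
})

test_that("|score| grows monotonically with the planted shift", {
  shifts <- c(0, 0.5, 1, 2)
  med_by_shift <- sapply(shifts, function(sh) {
    med <- vapply(1:8, function(s) {
      eff <- list(x = effect_model("x", features = "ER_f0001", shift = sh))
      d <- screen_design(n_plates = 1, n_features = 5,
                         compounds = data.frame(compound_id = "x"),
                         effects = eff, cells_per_well_mean = 300,
                         n_jump = 0, n_activator = 0, seed = s)
      pm <- generate_platemap(d, 1, "resting")
      tab <- simulate_single_cells(d, pm, "resting", seed = 60 + s)
      fp <- fingerprint_plate(tab, pm)
      w <- pm$well[!is.na(pm$compound_id)]
      abs(fp[w, "ER_f0001"])
    }, 0)
    median(med)
  })
  expect_true(all(diff(med_by_shift) > 0))
})

test_that("block normalization removes a planted staining stripe", {
  d <- screen_design(n_plates = 1, n_features = 20, cells_per_well_mean = 200,
                     n_jump = 0, n_activator = 0, n_reference = 32, seed = 30)
  pm <- generate_platemap(d, 1, "resting")
  blocks <- list(LETTERS[1:4], LETTERS[5:16])
  ps_blocked <- c(); ps_unblocked <- c()
  for (s in 1:6) {
    tab <- simulate_single_cells(d, pm, "resting", seed = 70 + s)
    striped <- inject_stripe_artifact(
      tab, LETTERS[1:4], setNames(2 * d$sigma, d$feature_names))
    fp_s <- fingerprint_plate_blocked(striped, pm, blocks)
    fp_c <- fingerprint_plate_blocked(tab, pm, blocks)
    fp_u <- fingerprint_plate(striped, pm)
    refB <- intersect(pm$well[pm$role == "reference_control"],
                      rownames(fp_s)[well_row(rownames(fp_s)) %in% LETTERS[1:4]])
    ps_blocked <- c(ps_blocked, suppressWarnings(
      ks.test(as.vector(fp_s[refB, ]), as.vector(fp_c[refB, ]))$p.value))
    ps_unblocked <- c(ps_unblocked, suppressWarnings(
      ks.test(as.vector(fp_u[refB, ]), as.vector(fp_c[refB, ]))$p.value))
  }
  # blocked processing re-centres the striped reference wells ...
  expect_gt(median(ps_blocked), 0.01)
  # ... while unblocked processing leaves them visibly biased
  expect_lt(median(ps_unblocked), 1e-6)
})

test_that("blocked fingerprinting is consistent with the unblocked path", {
  d <- screen_design(n_plates = 1, n_features = 10, cells_per_well_mean = 150,
                     n_jump = 0, n_activator = 0, seed = 31)
  pm <- generate_platemap(d, 1, "resting")
  tab <- simulate_single_cells(d, pm, "resting", seed = 80)
  fp1 <- fingerprint_plate(tab, pm)
  fp2 <- fingerprint_plate_blocked(tab, pm, list(LETTERS[1:16]))
  expect_equal(unclass(fp1)[rownames(fp2), ], unclass(fp2)[, ],
               tolerance = 0)
  # every well appears exactly once
  fp3 <- fingerprint_plate_blocked(tab, pm, list(LETTERS[1:8], LETTERS[9:16]))
  expect_false(anyDuplicated(rownames(fp3)) > 0)
  expect_setequal(rownames(fp3), pm$well[pm$role != "dye_control"])
  # a block without reference wells is refused by name
  pm_rowa <- plate_map(full_plate_df(n_ref = 4))  # refs sit in row A only
  expect_error(
    fingerprint_plate_blocked(tab, pm_rowa, list("B", setdiff(LETTERS[1:16], "B"))),
    "block")
  # blocks must partition the rows
  expect_error(fingerprint_plate_blocked(tab, pm, list(LETTERS[1:8])),
               "partition")
})
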