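test_that("the brightfield prefilter applies its strict bounds", {
  tab <- simulate_brightfield_cells(c(W1 = 0.5), n_cells = 10, seed = 1)
  tab$area <- c(2000, 2000.1, rep(500, 8))          # boundary kept, above removed
  tab$int_mean <- c(rep(15000, 8), 10000, 9999)     # boundary kept, below removed
  filt <- prefilter_cells(tab)
  expect_equal(nrow(filt), 8)
  expect_equal(attr(filt, "removed"), c(oversized = 1, dark = 1))
  # empty table passes through
  empty <- tab[0, ]
  expect_equal(nrow(prefilter_cells(empty)), 0)
})

test_that("the activation classifier separates, overlaps and nulls as expected", {
  # widely separated populations train to 100%
  tr <- simulate_brightfield_cells(c(A02 = 0, A03 = 0, A04 = 1, A05 = 1),
                                   n_cells = 150, separation = 8, seed = 2)
  tr$label <- tr$true_label
  clf <- train_activation_classifier(tr)
  expect_equal(clf$training_accuracy, 1)

  # overlapping populations (1 SD apart) land in a plausible band
  accs <- vapply(1:10, function(s) {
    t2 <- simulate_brightfield_cells(c(A02 = 0, A03 = 1), n_cells = 200,
                                     separation = 1, seed = s)
    t2$label <- t2$true_label
    train_activation_classifier(t2)$training_accuracy
  }, 0)
  expect_true(all(accs > 0.6 & accs < 0.98))

  # permuted labels give chance accuracy
  t3 <- simulate_brightfield_cells(c(A02 = 0, A03 = 1), n_cells = 400,
                                   separation = 2, seed = 3)
  set.seed(4)
  t3$label <- sample(t3$true_label)
  acc_null <- train_activation_classifier(t3)$training_accuracy
  expect_lt(abs(acc_null - 0.5), 0.06)

  # single-class training set is refused
  t4 <- simulate_brightfield_cells(c(A02 = 0), n_cells = 50, seed = 5)
  t4$label <- t4$true_label
  expect_error(train_activation_classifier(t4), "single class")
})

test_that("percent activated follows 100*a/(a+b) and is bounded", {
  tr <- simulate_brightfield_cells(c(A02 = 0, A03 = 1), n_cells = 200,
                                   separation = 8, seed = 6)
  tr$label <- tr$true_label
  clf <- train_activation_classifier(tr)
  mixed <- simulate_brightfield_cells(c(B02 = 0.25), n_cells = 400,
                                      separation = 8, seed = 7)
  p <- percent_activated(clf, mixed)
  a <- sum(predict_activation(clf, mixed) == "activated")
  expect_equal(p, 100 * a / nrow(mixed))
  expect_gte(p, 0); expect_lte(p, 100)
  # invariant to cell order
  expect_equal(percent_activated(clf, mixed[rev(seq_len(nrow(mixed))), ]), p)
  # zero retained cells gives a flagged missing value
  expect_true(is.na(percent_activated(clf, mixed[0, ])))
})

test_that("the ChP2 gate enumerates its printed rules exactly", {
  conds <- setNames(rep(c("resting", "activated"), each = 16),
                    paste0(rep(c("B", "C"), each = 16), sprintf("%02d", rep(2:17, 2))))
  base <- setNames(c(rep(5, 16), rep(60, 16)), names(conds))

  gate <- function(pct) chp2_gate(pct, conds)$verdict
  expect_equal(gate(base), "pass")

  # exactly 15% in a resting well does not offend (strict >)
  p <- base; p[1] <- 15
  expect_equal(gate(p), "pass")
  # two offending resting wells still pass; three fail
  p2 <- base; p2[1:2] <- 16
  expect_equal(gate(p2), "pass")
  p3 <- base; p3[1:3] <- 15.01
  expect_equal(gate(p3), "rescreen")
  # activated wells: <30% offends, exactly 30% does not
  q <- base; q[17:19] <- 30
  expect_equal(gate(q), "pass")
  q2 <- base; q2[17:19] <- 29.9
  expect_equal(gate(q2), "rescreen")
  q3 <- base; q3[17:18] <- 10
  expect_equal(gate(q3), "pass")
})

test_that("the ChP5 decision kernel reproduces the rule table over control counts", {
  for (n in c(38, 62, 64)) {
    for (ab in 0:n) {
      for (after in c(0L, 2L, 3L, 5L)) {
        got <- chp5_decision(n, ab, after)
        want <- if (ab / n > 0.22) "repeat"
        else if (ab > 3) { if (after >= 3) "rescreen" else "renormalize" }
        else "pass"
        expect_identical(got, want)
      }
    }
  }
  # worked decision scenarios
  expect_identical(chp5_decision(62, 15), "repeat")        # 24.2% > 22%
  expect_identical(chp5_decision(62, 4, 0), "renormalize") # recovered
  expect_identical(chp5_decision(62, 4, 3), "rescreen")    # still abnormal
  expect_identical(chp5_decision(62, 0), "pass")
})

test_that("the ChP5 gate wires scores, roles and rescoring together", {
  scores <- setNames(c(rep(0.1, 28), rep(5, 4), rep(6, 6)),
                     sprintf("B%02d", 1:38))
  roles <- setNames(c(rep("reference_control", 32), rep("activator_control", 6)),
                    names(scores))
  # 4 reference controls score above threshold: abnormal, renormalize
  d1 <- chp5_gate(scores, threshold = 1, roles = roles)
  expect_equal(d1$verdict, "renormalize")
  expect_equal(d1$evidence$n_abnormal, 4)
  # rescoring that leaves 3 abnormal forces a rescreen
  d2 <- chp5_gate(scores, 1, roles,
                  rescore = function(dropped) {
                    setNames(c(rep(0.1, 25), rep(5, 3), rep(6, 6)),
                             setdiff(names(scores), dropped))
                  })
  expect_equal(d2$verdict, "rescreen")
  # positive controls scoring inactive are abnormal too
  scores2 <- scores; scores2[33:34] <- 0.05
  d3 <- chp5_gate(scores2, 1, roles)
  expect_equal(d3$evidence$n_abnormal, 6)
  expect_equal(d3$verdict, "renormalize")
  # > 22% abnormal at the outset repeats the plate
  scores3 <- scores; scores3[1:10] <- 5
  expect_equal(chp5_gate(scores3, 1, roles)$verdict, "repeat")
  expect_error(chp5_gate(numeric(0), 1, roles), "no control wells")
})

test_that("paired-condition quadrants follow strict threshold logic", {
  at <- function(wells, scores) {
    data.frame(well = wells, role = "experimental",
               compound_id = paste0("c", seq_along(wells)),
               cp_score = scores, active = scores > 0.1,
               stringsAsFactors = FALSE)
  }
  r <- at(c("A02", "A03", "A04", "A05"), c(0, 0.05, 0.2, 0.3))
  a <- at(c("A02", "A03", "A04", "A05"), c(0, 0.2, 0.05, 0.3))
  pt <- paired_condition_table(r, a, 0.1)
  expect_equal(pt$quadrant, c("dark", "activated_only", "resting_only", "both"))
  expect_equal(attr(pt, "axes"), c(x = "resting", y = "activated"))
  # quadrant counts agree with the illumination partition on the same input
  venn <- illumination_summary(r, a)
  expect_equal(as.vector(table(factor(pt$quadrant, names(venn$counts)))),
               as.vector(venn$counts))
  # unmatched wells are refused
  expect_error(paired_condition_table(r, a[-1, ], 0.1), "unmatched")
})

test_that("replicate-control reproducibility behaves on known inputs", {
  fp <- function(m, wells) fingerprint_matrix(
    matrix(m, nrow = length(wells), byrow = TRUE,
           dimnames = list(wells, paste0("f", seq_len(length(m) / length(wells))))))
  # identical replicates correlate perfectly
  set.seed(10)
  v <- rnorm(50)
  m1 <- fp(rep(v, 3), c("A02", "B02", "C02"))
  meta <- data.frame(compound_id = "J1", plate_id = c("p1", "p1", "p2"))
  rep1 <- jump_reproducibility(m1, meta, "within_plate")
  expect_equal(rep1$correlation, 1)
  # independent random fingerprints centre near zero
  set.seed(11)
  n_rep <- 40
  m2 <- fp(rnorm(n_rep * 482), sprintf("%s%02d", rep(LETTERS[1:10], 4), 1:10)[1:n_rep])
  meta2 <- data.frame(compound_id = "J2", plate_id = rep("p1", n_rep))
  rep2 <- jump_reproducibility(m2, meta2, "within_plate")
  expect_lt(abs(mean(rep2$correlation)), 0.05)
  # shared signal with modest noise keeps correlations high
  set.seed(12)
  signal <- rnorm(482); signal <- signal / sqrt(sum(signal^2))
  reps <- t(replicate(6, signal + rnorm(482, sd = 0.1 / sqrt(482))))
  rownames(reps) <- sprintf("A%02d", 2:7)
  colnames(reps) <- paste0("f", 1:482)
  meta3 <- data.frame(compound_id = "J3",
                      plate_id = rep(c("p1", "p2", "p3"), 2),
                      batch = rep(c("b1", "b2"), 3))
  rep3 <- jump_reproducibility(fingerprint_matrix(reps), meta3, "between_plate")
  expect_gt(median(rep3$correlation), 0.9)
  # singleton compounds are skipped, not fatal
  meta4 <- data.frame(compound_id = c("J4", paste0("x", 2:6)),
                      plate_id = "p1")
  rep4 <- jump_reproducibility(fingerprint_matrix(reps), meta4, "within_plate")
  expect_equal(nrow(rep4), 0)
})
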