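---
title: "Methods: fingerprinting, scoring and QC for activated Cell Painting screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting, scoring and QC for activated Cell Painting screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscreen)
options(cpscreen.log_level = "warn")
```

# Overview

`cpscreen` implements the analysis side of a high-content Cell Painting
screen run in two cellular states — resting and activated (e.g. by a PKC
agonist such as PMA). The pipeline takes per-cell morphological feature
tables from 384-well plates and produces, in order:

1. **HistDiff fingerprints** — per-well, per-feature histogram-difference
   scores against the plate's pooled reference (carrier-only) controls;
2. **CP Activity Scores** — the mean of squared fingerprint entries, a
   single per-well measure of phenotypic perturbation strength;
3. **activity thresholds** (IQR, FDR, elbow) separating illuminated from
   dark phenotypic space, and the **illumination Venn partition** of
   compounds (active in both conditions / one condition / neither);
4. **quality-control gates** at several checkpoints (brightfield
   activation classification, paired-condition comparison,
   control-anomaly decision rules, replicate-control reproducibility);
5. **feature reduction and clustering** for mechanism-of-action
   exploration, and **target-class analysis** (similarity enrichment and
   consolidation entropy);
6. **GR nuclear-translocation scoring** for the follow-up assay.

Because no per-cell feature data from the motivating screen is publicly
deposited, the package ships a first-class synthetic-screen generator with
planted ground truth. Every pipeline stage is exercised and tested against
those planted truths.

# The HistDiff score

For each feature on a plate, values of all cells are pooled to fix a
common range, divided into `B = 20` equal-width bins, and each well's cell
values are counted into those bins (half-open bins; the final bin is
closed so a value on the maximum edge counts). Counts are smoothed once
with the 3-tap kernel $(0.25, 0.5, 0.25)$ and normalized to unit sum,
giving a density $T$ per well and a density $R$ for the pooled
reference-control cells. The score is

$$ s = \operatorname{sign}(\mu_T - \mu_R) \sum_b (T_b - R_b)^2 $$

with $\mu$ the bin-midpoint-weighted histogram mean. The score is
dimensionless, zero for identical histograms, positive when the treated
population sits above the reference, and bounded by 2 in magnitude for
unit-normalized histograms.

Published descriptions of histogram-difference fingerprinting name the
steps (bin, smooth, normalize, compare) but not the comparison statistic,
bin count, or kernel. The definition above is therefore this package's
documented contract: 20 bins balance resolution against typical per-well
cell counts (~400), and the minimal symmetric kernel makes smoothing
reproducible. The statistic is isolated behind `histdiff_score()`, so an
alternative comparison can be swapped in without touching callers.

Two design points matter in practice:

* **Leave-one-out reference scoring.** A reference well scored against a
  pool containing its own cells is biased toward zero, which in turn
  biases every control-derived activity threshold and inflates the
  false-positive rate among treated wells. Reference wells are therefore
  scored against the pool with their own cells removed, making control
  scores exchangeable with treated-well null scores.
* **Degenerate features and empty wells.** A zero-variance feature falls
  back to a unit-width bin range (constant wells score 0); an empty well
  yields an all-missing fingerprint carrying an `empty` flag — never a
  silent zero — and wells under `min_cells = 10` cells are flagged
  `low_count`.

## Block normalization

Occasional plates show staining stripes across row bands. Because
reference controls are placed at randomized positions, each band still
contains reference wells, so the plate can be partitioned into row blocks
and each block processed independently (`fingerprint_plate_blocked()`),
then concatenated. With the trivial single-block partition this is
exactly the unblocked computation. The stripe-removal property is tested
by comparing striped-block reference scores against the identical plate
without the artifact, both processed with the same partition — comparing
against a *differently blocked* run would confound artifact removal with
the reference-pool-size effect on score spread.

# CP Activity Score and thresholds

$$ \mathrm{CPscore} = \frac{1}{n}\sum_{i=1}^{n} x_i^2 $$

over the $n$ fingerprint features $x_i$; missing features are excluded
from numerator and denominator. No further screen-level rescaling is
applied. Three threshold rules are implemented, all operating on CP
scores of reference controls (elbow: on all scores):

* **IQR** — scores above the third quartile are outliers; the highest
  control at or below Q3 is the threshold. Quantiles use the type-7
  (linear interpolation) convention, recorded in the provenance. A
  conventional Q3 + 1.5 IQR fence is available behind a flag for
  sensitivity analysis, but the literal above-Q3 rule is the default.
* **FDR** — the top $\lceil qN \rceil$ controls ($q = 0.05$) are
  excluded; the maximum of the remainder is the threshold. Note the
  expected null exceedance of this rule is about $q + 1/N$, so the
  active-call rate on pure-null data sits slightly above $q$.
* **Elbow** — scores are sorted ascending and both axes rescaled to the
  unit square; the knee is the point of maximum perpendicular distance
  to the chord between the first and last point (hence invariant to
  affine rescaling of the scores). An exactly collinear curve is a
  degenerate-input error.

Activity calls are strict (`score > threshold`). A well is **cytotoxic**
when its cell count is strictly below 50% of the mean control-well
count. The illumination summary partitions compounds into
`both` / `activated_only` / `resting_only` / `dark` from their
per-condition calls; the screen-wide threshold pools reference controls
across plates and conditions, mirroring the use of a combined DMSO
control pool.

# Quality-control gates

**Brightfield activation checkpoint.** Putative cells with area
$> 2000\,\mu m^2$ or brightfield mean $< 10{,}000$ are removed. The
activation classifier is a linear discriminant on a 23-feature panel
(6 morphology, 9 intensity, 8 texture — the counts that sum to the
printed 23); the screen's original classifier weights are not available,
so the contract is the decision interface, not a weight vector. Percent
activated is $100a/(a+b)$. A plate passes when at most two resting
control wells have strictly more than 15% activated cells and at most two
activated control wells have strictly less than 30%.

**Control-anomaly decisions.** A reference control scoring active, or a
positive control scoring inactive, is abnormal. A plate with more than
22% abnormal controls at the outset is repeated; with more than 3
abnormal wells the abnormal controls are dropped and scoring recomputed,
after which 3 or more remaining abnormal wells trigger a rescreen;
otherwise the plate passes. The 3-well count follows the printed rule
(calibrated to a 38-well control set at roughly 10%); the decision kernel
is a pure function of the counts and is enumerated exhaustively in the
tests.

**Paired-condition table.** Per-well resting (x) vs activated (y) CP
scores with strict threshold lines on both axes; quadrant counts agree
with the illumination partition by construction. The axis convention
(x = resting, y = activated) is fixed and recorded in the output, since
published descriptions of the comparable tool label the axes
inconsistently.

**Replicate controls.** For replicated control compounds, all pairwise
Pearson correlations between replicate fingerprints are reported per
grouping level (within plate, between plates, between batches), in long
format for violin plots.

# Feature reduction and clustering

Zero-variance features are dropped first. Collinearity pruning flags all
feature pairs with $|r| > 0.8$ and, processing pairs in descending $|r|$
with a stable name tie-break, removes the member with the higher mean
absolute correlation to all remaining features until no pair exceeds the
cut. The processing order is fixed because determinism is required for
provenance replay; the removed set is recorded and replaying it
reproduces the retained features exactly, and the operation is
idempotent. Per-condition fingerprints are concatenated column-wise
(condition-suffixed names) for combined-condition views.

For pairwise analyses the fingerprints are projected to 100 components.
This package uses classical multidimensional scaling (principal
coordinates) of the correlation distance $1 - r$: a deterministic,
parameter-free embedding whose components play the same role as PCA
components and preserve the correlation geometry that the downstream
similarity and clustering stages use. Density-based clustering
(`cluster_hdbscan()`) follows the HDBSCAN construction — core distances
at `min_samples` neighbours, mutual-reachability distances, a minimum
spanning tree, condensation at `min_cluster_size = 5`, and
excess-of-mass cluster extraction with points outside any stable cluster
labelled noise (−1); it is implemented in the package and cross-checked
in the test suite against an independent reference implementation on
planted-group data. Hierarchical clustering uses complete linkage on
$1 - r$ (sign-aware, matching guilt-by-association logic; anticorrelated
profiles are distant). Heatmap exports are tab-delimited matrices plus
merge-table tree files, with an optional compartment sort that groups
feature columns by their stained-compartment prefix.

# Target-class analysis

For each annotated class, in-class pairwise similarities are compared
against member-to-nonmember similarities with a one-sided two-sample KS
test (alternative: in-class stochastically greater), reported as
$-\log_{10} p$; the significance call uses the raw $p < 0.05$ (as in the
pilot-style analysis), with Benjamini–Hochberg-adjusted values reported
alongside. Classes with fewer than two annotated members are skipped.

Consolidation entropy quantifies how tightly a class clusters in each
condition: the Shannon entropy (bits) of the members' distribution over
cluster labels, with each noise point counted as its own singleton label
(noise is not a shared phenotype). A class whose activated-condition
entropy is lower than its resting entropy (delta < 0) consolidated under
activation. The published description names the pairwise Euclidean
distances but not the entropy functional; this cluster-membership
entropy is the package's documented reconstruction, and the cluster
labels are injected so an alternative functional can replace it without
touching callers.

# GR nuclear translocation

A cell is nuclear-enriched iff **all six** ratio criteria hold strictly:
GR-nuclear-sum/Hoechst-sum > 0.35, GR nuclear/cytoplasmic sum > 0.25,
mean > 1.7, median > 1.7, quantile > 1.7, contrast > 0.3. The conjunction
is the only reading under which each listed threshold matters, and strict
inequalities mean boundary cells fail. Cells with non-positive
denominators are excluded from both the numerator and denominator of the
well percentage. Percentages pool cells per well by default; a per-field
average is available, matching the acquisition-time convention.

# The synthetic screen generator

The generator emulates the features of the real screen that the analysis
depends on, with planted truth stored alongside:

* 384-well plates with 64 controls (32 reference, 24 JUMP replicates as
  eight compounds in triplicate, 8 activator controls), 318 experimental
  wells, and dye wells at A01/P24; control positions are randomized per
  plate (a seeded shuffle stands in for the original MILP randomizer).
* Per-feature base distributions (normal by default; log-normal option
  for intensity-like skew) with parameters drawn once per screen; 482
  features named by stained-compartment prefixes by default.
* Compound effects as location shifts in control-SD units on a feature
  subset, with condition specificity (both / activated-only /
  resting-only / none) and a cytotoxic cell-count reduction factor.
* A global activation signature — +1 SD on a fixed 30% of features in
  every activated well — reflecting a broad activator response across
  stained compartments. Activator-control wells have their activation
  state flipped relative to the plate, reproducing the positive-control
  design (activator wells on resting plates and vice versa).
* Cells per well are negative-binomial (mean 400, dispersion 10), so
  counts are over-dispersed and exercise the cytotoxicity flag.
* Brightfield records draw the 23-feature panel from two overlapping
  multivariate normal populations separated on the texture/intensity
  features the real classifier found discriminative, plus planted
  oversized/dark junk objects; GR records are constructed from sampled
  criterion ratios in an all-pass or at-least-one-fail regime.

What the generator does **not** emulate: image-level artifacts other
than row stripes, feature-extraction error models, spatial edge effects,
batch drift, or realistic compound effect-size distributions (none is
published; the planted 1.5 SD / 20-feature default is an exercising
choice, not a biological claim). Passing recovery tests therefore
demonstrates correctness of the analysis pipeline on data with planted
truth — not performance claims about any real screen.

# Problem sizes and numerical choices

The test suite and the acceptance script run on scaled screen instances
chosen as the package's own benchmark sizes: the planted recovery screen
uses 1,000 compounds (50 both / 30 activated-only / 20 resting-only at
1.5 SD on 20 features, 900 inert) on 4 plates per condition with 100
features and ~200 cells per well; null-calibration checks use 400 cells
per well at 20 features; the enrichment and consolidation simulations use
the member counts stated with each test. Feature counts below the
482-feature default keep repeated end-to-end simulation fast without
changing any algorithmic path.

Other numerical conventions, gathered in one place: type-7 quantiles;
strict comparisons at every published threshold; FDR tie-break by
descending order with stable indices; collinearity tie-break by feature
name; elbow degeneracy tolerance $10^{-9}$ of the chord; histogram
degenerate-range fallback to a unit interval; correlation distance
$1 - r$ (not $1 - |r|$); embedding component signs fixed by making the
largest-magnitude loading positive; all generators seeded explicitly and
deterministically.

# A short worked example

```{r example, eval = FALSE}
design <- planted_screen_design(n_both = 10, n_activated_only = 6,
                                n_resting_only = 4, n_inert = 80,
                                n_features = 60, n_plates = 1,
                                cells_per_well_mean = 150, seed = 1)
rec <- screen_recovery(design, seed = 2)
rec$summary            # illumination partition of the 100 compounds
rec$threshold          # FDR-5% CP Activity threshold and provenance
table(planted = rec$truth$planted_category, called = rec$truth$category)
```

# Known limitations

* The HistDiff comparison statistic, smoothing kernel and bin count are a
  documented reconstruction (see above); absolute score values are not
  comparable to other implementations, though rankings and calls are
  robust to the choice in our tests.
* The 100-component embedding is a linear (PCoA) map; strongly
  non-convex cluster shapes that a nonlinear embedding might separate
  can remain mixed. The clustering stage consumes any embedding, so a
  nonlinear alternative can be substituted where available.
* The activation classifier is trained per screen on control wells of
  known state; it does not ship pre-trained weights.
* Decision thresholds in the QC gates are taken verbatim from the
  published rules; their denominators are data-driven from the plate map
  rather than hard-coded, since published control counts vary between
  sections (38, 62 and 64 in different contexts).
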