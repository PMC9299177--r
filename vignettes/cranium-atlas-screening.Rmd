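---
title: "Screening commingled crania and atlases: methods and design notes"
author: "craniosort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening commingled crania and atlases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniosort)
```

## The problem

When skeletal remains of several individuals are commingled, re-attaching a
disarticulated cranium to the right postcranial skeleton often reduces to one
joint: the atlanto-occipital articulation between the occipital condyles (OC)
and the superior articular facets of the first cervical vertebra (C1, the
atlas). `craniosort` implements a two-arm screening procedure for this joint:

1. an **osteometric arm** that asks whether sixteen caliper distances (eight
   per bone) carry enough individualizing signal to *re-associate* pairs, and
2. a **3D surface arm** that rigidly superimposes the articular surface
   patches of a candidate cranium-atlas pair and uses the residual
   root-mean-square (RMS) distance to *exclude* pairs that cannot belong to
   the same individual.

The empirical outcome this package operationalizes is asymmetric: linear
measurements alone do not support re-association (no classifier finds the
correspondent pairs), while the 3D surfaces support a conservative,
exclusion-only screen (matches never exceed a derivable RMS ceiling;
roughly a third of mismatches do).

## Osteometric arm

### Data model and features

Each individual contributes eight occipital and eight atlas distances in
millimetres (`measurement_schema()`), paired by mechanical homology
(`measurement_pairings()`): facet widths, facet lengths, foramen diameters,
and the bilateral medial/lateral spans. Note that the spans pair across
naming conventions — the occipital lateral-span measurement pairs with the
atlas lateral span, and medial with medial — so the pairing is *anatomical*,
not positional in the table.

For a candidate cranium x atlas combination, nine features are computed
(`extract_features()`): the eight paired differences, oriented as
`occipital - atlas` (with population-mean widths and foramen diameters this
direction gives negative means, the atlas facet being on average the larger
surface), and a ninth feature, the difference of the Euclidean norms of the
two 8-vectors, which summarizes overall joint size. A squared-norm variant
is available behind `squared_norm = TRUE` but is off by default: the
Euclidean norm is the natural "size of the measurement vector" reading.

`build_pairwise_dataset()` forms every cranium x atlas combination: `n`
individuals give `n^2` rows, of which exactly the `n` diagonal rows are
labelled `correspondent`. At the reference scale (`n = 150`) this is a
22,500-row dataset with a 1:149 class imbalance — the central difficulty of
the classification task, and the reason the package reports PPV alongside
specificity (a majority-class predictor trivially achieves specificity
`(n^2 - n) / n^2`).

### Measurement reliability

`compute_tem()` implements the Dahlberg technical error of measurement,
`TEM = sqrt(sum(d^2) / 2N)` for paired repeated measurements, with the
relative TEM expressed against the grand mean of all `2N` values and an
acceptability cut-off of 7.5% — the conventional anthropometric threshold.
TEM is symmetric in the two series, scales linearly with the measurement
unit, and rTEM is scale-invariant; these properties are enforced by tests.

### Classifiers and evaluation

Six supervised families are evaluated (`cross_validate()`,
`evaluate_classifiers()`): linear discriminant, logistic regression,
quadratic discriminant, Gaussian-kernel SVM, boosted trees (50 learners),
and a feedforward neural network (one hidden layer of 50 tanh units, trained
with an internal 70/15/15 train/test/validation split and early stopping on
the validation cross-entropy). The network is implemented in the package
itself because this exact model — tanh hidden activation plus
validation-based early stopping — is not expressible with the single-layer
tools available; everything else delegates to the standard implementations
(MASS, stats, e1071, xgboost).

Evaluation uses stratified 10-fold cross-validation. Stratification is a
deliberate design choice: with 150 positives in 22,500 rows, unstratified
folds can be positive-free, which destabilizes every per-fold metric. Scores
are pooled out-of-fold; the confusion matrix uses a 0.5 probability
threshold and AUC is threshold-free. Undefined-metric convention: if a model
never predicts a positive, PPV *and* sensitivity are reported as `NA`
(rendered `n.a.`); if it predicts positives but none is correct, both are 0.
This mirrors how such degenerate outcomes are conventionally tabulated.

`correlation_report()` gives the Pearson correlation of each correspondent
measurement pair across individuals with Taylor's strength bands (poor
&le; 0.3 < low &le; 0.5 < moderate &le; 0.7 < strong), half-open at each
boundary.

## 3D surface arm

### Data model

A `roi_mesh` is an open triangulated patch in millimetres holding *both*
facets of one bone at their original spatial separation — the bilateral
geometry (inter-facet distance and relative orientation) is part of the
matching signal and is never normalized away. `crop_roi()` emulates the
manual contour-selection step used to isolate articular surfaces from a
full bone scan: an ordered closed 3D polyline is projected onto its
best-fit plane together with the mesh vertices, and a point-in-polygon test
decides retention. A `landmark_set` holds the four labelled edge points
(anterior, posterior, lateral, medial) per facet used for initial
orientation.

### Registration

Superimposition is rigid only — no scaling, no reflection — in both stages,
because both meshes are real-size scans of real bones; any scale freedom
would absorb exactly the size differences the screen must detect.

1. `landmark_align()`: closed-form least-squares (Kabsch) fit on the eight
   label-matched landmarks, with a collinearity guard (the rigid fit is
   underdetermined below three non-collinear points).
2. `icp_refine()`: iterative closest point against the destination
   *surface*. Each iteration matches every transformed source vertex to its
   nearest point on the destination triangulation and applies the
   closed-form rigid update. The recorded per-iteration RMS (correspondence
   RMS after each update) is non-increasing by the classical ICP argument:
   re-matching can only shorten each correspondence and the rigid update can
   only shrink the sum of squares. Iteration stops when the RMS improves by
   less than `convergence_tolerance` (default 1e-6 mm) or at
   `max_iterations` (default 100); non-convergence is flagged, not thrown.
   No correspondence rejection is applied.

"Point-to-point distance" is implemented as vertex-to-nearest-surface-point
(point-to-triangle) distance rather than vertex-to-nearest-vertex: the two
bones in the reference protocol were digitized by different scanners with
different mesh resolutions, and surface distance is invariant to
retriangulation where vertex distance is not. A `point_to_vertex` mode is
kept behind a flag for sensitivity analysis. Distances are unsigned
(`distance_summary()` reports RMS, min, max, SD). By convention the OC mesh
moves onto the C1 mesh (`superimpose()`; `swap = TRUE` reverses the roles —
the RMS is not exactly symmetric because the vertex set being measured
changes).

`export_colormap()` writes the registered moving mesh as PLY with per-vertex
distances both as a `quality` scalar and as a blue-green-red colour ramp
over a fixed scale, the usual first visual readout of a superimposition.

### Screening logic

`design_experiment()` builds the superimposition task list: every individual
as its own match pair, plus ordered same-sex mismatch pairs sampled
uniformly without replacement within each sex (the reference design: 46
individuals, 26 female and 20 male, with 130 mismatch combinations per sex —
306 tasks). Sampling is seeded; the reference study does not state how its
mismatch combinations were chosen, so uniform-without-replacement is the
neutral choice.

`derive_threshold()` is deliberately primitive: the maximum RMS observed
among matches. `screen_pair()` excludes a candidate pair only for RMS
*strictly above* the threshold; a tie is inconclusive (exclusion must be
conservative), and no verdict ever asserts a positive match — the screen's
sensitivity for confirming re-associations is zero by construction, which is
the honest reading of the evidence: below the threshold, match and mismatch
RMS distributions overlap completely.

`group_stats()` runs the supporting inference: two-way ANOVA on sex and
group (match/mismatch) with interaction, using type-II sums of squares
because the design is unbalanced (46 vs 260); Levene's test (mean-centred)
for homoscedasticity across the four cells; Jarque-Bera normality per cell.
The reference description assigns Levene to normality and Jarque-Bera to
homoscedasticity, which inverts the tests' standard purposes; the package
implements the standard assignment. With an empty cell the model degrades to
a one-way ANOVA on group, with a warning.

## Synthetic data: what is emulated, and what is not

The reference measurements and scans are not publicly deposited, so the
package carries three generators, each calibrated to a different printed
summary of the reference population, so that no pipeline stage depends on an
uncalibratable model of another:

* `simulate_measurements()` — per-measurement normal populations with the
  reference means and SDs, and the eight correspondent-pair correlations
  (0.514, 0.481, 0.650, 0.622, 0.671, 0.591, 0.606, 0.402) induced by a
  shared-factor construction: both sides of pairing *i* load on one
  per-individual standard-normal size factor with weight `sqrt(r_i)`. This
  also induces positive cross-measurement correlation (large joints are
  large everywhere), which is anatomically realistic even though only the
  eight pairwise correlations are calibrated. Values below 0.1 mm are
  resampled. The sex ratio defaults to the reference 67F/83M.
* `simulate_rms()` — match and mismatch RMS outcomes from truncated
  distributions (lognormal by default: RMS is positive and right-skewed;
  truncated normal available) matched to the printed moments and ranges
  (match: mean 0.29, SD 0.09 on [0.15, 0.53]; mismatch: mean 0.46, SD 0.20
  on [0.14, 1.49]; sex-specific rows available). The solver matches the
  *truncated* distribution's moments where the family permits, so that
  realized draws reproduce the calibration at large n; where the printed SD
  sits above the family's ceiling on the printed range (the female-match
  row), it falls back to matching the untruncated moments and truncating.
  Bounds are respected exactly (inverse-CDF sampling), so match draws never
  exceed 0.53 mm by construction.
* `simulate_surface_pair()` — full mesh pairs: each synthetic individual has
  bilateral convex elliptical dome patches (length, width, medial/lateral
  placement drawn from the measurement calibration; dome height a fixed
  ratio of width with small individual variation), and its atlas counterpart
  is the congruent surface of the *same* (matched) or an *independent*
  (mismatched) individual, deformed along vertex normals by a smooth random
  field of RMS amplitude `sigma_c` and posed by a random rigid displacement.
  Landmarks are the extremal boundary points of each facet.

`sigma_c` is a free parameter of the surface model, not a population value:
real articular congruency noise structure is unknown. Its default (0.3 mm)
makes end-to-end registered match RMS land near the calibrated match mean
(about 0.25–0.3 mm) and mismatch RMS clearly above it; it is documented as a
knob, and the mesh generator is validated by *ordering* properties (matched
pairs register closer than mismatched ones; a perfectly congruent pair
registers to numerical zero) rather than by moments, which belong to
`simulate_rms()`.

What the generators do **not** emulate: real condylar shape variation (no
anatomical shape atlas), taphonomic damage, osteoarthritic remodelling,
scanner noise and holes, or left/right asymmetry beyond independent sizes.
Tests passing on synthetic data therefore validate the *machinery* —
registration correctness, threshold logic, metric handling under extreme
imbalance — and the qualitative reproduction of the reference outcome, not
field performance on real assemblages.

## Numerical choices

* Rigid transforms are validated to 1e-9 (orthogonality, determinant +1).
* The Kabsch fit uses SVD with the standard determinant sign correction, so
  reflections are never returned.
* Point-to-triangle distance: per point, one vectorized pass over all
  triangles (in-triangle orthogonal projection where admissible, otherwise
  the nearest of the three edges); exhaustive, no spatial pruning — mesh
  sizes here (hundreds of faces) do not warrant an acceleration structure.
* Truncated-moment matching solves two parameters by Nelder-Mead on the
  squared moment error (analytic truncated moments); targets infeasible for
  *any* distribution on the range (`sd^2 > (mean - lo)(hi - mean)`) are an
  error.
* Ties at the screening threshold are inconclusive (strict `>` excludes).
* All generators and the cross-validation take explicit seeds and restore
  the caller's RNG state; nothing depends on the global seed.

## Problem sizes used by the test-suite

The shipped tests exercise the reference scale where it is the point of the
check (the 22,500-row pairwise dataset, 10-fold CV of all six families, the
306-task design, 46/260 RMS screening) and reduced sizes where only a
property is being verified: mesh-registration properties run on 4-ring x
10-sector facets (82 vertices per mesh) with 15–40 registrations per
property, and the surface-ordering property uses 20 paired draws. These
sizes are the package's chosen trade-off between Monte-Carlo resolution and
a test suite that stays pleasant to run; the properties they check are
size-free.

## Known limitations

* The exclusion threshold is a sample maximum — it grows with match sample
  size and has no confidence statement attached; with 46 matches it is a
  point estimate of the true match ceiling.
* The RMS generator reproduces printed moments, not the unknown true shape
  of the RMS distributions; the mismatch exclusion rate implied by the
  calibrated lognormal is ~29–30%, slightly below the reference 32%, which
  is the residual misfit between a two-parameter family and reality.
* The surface generator's domes are far smoother than real condyles; real
  RMS values include scanner noise and segmentation edge effects that are
  not modelled.
* `read_stl()`/`read_ply()` support the common subsets of those formats
  (binary + ASCII STL; ASCII PLY with float vertex properties), not every
  dialect in the wild.
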