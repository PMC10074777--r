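---
title: "Lesion-wise evaluation of automated brain-metastasis contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-wise evaluation of automated brain-metastasis contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionwise)
```

## The problem

Stereotactic radiosurgery (SRS) of brain metastases requires every lesion to
be found and contoured on the planning MR. When an automated contouring tool
proposes structures, its output must be scored *per lesion*, not per voxel:
a cohort dominated by one large metastasis would otherwise hide systematic
failure on the many small ones that decide clinical utility. `lesionwise`
implements a lesion-wise evaluation of predicted structure sets against
physician ground truth, together with a synthetic cohort simulator with a
known detection and boundary-error model, so that the entire pipeline can be
validated by parameter recovery without access to patient data.

## Metrics and matching rules

All computation happens on binary masks obtained by rasterizing planar
contours onto a common reference grid in physical millimetres.

**Detection.** A ground-truth lesion counts as *detected* when the physical
centroid of at least one predicted component, mapped to its nearest voxel,
is a member voxel of that lesion. A predicted component is a *false
positive* (FP) when it shares no voxel with any ground-truth lesion. The
two rules are intentionally asymmetric: a prediction that grazes a lesion
without placing its centroid inside it yields neither a detection nor an
FP. When several predicted components place their centroids inside one
ground-truth lesion, their union is the prediction — the only convention
that keeps one DSC per ground-truth lesion well defined.

Centroids are unweighted means of member-voxel centers; for non-convex
(e.g. crescent) shapes they can fall outside the lesion, and the rule is
applied literally in that case. The same applies to a predicted centroid.

**Lesion-wise DSC.** `2|A∩B| / (|A|+|B|)` between the ground-truth lesion
and its matched prediction, computed only for detected lesions.

**Average Hausdorff distance (AVD).** The average *symmetric* surface
distance: surface voxels are members with at least one 6-neighbour outside
the lesion, and AVD is the mean of the concatenated directed
nearest-neighbour distance lists between the two surface-voxel center
sets. A `max_directed` variant (maximum of the two directed means) is
available but off by default. AVD is reported in millimetres and relative
to lesion size, as a percentage of the ground-truth lesion's *effective
diameter* — the diameter `d = 2(3V/4π)^{1/3}` of the volume-equivalent
sphere. A distance normalized by a volume would be dimensionally
inconsistent, so the effective diameter is the natural "lesion size" for a
relative distance.

**Sensitivity.** Detected over total ground-truth lesions, as a
percentage, pooled over lesions (never averaged over cases), overall and
restricted to effective-diameter intervals: cumulative thresholds
(≥ 5, ≥ 7.5, ≥ 10 mm) and half-open bins [5, 7.5), [7.5, 10), [10, ∞) mm.

**Connectivity.** Components are 26-connected; surfaces use the
6-neighbourhood — the standard pairing for 3D lesion masks. Distances are
between surface-voxel *centers*; sub-voxel surface meshing is out of
scope, which makes every distance reproducible against a brute-force
oracle. Anisotropic spacing is honoured in all volumes, centroids and
distances.

## Rasterization

A voxel is set when its center lies inside an odd number of the polygons
assigned to its slice (even-odd rule), so inner contours carve holes. Each
polygon is assigned to the nearest grid plane and must lie within half a
slice spacing of it. Ground truth and prediction are always rasterized onto
the *same* reference grid; the metrics are only well defined on a common
grid, and the package refuses mixed-grid comparisons. Whether a clinical
comparison should use the MR or the CT grid is a study-design question; the
package takes the grid it is given.

Voxel centers exactly on a polygon edge resolve deterministically by the
half-open crossing convention; the axis-aligned square fixtures in the test
suite are constructed to be exact (a 20 × 20 mm square on a 1 mm grid
covers exactly 400 voxel centers).

## Statistical stratification

Kruskal–Wallis tests relate patient-level characteristics (sex, age, race,
histology, tumor count) to per-case metric aggregates (mean lesion-wise
DSC, mean AVD in mm and %, FP count, per-case sensitivity), and the
lesion-level characteristic tumor size to lesion-wise DSC, AVD and the
binary detection indicator (the per-lesion quantity that aggregates to
lesion-wise sensitivity). The H statistic and chi-square p-value come from
`stats::kruskal.test` (midranks with tie correction); the package adds the
all-ties convention (H = 0, p = 1) and a label-permutation p-value. The
permutation route exploits that, conditional on the pooled midranks, H is
a fixed monotone transform of `S = Σ nᵢ R̄ᵢ²`, so permutations only
redistribute rank sums — no re-ranking per draw.

The size-versus-FP cell is structurally absent: a false positive has no
ground-truth size, so no such test exists; the grid carries an explicit
marker rather than a value.

Design choices left open by convention, all configurable: age enters in
tertiles (alternatives: median split, custom cut points); tumor count in
the cohort-table bins 1/2/3/4/≥5; lesion size in sample quartiles
(alternatively fixed cut points such as 0.040/0.112/0.521 c.c.). Records
with undefined metric values (e.g. patients with no detected lesion) are
excluded per cell and the exclusion count reported. When any group has
fewer than five observations the chi-square approximation is doubtful and
the package warns, offering the permutation p-value as the remedy. No
multiple-testing correction is applied by default (each cell is read at
0.05); Holm adjustment is available.

## The synthetic cohort

The simulator emulates the structure of a published 100-patient /
435-metastasis SRS validation cohort. All defaults were fixed once, by
calibration against that cohort's printed summaries, and are not tuned per
run:

* **Lesion counts**: zero-truncated negative binomial, `mu = 1.3`,
  `size = 0.28`, clipped at 52 — distribution median 2,
  P(count ≤ 2) = 0.57 as in the emulated cohort, mean ≈ 3.4 (the cohort's
  4.35 cannot be reached by a ZTNB that also preserves the median and the
  ≤2 mass; the median was prioritized). Note that with P(≤ 2) barely above
  one half, a single 100-patient draw occasionally has sample median 2.5
  or 3 — as would real cohorts drawn from these frequencies.
* **Lesion volumes**: log-normal with `meanlog = log(0.112)` and
  `sdlog = (log 0.521 − log 0.040) / (2 Φ⁻¹(0.75)) = 1.90` (closed-form
  fit to the printed quartiles), clipped to [0.010, 26.475] c.c. The
  printed quartiles are slightly asymmetric on the log scale, so the first
  quartile is matched approximately.
* **Geometry**: 0.469 × 0.469 × 1.0 mm voxels (the cohort's median MR
  resolution) over a 180 × 220 × 180 mm brain box; spheres are placed
  uniformly with ≥ 2 mm surface separation, largest first, by rejection
  sampling.
* **Detection**: logistic in log effective diameter, intercept −1.745,
  slope 2.488 — solved so that the implied overall and ≥ 10 mm
  sensitivities are 89.3% and 99.1% under the volume model. A constant-p
  model is available for recovery experiments.
* **Boundary error**: each detected lesion's contour radius is perturbed
  by a smooth angular field — a uniform radial bias plus three Fourier
  modes, half the variance in the bias — applied coherently across
  slices, plus an optional rigid offset. White per-vertex jitter is *not*
  used: rasterization low-pass filters vertex-frequency noise, so it
  cannot produce realistic error levels. The default pointwise sd of
  1.1 mm reproduces the reported mean lesion-wise DSC (≈ 0.72) and
  relative AVD (≈ 7–8% of lesion size).
* **False positives**: Poisson per case (default rate 0.72, echoing the
  reported mean FP count) with small log-normal volumes, placed with
  clearance from every ground-truth lesion.
* **Covariates**: sampled from the cohort's published frequency tables,
  independent of performance unless an effect is injected
  (`covariate_effects` can shift the detection logit or scale the
  boundary noise within a stratum, for power studies).

Identical configuration and seed reproduce the cohort — and the entire
written report bundle — byte for byte.

**What the simulator does not emulate.** Lesions are spheres; real
metastases are lobulated, which stresses the centroid rule differently.
There is no imaging appearance, no anatomy (lesions place uniformly in a
box), no image artifacts, no inter-observer variability in the ground
truth, and boundary error is angular-smooth by construction. Passing
recovery tests therefore demonstrates that the *measurement pipeline* is
faithful, not that any particular segmentation tool performs at the
simulated level on real data.

**A known tension in the emulated summaries.** The reported AVD pair
(0.704 mm ↔ 7.34% of lesion size) implies a typical detected-lesion
effective diameter near 9.6 mm, larger than the reported size quartiles
imply (median ≈ 6 mm). With a single noise scale the simulator matches the
dimensionless pair (DSC and relative AVD); its absolute AVD then sits near
0.47 mm. Matching all three simultaneously would require a size-dependent
error model, which the reported summaries themselves argue against
(absolute AVD is described as uncorrelated with size).

## The fast frame-level path and null calibration

`simulate_cohort_frame()` draws the same cohort structure but replaces
rasterize-and-measure with the analytic error model (`avd = δ`,
`dsc = 1 − 3δ/d` — the thin-shell approximation for a sphere), producing a
`cohort_frame` directly. Its `"exchangeable"` mode is the calibration
null: every metric at both levels is drawn i.i.d., independent of
covariates, size and count, so each cell of the stratified grid tests a
true null. This is deliberate: under the realistic (`"size_coupled"`)
model the size and count cells are *not* null — aggregation alone couples
per-patient metric dispersion to lesion count — so they cannot be used to
measure the tests' type-I error. The null study in the test suite runs 500
replicates of 50 patients and checks per-cell rejection at 0.05 using the
permutation p-value (exact by construction; the chi-square approximation
is visibly conservative for the sparse race and histology categories at
this cohort size). With 29 cells each checked against a 95% interval, a
handful of chance exceedances is expected even under perfect calibration,
and the acceptance check allows for that multiplicity.

## Numerical conventions

* Effective diameter inverts exactly (diameter → sphere volume →
  diameter to 1e−9); volumes are voxel count × voxel volume, in c.c.
* Undefined quantities (no lesion passes a diameter filter; no lesion
  detected cohort-wide) are `NA` markers end to end and render as `n/a`,
  never as 0.
* Per-case means of DSC/AVD are over detected lesions only; cohort means
  pool all detected lesions across cases; mean FP is the mean of per-case
  counts.
* Components order deterministically by minimal (z, y, x); ties in
  nearest-neighbour distances are irrelevant to the reported means.
* Problem sizes in the validation suite — 100 random mask pairs at ≤ 15³
  voxels for the metric oracles, 200 patients for parameter recovery, 500
  replicates of 50 patients for null calibration, a five-point size
  ladder with 20 replicate spheres per size — were chosen to give each
  check sampling margins well inside its tolerance.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, patients = 20)
cohort <- generate_cohort(cfg)
cases <- evaluate_cohort(cohort)
summary <- aggregate_cohort(cases)
summary

frame <- cohort_frame(cases, cohort$covariates)
grid <- build_stratified_grid(frame, on_error = "na")
recover_parameters(cohort$truth, summary)
```

The command-line wrapper (`inst/cli/lesionwise.R`) exposes the same
pipeline as `evaluate`, `simulate`, `stats` and `render` verbs over YAML
run configurations, for batch use on directories of per-patient
structure files (json-contours, DICOM RTSS via the bundled pydicom
bridge, or NIfTI label volumes).

## Limitations

Beyond the simulator's scope noted above: DICOM RTSS support covers the
geometry payload (names, planar contours, frame of reference), not the
full referenced-image machinery of clinical RTSS objects; volumes below a
few voxels quantize visibly at the default spacing (a 0.010 c.c. lesion
spans ~2–3 slices); and the chi-square Kruskal–Wallis p-values inherit the
usual small-group caveats — use the permutation option when group sizes
fall below five.
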