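---
title: "Methods: NTCP-driven proton/photon selection at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NTCP-driven proton/photon selection at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rtdecide` implements a complete, desk-scale model-based selection
pipeline for prostate radiotherapy: which patients gain enough
normal-tissue sparing from proton therapy to justify it over photon
(VMAT) treatment? The pipeline follows the two-model workflow used in
clinical decision-support research — predict the dose each modality
would deliver, convert the dosimetric predictor into a complication
probability, and select by thresholded NTCP difference — with every
component reimplemented so it runs on synthetic anatomy in minutes on
one CPU. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic setting can and cannot show.

## The decision problem and the two-step rule

For each patient the pipeline produces a photon NTCP and (when needed) a
proton NTCP for late rectal bleeding, then applies:

* **Step 1.** If the photon NTCP does not exceed 10%, photon therapy is
  selected outright; the proton plan or prediction is never evaluated
  (`decide()` takes a deferred provider and provably does not invoke it,
  which mirrors the clinical workflow where the costly comparison is
  made only for plausible proton candidates).
* **Step 2.** Otherwise ΔNTCP = NTCP(photon) − NTCP(proton) in
  percentage points is computed; proton therapy is selected only when
  ΔNTCP exceeds 10 points.

Both comparators are strict ("exceeds") by default. Published accounts
of this rule differ between a strict and a closed second comparison; we
follow the rule's prose form (photon when ΔNTCP ≤ 10) and expose both
comparators in `decision_thresholds()` so the boundary semantics can be
flipped for sensitivity analyses. A negative ΔNTCP (proton worse)
selects photon.

## NTCP models

The operative model is a published multivariable logistic model for
late rectal bleeding:

S = −3.07 + 0.79 · anticoagulant_use + 0.12 · V6300cGy(rectum wall),

NTCP = 1 / (1 + e^{−S}).

`V6300cGy` is the percent of rectum-wall volume receiving at least
6300 cGy in 2-Gy-equivalent dose, and `anticoagulant_use` is a 0/1
clinical covariate. Some printings of the logistic response carry a
minus sign in the denominator (1/(1 − e^{−S})), which is not a
probability — it exceeds 1 for S > 0 and diverges at S = 0; we
implement the standard logistic and keep the as-printed variant behind
`logistic_ntcp(..., as_printed = TRUE)` strictly for audit.

A Lyman–Kutcher–Burman (probit) model is provided for completeness:
`lkb_ntcp()` maps the generalized equivalent uniform dose through the
standard normal CDF at u = (EUD − TD50)/(m · TD50), with
`generalized_eud()` computing (mean Dᵃ)^{1/a}. The LKB parameters are
not pinned by the decision method; the defaults (TD50 = 76.9 Gy,
m = 0.13, a = 11.9) are literature-style late-rectal values and are
plain config entries, not fitted quantities. The logistic model is what
the decision rule consumes.

### Fractionation correction

The prescription (67.5 Gy RBE in 25 fractions, 2.7 Gy/fraction) is
hypofractionated relative to the 2 Gy/fraction convention of the V6300
predictor, so physical dose is converted voxelwise to EQD2 under the
linear-quadratic model: EQD2 = D · (d + α/β)/(2 + α/β) with
d = D/n. We use α/β = 3 Gy, the standard late-rectal-toxicity value;
the exact transform and α/β are the main fidelity risk of the chain
(the source decision method names a biologically-effective-dose
transform without writing it), so both are exposed in
`fractionation_params()`. At 2 Gy/fraction the transform is the
identity; at 2.7 Gy/fraction it maps 67.5 Gy to 76.95 Gy, which is why
the prescription region clears the 63 Gy threshold comfortably and the
decision hinges on the dose gradient across the rectum wall.

## Synthetic cohort: what the generator emulates

`generate_phantom()` builds parametric pelvic anatomy on a
64 × 64 × 48-voxel grid at 2.5 mm isotropic spacing (fixed axis
convention (z, y, x) = superior→inferior, anterior→posterior,
right→left; one convention throughout avoids margin-direction bugs).
Organs are ellipsoids, tubes and shells: prostate + seminal-vesicle CTV,
a full-length rectum tube abutting the posterior CTV surface (per-case
gap 1 ± 1.75 mm, occasionally touching), a 3 mm rectum wall shell, bladder, femoral heads, sigmoid colon, small-bowel
compartment, and — in dual-gradient cases — pelvic lymph-node bands plus
a presacral band forming a second CTV. The default grid size was chosen
so DVH statistics are stable while a full cohort plans in about a
minute.

Clinical margins are applied exactly: PTV1 = CTV1 + 1.0 cm in five
directions and 0.5 cm posteriorly; PTV2 = CTV2 + 1.0 cm
superior/inferior, 0.7 cm left/right/anterior, 0.5 cm posterior.
`expand_ctv_to_ptv()` implements the expansion as a separable,
direction-signed box dilation (a voxel joins the PTV iff each signed
axis distance to some CTV voxel is within that direction's margin),
because clinical margins are prescribed per direction — including
different margins along one axis — which a Euclidean dilation cannot
express. Tests verify it against an exhaustive O(V²) oracle.

Because the posterior margin exceeds the typical prostate–rectum gap,
the anterior rectum wall overlaps PTV1 in most cases; this overlap
crescent, which receives prescription-level dose from *both*
modalities, plus the modality-dependent dose bath just beyond it, is
exactly the geometry the selection problem lives on. Covariates are
drawn per case: dual-gradient assignment (default 35% of cases, nodal
prescription 45 or 50 Gy), and anticoagulant use (default prevalence
25% — the source cohort's prevalence is unreported, so this is a knob
with no fidelity claim). Cohorts are bit-reproducible: per-case seeds
derive from the cohort seed, and generators save/restore the global RNG
state.

What the phantoms do **not** emulate: CT heterogeneity that matters for
transport (everything is water-equivalent soft tissue with cosmetic
intensity levels), organ deformation between fractions, intra-observer
contouring variation, and implants. Passing tests therefore demonstrate
that the *pipeline* behaves correctly on anatomy with the right
topology and scale, not that the dose engines are dosimetrically
faithful to any clinic.

## Dose engines

`plan_dose()` is a ray-tracing dose-painting surrogate, not an inverse
optimiser. Per axial slice and beam direction, the slice is rotated so
the beam runs along the image rows (nearest-neighbour maps, precomputed
per angle), depth is measured from the body entry per ray, an analytic
depth-dose kernel is accumulated within a conformal aperture (the
target's beam's-eye projection with a 3 mm Gaussian penumbra), and the
slice is rotated back.

* **Photon (VMAT-like)**: a 360° arc discretised at 10° with a
  build-up/exponential kernel (`photon_depth_dose()`: linear build-up to
  1.0 at 15 mm, then e^{−0.005 d}); many low-weight directions produce
  the characteristic dose bath.
* **Proton (IMPT-like)**: the four fixed clinical gantry angles (90°,
  270°, 150°, 210°); each ray carries a spread-out Bragg peak
  (`sobp_depth_dose()`, built from the pristine `bragg_depth_dose()`
  shape: entrance plateau ≈ 0.33 of peak, flat top across the target,
  distal range margin 4 mm, Gaussian distal falloff below 5% within
  ~6 mm). In dual-gradient plans the nodal component uses the lateral
  fields only, keeping distal edges out of the rectum, as a planner
  would.

Two optimiser-like behaviours are grafted on, because a flat conformal
sum cannot reproduce them: (1) a rectum-sparing gradient — inside the
rectum, outside any target, the attainable dose falls linearly with
voxel-shell distance from the target down to 50% beyond ~6 shells —
emulating the trade-off an optimiser buys; and (2) hotspot caps at
103.5% of the component prescription, reflecting the Dmax constraints
(< 7000 cGy rectum at a 6750 cGy prescription). Each component is then
rescaled so ≥ 95% of its target receives the prescription (the
acceptable-variation fallback to 90% applies when geometry makes 95%
infeasible), overlapping components combine by maximum, and a seeded,
spatially smoothed 1.5% multiplicative noise field emulates
plan-to-plan delivery variability. `check_plan_criteria()` scores any
dose map against the protocol table (per-protocol vs
acceptable-variation vs fail; missing ROIs flagged, never thrown).

These choices were calibrated once, at design time, against clinical
plausibility targets: rectum-wall V6300 in the 5–25% range, proton
integral dose a bit under half of photon, PTV coverage ≥ 95%, and a
cohort that contains both photon- and proton-favoured cases. They were
then frozen; the package makes no claim of fidelity to any treatment
planning system's optimizer.

## Learned dose prediction

`build_model()` assembles the image-to-dose regressor: a 7×7 stem
convolution (stride 2) with 3×3 max pooling, four stages of bottleneck
residual blocks (1×1 reduce → 3×3 → 1×1 expand with identity or
projection shortcuts; the second stage strided so the deepest features
sit at 1/8 resolution), then a decoder of three stride-2
fractionally-strided deconvolutions interleaved with 3×3 convolutions
restoring full resolution, and a linear 3×3 regression head. Inputs are
three aligned channels per axial slice: min-max-normalised CT, a
structure map with each ROI at a distinct level in [0, 1], and the
dose-painted target map (prescription painted into PTV voxels — both
levels for dual-gradient cases — normalised by the PTV1 prescription).
The full-depth configuration `block_counts = c(3, 4, 23, 5)`,
`base_filters = 64` (a 101-layer-class residual encoder) is
constructible and covered by a build test; all training runs use the
desk-scale variant `c(1, 1, 2, 1)` × 4 filters, which trains in minutes
on one CPU.

Everything is implemented in R on BLAS matrix kernels (im2col
convolutions with cached index plans; the stride-8 information path and
the transposed convolutions have exact, bijective scatter gradients).
Training is mean-squared error on prescription-normalised dose, Adam
(lr 2 × 10⁻³), global gradient-norm clipping at 1.0 (without which
training diverges for some seeds), batch 8, seeded shuffling — bitwise
reproducible for a fixed config. The loss and optimiser are our
choices; the source method reports none. A design note: the single
stride-8 deconvolution we tried first restores resolution exactly but
produces visibly blocky dose and inflated errors at steep gradients —
precisely where the rectum wall lives — which is why the decoder
upsamples progressively.

`crossvalidate()` implements the five-fold protocol: a seeded
round-robin partition after shuffling (48 cases → fold sizes
10/10/10/9/9), each case predicted exactly once by a model that never
saw it, per-ROI error reported as the prescription-normalised MAE —
per case the mean over ROI voxels of |pred − truth|/prescription × 100,
pooled as the unweighted mean over cases, so small and large organs
weigh cases equally. The non-learning reference is the voxelwise mean
of the training-fold ground-truth maps; beating it is the minimum bar
for "the network learned anatomy-conditional dose", and the held-out
rectum-wall MAE vs this baseline is the pipeline's learning-sanity
gate. At the test scale (16 cases, training on every 2nd–4th slice,
10–18 epochs) the predictor's held-out rectum-wall MAE runs 30–50%
below the baseline; target-region MAE benefits less, since the compact
high-dose region is harder for a bottleneck architecture without skip
connections — a known cost of the plain encoder–decoder design we
deliberately kept.

## Evaluation statistics

Decisions predicted from learned doses are scored against engine-truth
decisions with proton as the positive class: accuracy, SEN = TP/(TP+FN),
SPE = TN/(FP+TN), and ROC/AUC. The ROC needs a continuous score behind
the binary decision; since none is prescribed, the default ranks cases
by predicted ΔNTCP, with step-1-gated cases pushed below all step-2
cases via min(Δ, NTCP_photon − threshold) — documented, overridable
(`evaluate_cohort(scores = ...)`), and reported alongside the
binary-only AUC (SEN+SPE)/2 for transparency. `roc_auc()` sweeps
thresholds over the observed scores and integrates by trapezoid, which
with midrank ties equals the Mann–Whitney statistic; tests check it
against an exhaustive pair-ordering oracle and against an independent
library implementation.

Agreement between engine and predicted dosimetry uses the paired
two-tailed t-test on V6300 and NTCP per modality, with Shapiro–Wilk
normality (on the paired differences) and Levene variance checks
attached as advisory reports — they never switch the test, matching the
declared parametric analysis. Degenerate inputs are defined explicitly:
all-zero differences give t = 0, p = 1; constant non-zero differences
are flagged rather than producing an unstable statistic.

## Numerical and engineering choices

* Internal dose unit is cGy end to end (the unit of the protocol
  table); Gy appears only in the LQ/EUD formulas with explicit
  conversion.
* V_D metrics use exact voxel counting with a closed lower bound
  (dose ≥ threshold); the binned DVH curve (`compute_dvh()`, default
  10 cGy bins) is for reporting only, so the NTCP predictor never
  inherits binning error.
* Margin voxel counts use floor(margin/spacing) with a 10⁻⁹ tolerance
  so an exact multiple of the spacing includes its boundary layer.
* Model inputs whose height/width is not divisible by 8 are padded
  internally and cropped after the decoder; shape contracts never
  throw.
* All stochastic stages (anatomy, covariates, delivery noise, weight
  init, shuffling, fold assignment) draw from seeds derived from a
  single configurable seed and restore the caller's RNG state.
* `run_pipeline()` caches stage outputs under `out_dir/cache` keyed by
  stage name, making re-runs idempotent; logs are one structured line
  per case and stage with seed provenance.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 16–20
phantoms on the default grid, five-fold cross-validation with the tiny
model configuration (photon: 10 epochs on every 3rd slice; proton: 18
epochs on every 4th slice — the proton dose field's compact support
makes its loss landscape slower to traverse, so it gets a longer
schedule), and 201×201-point rule enumerations. These sizes were chosen
as the smallest at which every qualitative property of the method is
exercised with comfortable statistical margin.

## Known limitations

* The dose engines are surrogates; absolute DVH/NTCP levels depend on
  their calibration and should not be read as clinical values. Cohort
  headline numbers from clinical studies (accuracy, AUC, MAE tables)
  are not reproduction targets here.
* The EQD2 route into the V6300 predictor, and α/β = 3, are assumptions;
  both are config-exposed.
* The logistic NTCP model was developed for proton cohorts; applying it
  to photon plans inherits that external-validity caveat.
* 2-D slice-wise prediction ignores superior-inferior dose correlations;
  a 3-D model would need resources out of scope for this package.
* Single-class truth cohorts (all-photon or all-proton) have undefined
  SEN/SPE/AUC; `evaluate_cohort()` returns `NA` for these rather than
  guessing.
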