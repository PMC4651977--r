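---
title: "Scan-rescan repeatability of automated plaque classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-rescan repeatability of automated plaque classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plaquerep studies a practical question in carotid vessel-wall imaging: when
the same patient is scanned twice within a short interval, how consistently
does a segmentation method recover the areas of atherosclerotic plaque
components (fibrous tissue, lipid-rich necrotic core, calcification, loose
matrix) from multi-contrast MRI — and is a trained pixel classifier more
consistent than a human reader?  Because real paired carotid MRI data with
expert annotations are not freely available, the package pairs the analysis
pipeline with a synthetic cohort generator whose perturbation structure
emulates the main sources of scan-rescan variability, so that every claim
made by the statistics can be checked against a known ground truth.

This vignette records the models, the tunable parameters and the reasoning
behind the design decisions, in the spirit of a methods section.

## The synthetic cohort

Each simulated patient owns one continuous anatomy: an outer vessel wall
ellipse and a smaller, eccentric lumen ellipse whose center, size and
orientation drift slowly along a through-plane coordinate $z$ (measured in
slice units).  The wall is the annulus between the two contours.  Plaque
components live in wall-relative coordinates — an angular position around
the lumen, a band of normalized radial depth $t \in [0,1]$ (0 at the lumen,
1 at the outer boundary), and a parabolic through-plane profile — so a
lesion tapers smoothly toward its ends, as real lesions do in stacks of 2 mm
slices.  Lipid cores sit toward the lumen ($t \le 0.75$), loose matrix
toward the adventitia ($t \ge 0.25$), calcification anywhere in the wall.
Where lesions overlap, assignment priority is calcification, lipid, loose
matrix: calcification dominates its neighbourhood visually and
histologically.

The acquisition geometry defaults to the protocol the analysis targets: a
120 × 120 matrix at 0.5 × 0.5 mm² pixels (60 mm field of view), 8 axial
slices of 2 mm.  Patient-level component prevalences default to values
typical of a symptomatic 30–70 % stenosis cohort — lipid 43 %,
calcification 87 %, loose matrix 65 % — and fibrous tissue is, by
definition of the model, present in every wall.  Mean per-slice lesion
areas default to 17.5 / 12.2 / 15.8 mm² for lipid / calcification / loose
matrix, drawn lognormally per lesion (coefficients of variation 0.45–0.55)
and truncated at 90 % of the annulus band capacity so a heavy-tailed draw
cannot exceed the wall; a configuration whose *mean* lesion cannot fit is
rejected outright.

Intensities are phenomenological, not an MR physics simulation.  Every
tissue has a mean signal relative to fibrous tissue (= 1.0) on each of the
four weightings, encoding the standard visual criteria: calcification
hypointense on all four weightings (0.4); lipid hyperintense on T1w and PDw
(1.35); loose matrix hyperintense on T2w and PDw (1.4).  Lipid's T2w
contrast is left neutral, as the visual criteria do not commit to one.  A
pixel's value is its class mean times a per-session, per-weighting
multiplicative drift, plus additive Gaussian noise (default SD 0.08 in
relative-intensity units, roughly SNR 12 against the wall reference — a
plausible 3T vessel-wall regime).  The intensity table is a configuration
argument, never a constant: the relative ratios are a stand-in for
quantities the visual criteria only order, not measure.

### The rescan

Session 2 re-images the same anatomy under four perturbations, each with
its own configuration field and each reducible to zero:

* an integer **through-plane stack shift** (default 1 slice).  The
  bifurcation index is carried as alignment ground truth, so slice matching
  by bifurcation reproduces the stack offset exactly;
* a **sub-slice through-plane misalignment** (Gaussian, SD 0.35 slices,
  truncated at half a slice).  Integer alignment cannot correct motion
  smaller than the slice thickness; because lesions taper in $z$, this
  residual misalignment changes true component areas between sessions and
  forms a common repeatability floor that affects the manual and the
  automated method identically.  Omitting it would make the automated
  pipeline implausibly repeatable;
* a small **in-plane translation** (Gaussian, SD 0.2 mm) of the whole
  anatomy, standing in for repositioning;
* a per-weighting multiplicative **intensity drift** (SD 0.05), which the
  median-ROI normalization is designed to remove, plus fresh noise.

### The simulated observer

The manual reader is modelled with two error mechanisms:

1. **Omission of small components.** A component whose area in a slice is
   below `small_area_threshold_mm2` (default 8 mm²) is missed with
   probability `p_miss_small` (default 0.35), its pixels read as fibrous.
   This produces the one-sided detections that populate the steep
   $|d| = 2\bar{x}$ line of a Bland–Altman plot.
2. **Intensity-bias-driven boundary placement.**  Each reading session
   draws one intensity bias (SD `session_bias_sd` = 0.08 relative units).
   For a component whose mean contrast against fibrous tissue is $m$, the
   perceived boundary displaces by `round(bias / m + jitter)` pixels
   (eroding or dilating the region within the wall), so faint classes move
   much more than conspicuous ones.  Components with $m$ at or above
   `reliable_contrast` (default 0.5) are traced without jitter at all: a
   region dark on all four weightings is delineated the same way twice.

All random decisions of a read are drawn up-front from the session seed
with a fixed call pattern, which gives the model two properties the
analysis relies on: re-reading the same session reproduces the same labels
exactly (high intra-observer agreement), and increasing `p_miss_small`
can only remove detections, never add them (monotone degradation).

The observer parameters are a deliberate calibration, not a fit to any
patient data: they are chosen so that, under the default configuration, the
manual reader's scan-rescan coefficient of repeatability exceeds the
automated classifier's for the low-contrast classes (lipid, loose matrix)
while remaining comparable for calcification — the qualitative regime the
pipeline is built to study.  The magnitudes of the resulting CRs are a
property of the synthetic world and carry no claim about any real cohort.

## Feature extraction

Within each slice the pipeline uses only the vessel wall, rasterized from
the two contours by a pixel-center containment rule (outer boundary
inclusive, lumen boundary counted as wall).  Features per wall pixel, 127
in total under the defaults:

* **Normalized signal intensity** (4): each weighting divided by the median
  of its own 4 cm circular ROI centered at the lumen.  The median is robust
  to the lumen and plaque pixels inside the ROI, and division removes any
  session- or weighting-level multiplicative drift; the operation is
  idempotent and scale-invariant by construction.
* **Scale-space derivatives** (4 weightings × 5 scales × 6 responses =
  120): the full second-order jet $\{L, L_x, L_y, L_{xx}, L_{xy},
  L_{yy}\}$ at $\sigma$ = 0.1, 0.25, 0.5, 1, 2 mm, computed by separable
  correlation with sampled-Gaussian derivative kernels, reflect padding,
  and $\sigma^k$ (γ = 1) scale normalization of order-$k$ derivatives so
  responses are comparable across scales.  The derivative kernels are
  renormalized to be exact on polynomials of their order (a first-order
  kernel has unit response to a unit ramp, a second-order kernel is
  zero-sum with unit response to $x^2/2$); this matters at the smallest
  scale, where $\sigma$ = 0.1 mm is only 0.2 pixels and a raw sampled
  kernel would be badly biased.  The jet choice, the scale normalization
  and the derivative orders are all configuration, since reasonable
  variants exist (gradient magnitude, unnormalized derivatives).
* **Wall geometry** (3): distance to the lumen boundary, distance to the
  outer boundary (polygons resampled at ≤ 0.1 mm arc spacing, pixel-center
  to nearest point), and local wall thickness as their sum.

Filtering runs on a window cropped to the wall's bounding box grown by the
largest kernel radius, which leaves responses on wall pixels bit-identical
to full-image filtering.  Slices missing any weighting are excluded from
feature building and counted in an exclusion log, and the same slices are
excluded from the area statistics of every method so all methods are
compared on one slice basis.

## The classifier

A linear discriminant: each class is a multivariate Gaussian with its own
mean and one pooled covariance, so posteriors reduce to linear discriminant
functions.  Priors follow a fixed rule: fibrous tissue receives 0.55, and
the remainder is split across the other classes in proportion to their
training frequencies, which counteracts the fibrous-majority bias a plain
frequency prior would impose on the minority plaque classes.  Pixels take
the maximum-posterior class; exact ties (a measure-zero event) go to the
earlier class in the fixed order fibrous, lipid, calcification, loose
matrix, ulceration, hemorrhage.

The pooled covariance is shrunk toward its diagonal with coefficient
$10^{-4}$, with degenerate diagonal entries floored at 1 % of the mean
diagonal: with 127 features, small training folds and noise-free test
cohorts the raw estimate can be singular, and the floor keeps the
deliberately noise-free parameter-recovery configurations invertible.  A
covariance that remains numerically singular (condition estimate below
$10^{-13}$) raises an error advising shrinkage rather than producing
garbage posteriors.  Optional feature standardization exists as a flag
(default off) because the original analysis regime is not known to have
used it.

**Post-processing.**  A pixel that is the only pixel of its component in a
slice is relabelled to the modal class of its in-mask neighbours in a 3 × 3
window (center excluded; neighbourhood ties keep the earliest class in
canonical order; a singleton with no in-mask neighbour becomes fibrous).
All singletons are resolved in one simultaneous pass against the original
labels.

**Cross-validation.**  Leave-one-patient-out at the dataset level: each of
the $2n$ patient-sessions is predicted by a model trained on the $2(n-1)$
datasets of all other patients — both sessions of the test patient are
excluded, so the test patient's pixels can never leak into training.
Training labels are the simulated observer's read (the classifier learns
from the expert, errors included); ground truth is reserved for
evaluation.  Folds are assembled from per-dataset, per-class sufficient
statistics (counts, feature sums, cross-products), which makes each fold's
pooled covariance the global accumulation minus the held-out patient's
terms — algebraically identical to refitting from scratch and roughly 40×
cheaper, which is what makes multi-seed experiments affordable on one CPU.

## Quantification and statistics

Areas are pixel counts times the pixel area; the class areas of a slice
partition the wall area exactly.  Volumes are slice-area sums times the
slice thickness.  Scan pairs are aligned by matching bifurcation indices;
slices without a partner are dropped and counted.  A component is present
for a patient-session if its total area there is positive (after
post-processing) — a deliberately simple presence rule, recorded as such.

Per class and method, on aligned slice pairs:

* **Spearman correlation** (average ranks under ties) with a Fisher-z
  confidence interval using variance $1.06/(n-3)$, the Fieller correction
  appropriate for rank correlations.  The correlation is binned into the
  conventional qualitative categories, with the 0.80 boundary assigned
  upward (excellent) and the other stated ranges closed at their upper
  edge; the published category edges are ambiguous exactly at 0.8, so the
  convention is documented rather than guessed.
* **Bland–Altman**: bias (mean of $v_1 - v_2$), sample SD of differences,
  limits of agreement bias ± 1.96 SD, and the coefficient of repeatability
  CR = 2 SD.  Both multipliers are configuration.  Pairs with exactly one
  zero member are flagged: they are detections in one scan only and fall
  on the $|d| = 2\bar{x}$ line (slope $\arctan 2 \approx 63.4^\circ$) of
  the plot.
* **Levene's test** (classic group-mean centring, one-way ANOVA on
  absolute deviations) compares the spread of inter-scan differences
  between the manual and automated methods — the formal test behind "one
  method is more repeatable".
* **Wilcoxon matched-pairs** tests the bias against zero, since inter-scan
  area differences are not normally distributed (checked per class with
  the **D'Agostino–Pearson** omnibus test, $K^2 = Z_{skew}^2 +
  Z_{kurt}^2 \sim \chi^2_2$, implemented from the standard transformed
  skewness and kurtosis statistics).  Zero differences are dropped; for
  ≤ 25 non-zero differences the p-value is exact, computed by convolving
  the signed-rank distribution over doubled (hence integer) average ranks,
  which stays exact under ties — a case the textbook enumeration and the
  standard implementation both decline; beyond 25 a normal approximation
  with continuity and tie correction is used.  An all-zero difference set
  is returned as a flagged degenerate result, not a p-value.

Pairs entering the per-class Spearman and Bland–Altman computations default
to those where the component is present in at least one session for that
method (`pair_inclusion = "any_nonzero"`): slices where a component is
absent in both scans carry no information about that component's
measurement repeatability, and padding the correlation with (0, 0) pairs
would inflate it.  The alternative `all_pairs` is available.  No
multiple-testing correction is applied — the battery is reported
per-class at α = 0.05, and the report is descriptive rather than
confirmatory.

## What the generator does and does not emulate

It emulates: co-registered multi-contrast slices; annular wall geometry
with manually-traced-style contours; class-wise relative intensity rules;
patient-level component prevalence and lesion size/taper; scan-rescan
stack shift, sub-slice misalignment, drift, repositioning and noise; and a
reader whose errors are small-component omission and contrast-dependent
boundary placement.

It does not emulate: MR physics (sequences, flow, gating, blood
suppression), coil sensitivity bias fields (assumed already corrected),
Rician noise statistics, in-plane rotation or non-rigid motion,
inter-sequence misregistration (slices are generated co-registered; the
manual registration step of a real workflow is out of scope), reader
fatigue or drift over a session, inter-observer variability (one observer
model), and histology-grade truth.  Passing tests therefore demonstrate
that the pipeline's statistics behave correctly and that the qualitative
manual-versus-automated ordering emerges under the modelled error
structure — not that any particular CR magnitude transfers to patients.

## Numerical choices and problem sizes

Polygon containment uses an even-odd ray-crossing test with explicit
on-edge handling (outer boundary inclusive, lumen exclusive); pixel
rasterization only tests pixels inside the polygon's bounding box.  The
test suite cross-checks containment against an independent implementation.
Distances use polygons resampled at 0.1 mm.  Lesion draws are truncated,
never resampled, to keep the draw count — and hence reproducibility —
independent of parameter values.  Seeds derive hierarchically from the
single experiment seed (patient → stage → session), so any subset of the
pipeline is reproducible in isolation; all derived seeds stay below
$2^{31}$.

Unit tests run on miniature cohorts (2–4 patients, 3–4 slices, 60 × 60
grids) where every oracle can be brute-forced; the end-to-end acceptance
checks use the shipped default configuration (23 patients, 8 slices,
120 × 120) across ten seeds for the headline ordering, and a 5-patient
clean-cohort configuration for parameter recovery.  These sizes are the
package's chosen experiment scale: large enough for the orderings to be
stable across seeds, small enough to iterate on a single CPU.

## Known limitations

The observer model has no spatial correlation in its errors beyond whole
regions, and its miss mechanism is a hard threshold.  The LDC inherits the
usual linear-discriminant assumptions (shared covariance, Gaussian
classes); no nonlinear classifier is in scope.  Ulceration and hemorrhage
are representable (and classifiable when enabled) but excluded from the
quantitative battery, mirroring their rarity in the clinical population
the defaults describe.  The Fisher-z CI for Spearman's r is approximate at
small n; a bootstrap is the natural extension.  Volumes are slab sums of
pixel areas, not mesh-based.
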