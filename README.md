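# plaquerep

Scan–rescan repeatability of automated carotid plaque component
classification from multi-contrast vessel-wall MRI.

## The problem

Multi-contrast carotid MRI (T1w, T2w, PDw, TOF) can characterize the
composition of atherosclerotic plaque — fibrous tissue, lipid-rich necrotic
core, calcification, loose matrix — inside the manually traced vessel wall.
Longitudinal studies need those component areas to be *repeatable*: if the
same patient is scanned twice within a month, the measured areas should
agree. Manual delineation is the reference standard but is labour-intensive
and sensitive to how a reader resolves low-contrast boundaries on a given
day. plaquerep implements, end to end, the competing approach: a supervised
pixel classifier trained on an expert's segmentations, and the statistical
battery that decides whether the classifier is more scan–rescan repeatable
than the expert.

Because paired carotid MRI with expert annotations is not publicly
available, the package includes a first-class synthetic cohort generator:
annular vessel-wall phantoms with known per-pixel tissue labels, imaged
twice under realistic rescan perturbations (stack shift, sub-slice
through-plane misalignment, intensity drift, repositioning, noise), read by
a simulated imperfect observer. Every statistic the package reports can
therefore be validated against ground truth.

## The method

Per wall pixel, 127 features: the four normalized signal intensities (each
weighting divided by the median of a 4 cm circular ROI at the lumen), the
full Gaussian scale-space jet {L, Lx, Ly, Lxx, Lxy, Lyy} at sigma = 0.1,
0.25, 0.5, 1, 2 mm per weighting (scale-normalized), and three wall-geometry
features (distance to lumen, distance to outer wall, thickness). A linear
discriminant classifier — one Gaussian per class with a pooled covariance —
assigns each pixel the maximum-posterior class, with the fibrous-tissue
prior fixed at 0.55 and the remainder distributed by training frequency.
Isolated pixels (the only pixel of their component in a slice) are
relabelled to the 3×3 neighbourhood majority. Evaluation is
leave-one-patient-out: both scans of the test patient are held out,
training labels come from the observer's read.

Repeatability of the resulting per-slice component areas is quantified on
bifurcation-aligned scan/rescan slice pairs with Spearman's r (with
Fisher-z CI and the conventional poor/fair/satisfactory/good/excellent
bins), Bland–Altman bias, 95 % limits of agreement and the coefficient of
repeatability CR = 2 × SD of the paired differences, Levene's test for
comparing the difference variances between methods, the Wilcoxon
matched-pairs test for bias (exact under ties up to n = 25), and the
D'Agostino–Pearson normality check.

## Worked example

```r
library(plaquerep)

cfg_file <- system.file("extdata", "demo_experiment.yaml", package = "plaquerep")
res <- run_experiment(validate_config(cfg_file))  # 4 patients, ~30 s
print(res$report)
```

```
<repeatability_report> 4 patients, 8 datasets, 20 aligned slice pairs

Scan-rescan repeatability (area, mm2):
    method         class     r agreement   bias    cr n_pairs
 automated calcification 0.909 excellent -0.650  3.45      10
 automated       fibrous 0.939 excellent  1.050  5.90      20
 automated         lipid 0.929 excellent -1.321  4.14       7
 automated  loose_matrix 0.638      good  0.583 10.46       6
    manual calcification 0.619      good -1.719  6.85       8
    manual       fibrous 0.748      good  0.487 13.15      20
    manual         lipid 0.655      good  2.714 16.23       7
    manual  loose_matrix 0.754      good -1.042  7.39       6

CR comparison (Levene):
         class levene_W levene_p cr_manual cr_automated
       fibrous    4.832   0.0341     13.15         5.90
         lipid    8.433   0.0132     16.23         4.14
 calcification    2.149   0.1621      6.85         3.45
  loose_matrix    0.315   0.5868      7.39        10.46
```

Reading the output: each row summarizes the paired scan/rescan areas of one
tissue class under one segmentation method. For lipid, the automated
classifier's coefficient of repeatability (4.14 mm²: two measurements of
the same plaque are expected to agree within about 4 mm² for 95 % of
pairs) is far below the simulated observer's (16.23 mm²), and Levene's
test confirms the variance difference (p = 0.013). Calcification — dark on
all four weightings, hence easy to trace — is similar for both methods. At
this demo size loose matrix has only 6 informative pairs and its ordering
is unstable; the shipped default configuration (23 patients,
`inst/extdata/default_experiment.yaml`) is the scale at which the orderings
are stable across seeds. `tidy(res$report)` returns the full table,
`glance(res$report)` the one-row summary, and
`autoplot(res$report, type = "bland_altman")` the per-class difference
plots (single-scan detections fall on the steep |diff| = 2·mean line).

The pipeline stages are ordinary functions on tibbles if you want the
pieces: `generate_cohort()`, `simulate_observer()`,
`build_feature_matrix()`, `train_ldc()`, `classify_pixels()`,
`remove_isolated_pixels()`, `lopo_crossval()`, `component_areas()`,
`align_scan_pairs()`, `bland_altman()`, `levene_test()`, `build_report()`.
See `vignettes/plaque-repeatability.Rmd` for the models and the reasoning
behind the defaults.

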