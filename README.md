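# kneemoments

Automatic detection and Kellgren–Lawrence (KL) grading of knee
osteoarthritis from plain radiographs, built on Hu's seven moment
invariants.

Knee OA erodes the cartilage between femur and tibia; on a radiograph this
shows as narrowing of the radiolucent *joint space* between the two bone
shadows, plus marginal osteophytes. `kneemoments` implements the full
measurement chain for the five-level KL scale (Normal, Doubtful, Mild,
Moderate, Severe):

1. 3×3 median denoising and bone-contour detection (Otsu threshold +
   boundary tracing);
2. joint-space ROI localisation by **pixel density**: the smoothed
   directional intensity-sum profile of a knee film has two high plateaus
   (femur, tibia) around a valley at the joint line;
3. segmentation of the joint space with a region-based two-phase
   **active contour** (3×3 morphological smoothing per iteration, darker
   phase kept);
4. **Hu invariant moments** of the segmented region. For intensities
   f(x,y), raw moments m_pq = Σ Σ x^p y^q f(x,y), central moments μ_pq about
   the centroid (m10/m00, m01/m00), normalised moments
   η_pq = μ_pq / μ00^γ with γ = (p+q)/2 + 1, combined into the seven
   invariants φ1…φ7 (translation-, scale- and rotation-invariant; φ7 flips
   sign under reflection);
5. **k-NN grading** (k = 3, standardised Euclidean distance) under
   stratified two-fold cross-validation, with a CART decision tree as the
   comparison classifier;
6. evaluation and inter-rater agreement statistics: multiclass
   precision/recall in two denominator conventions, a goodness-of-fit
   chi-square on per-grade counts (expected count = average of the two
   raters), and the paired t statistic over per-grade count differences.

Everything is testable without clinical data through a deterministic
synthetic knee-phantom generator (bright femur/tibia bands, grade-dependent
joint-space gap, osteophyte bumps, clipped Gaussian noise) that carries its
own ground truth. The package also ships, as plain CSV, the printed
evaluation tables of a published 2,000-radiograph grading study (two expert
raters), which the metrics reproduce exactly.

## Worked example

```r
library(kneemoments)

# A labelled cohort of 200 phantoms (40 per grade), end-to-end features.
feats <- generate_feature_dataset(n_per_grade = 40, seed = 11, noise_sd = 5)
cv <- two_fold_cv(feats, k = 3, seed = 2)
glance(cv)
#> # A tibble: 1 × 4
#>   classifier     n accuracy  seed
#>   <chr>      <int>    <dbl> <int>
#> 1 knn          200     0.98     2

# The bundled reference tables reproduce the published headline numbers.
ref <- kl_reference_tables()
overall_accuracy(ref$confusion_expert1)
#> [1] 0.998
precision_recall(ref$confusion_expert1, convention = "paper")$precision
#> [1] 0.9953917 0.9981061 1.0000000 1.0000000 1.0000000

chi_square_agreement(ref$grade_counts$algorithm_expert1,
                     ref$grade_counts$expert1)
#> <agreement_test> chi-square: statistic = 0.006858, df = 4
#>   critical = 9.48773 (alpha = 0.05) -> accept-H0

paired_t_agreement(ref$grade_counts$expert1, ref$grade_counts$expert2)
#> <agreement_test> paired-t: statistic = 0.000000, df = 4
#>   critical = 2.13185 (alpha = 0.05) -> accept-H0
```

The k-NN cross-validation accuracy of 0.98 says the pipeline recovers the
grade of 98% of noisy phantoms from the segmented joint-space shape alone;
the two agreement tests accept the consensus hypothesis (statistic below the
critical value), i.e. the algorithm's per-grade counts are statistically
indistinguishable from the experts' annotations.

A command-line interface wraps the same functions
(`exec/kneemoments <simulate|features|fit|grade|evaluate|stats>`), writing
PNG phantoms with JSON ground-truth sidecars, CSV feature tables,
JSON-persisted k-NN models, and schema-validated JSON run reports with
distinct exit codes per failing stage.

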