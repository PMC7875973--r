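---
title: "Predicting individual task activation from resting-state connectivity: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual task activation from resting-state connectivity: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task-fMRI contrast maps differ reliably between people: the spatial layout of
language, working-memory or relational-processing activations follows each
subject's individual functional anatomy. Resting-state fMRI measures that
anatomy without any task, through the covariance structure of spontaneous
activity. This package implements and validates a family of encoding models
that predict a held-out subject's cortical task contrast map from features of
their resting-state functional connectivity, together with the baselines and
the evaluation machinery needed to decide whether such predictions are ever
better than trivial group averaging.

The data model follows the HCP grayordinate convention: one combined spatial
axis of `n_total` positions of which `n_cortex` are cortical surface vertices
(the prediction targets live on the cortex only; subcortical positions
contribute features). A subject's rest acquisition is a `n_total x t` matrix
`X`; a task contrast is a length-`n_cortex` z-map `y`.

## Preprocessing contract

Every rest scan is preprocessed identically before feature extraction: the
first 5 frames of each run are discarded, runs are concatenated, and every
grayordinate row is demeaned and scaled to unit variance (population
normalization, `mean(x^2) = 1`). "Unit variance" is applied per grayordinate
over the concatenated post-discard frames: at this stage the only meaningful
"feature" axis is the grayordinate axis. Zero-variance rows are set to zero
rather than dropped, so that all downstream matrices keep a fixed shape; their
count is carried on the scan object. Preprocessing is idempotent. No spatial
smoothing is ever applied.

An open ordering question — whether variance normalization should happen
per run before concatenation or once after — is resolved here as per-run
*discard* followed by one global row normalization; since the runs are
generated (and, in real data, acquired) under matched conditions, the two
orders differ only marginally, and the global choice keeps the contract
simple.

## Feature extraction: the semi-dense connectome

All covariance-based extractors share one algebraic form,

    G = t(A) %*% X %*% t(X),

an `f x n_total` matrix of covariances between `f` projected time series and
every grayordinate — a "semi-dense connectome". The projection `A` determines
the method:

* **Parcel means** (`parcel_projection`): column `k` holds `1/|region k|` on
  the region's members, so projected series are region means. We use
  averaging rather than 0/1 indicator sums: Pearson-based scoring is
  scale-invariant but the ridge penalty is not, and averaged features put
  regions of different sizes on one scale.
* **Gaussian random projections** (`gaussian_random_projection`): entries
  i.i.d. `N(0, 1/f)`. The Johnson–Lindenstrauss alternative to an expert
  parcellation; `f = 379` mirrors the parcel configuration at full scale.
* **Group ICA** (`group_ica`): subject-level PCA in the time dimension,
  concatenation, group-level PCA, and a FastICA rotation (log-cosh contrast,
  symmetric decorrelation, at most 500 iterations, component signs fixed so
  each map's largest-magnitude entry is positive) into independent spatial
  maps; 80 components by default. The group stage uses concatenation plus
  group PCA; the canonical-correlation variant of the group stage is a known
  alternative, but its parameters are not standardized and the PCA route is
  the common, reproducible reading.
* **Dual regression** (`dual_regression_features`): group maps are regressed
  onto each frame (stage 1: subject time courses), then the time courses are
  regressed onto the data (stage 2: subject-specific spatial maps).
* **PCR semi-partial connectome** (`pcr_semipartial_connectome`): for each
  region, all grayordinates within 10 mm of the region's cortical vertices
  (geodesic metric on the cortex, Euclidean for subcortex) *plus the region's
  own members* are excluded; principal components of the remaining data are
  computed by a seeded randomized SVD (7 power iterations, oversampling 10);
  the region's mean time series is regressed on the component time courses;
  and the coefficients are back-projected to the full axis, with exact zeros
  on the excluded set. Excluding the region's own vertices is forced:
  regressing a mean on its own members is degenerate. 512 components at full
  scale; 64 at the synthetic desk scale used throughout the package's own
  validation, where the post-masking rank is a few hundred.
* **Activity flow** (`activity_flow_features`): a single feature, the
  covariance of each grayordinate with the group-mean activation template of
  the training set.

After extraction, each feature row is demeaned across grayordinates and
scaled to unit Euclidean norm ("unit norm" is read literally as the Euclidean
norm, not unit variance). The unfitted activity-flow model is the exception:
it predicts with the raw feature row, since it performs no fitting at all.

Geodesic distances on the synthetic spherical cortex are exact great-circle
lengths; on real meshes a shortest-path (Dijkstra) approximation along mesh
edges is the intended drop-in — exact polyhedral geodesics are out of scope.

## The vertex-wise ridge model

At every cortical vertex `j` an independent ridge regression is fitted over
training subjects: the design is the `n x f` matrix of subjects' connectome
features at that grayordinate (columns standardized by training mean and SD;
zero-variance columns dropped with zero weights), the target is the vector of
subjects' task z-values at the vertex, centered by its training mean (the
intercept). The penalty `lambda_j` is selected *per vertex* by generalized
cross-validation,

    GCV(lambda) = n * ||(I - H) y||^2 / tr(I - H)^2,

evaluated over the whole grid through a single SVD of the design. `H` is the
hat matrix of the full affine model: the unpenalized intercept contributes
one degree of freedom, `tr(I - H) = n - 1 - sum(d_k^2 / (d_k^2 + lambda))`.
This accounting matters: without the intercept term the criterion degenerates
on wide designs (`f >= n`, the normal regime here), collapsing toward the
smallest grid value and interpolation; with it, selected penalties track the
test-optimal ones. The penalty grid is 30 log-spaced values spanning
`[1e-3, 1e6]` times the design's mean squared singular value, and GCV ties
are broken toward the *largest* tied penalty — under a flat profile more
shrinkage is the conservative choice. A constant target is flagged degenerate
(zero weights, maximal penalty).

Variants: `method = "ols"` fixes the penalty at zero (minimum-norm solution
when under-determined); `"af_mod"` is the two-parameter slope-plus-intercept
fit used with the single activity-flow feature; `fit_parcel_rr` shares one
penalty across a parcel (selected by minimizing the summed per-vertex GCV
curves) while still solving weights per vertex — isolating exactly the
contribution of per-vertex hyperparameters. `fit_anatomical_rr` is the same
per-vertex ridge on 6 anatomical maps. Group baselines: the training-mean map
(`group_mean`) and the per-vertex one-sample t statistic converted to z by
exact tail matching, `qnorm(pt(t, n - 1))`, computed with log-probabilities
so extreme tails stay finite (`group_zstat`).

Targets are never variance-scaled: predictions must live on the z-map scale
for predictive R² to be meaningful.

## Evaluation

Two complementary scores. Per subject, the Pearson correlation between
predicted and observed maps across cortical vertices. Per vertex, the
predictive R²

    R2_j = 1 - sum_i (y_ij - yhat_ij)^2 / sum_i (y_ij - ybar_j)^2,

with `ybar_j` the **test**-subject mean — deliberately the harder denominator:
a model only scores positively where it beats the best constant predictor of
the test cohort itself. Negative values are meaningful and preserved.
Whole-cortex summaries weight each vertex's R² by the test-target variance at
that vertex. Suprathreshold-overlap metrics and intra- vs inter-subject
identification are deliberately absent: the package's evaluation philosophy
is that a prediction only counts where it jumps over the group-mean bar.

Significance machinery: a one-sided paired comparison against the baseline by
sign-flipping the per-subject score differences (5000 draws, add-one p,
Bonferroni across the contrast battery; sign-flips are the standard paired
construction, chosen over label swaps), and, for quantities measured over
repeated train/test
splits, the corrected resampled t-test with variance inflation
`(1/k + n_test/n_train)` and `k - 1` degrees of freedom. Learning curves use
nested training subsets (smaller inside larger) against a fixed test set to
reduce Monte-Carlo variance.

## Behavioral coupling

Per-subject prediction scores are Fisher-z transformed (`atanh`, the
variance-stabilizing transform) and correlated with task accuracy, matched by
subject. Raw accuracies are used rather than rank-normalized ones. The
multi-split benchmark repeats fit/score/correlate over 20 seeded train/test
permutations — identical splits for every model, which the paired corrected
resampled t-test requires — and compares each model's per-split correlations
to the group-mean baseline's on the Fisher-z scale.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the full study: spherical cortical geometry
(Fibonacci lattice, radius 80 mm; subcortical ball below), a seeded
nearest-centroid parcellation, rest scans, task maps, anatomical maps,
behavior, and ground truth. The generative model is

    X_i = t(M_i) T_i + E_i,   M_i = group_maps + deviations_i,

with AR(1) latent time courses (coefficient 0.5, a plausible BOLD
autocorrelation; only the spatial covariance matters downstream) and i.i.d.
measurement noise. Subject deviations are loadings on a fixed basis of 3
smooth spatial "deviation modes": inter-individual variation in functional
topography is low-dimensional. This structure is load-bearing. With free-form
(full-rank per subject) deviation fields, the part of the task signal that
covariance features can linearly resolve caps near half — the remainder is
information-theoretically invisible to any model in the battery — whereas
low-rank deviations make the planted signal essentially recoverable, which is
what a validation cohort must provide.

Task maps share the subject deviations: the contrast's loading vector is
applied to `M_i`, the resulting subject-varying signal is standardized per
vertex and scaled by the SNR profile, and unit-SD noise is added (optionally
heteroscedastic via `noise_sd_profile`). The SNR profile is the central
realism knob: 0.15 on the "primary-sensory" half (essentially stereotyped
across subjects, explainable fraction ≈ 0.02) and 1.0 on the "association"
half (explainable fraction 0.5). The per-vertex oracle ceiling
`snr² / (snr² + 1)` is stored in the ground truth.

Behavior couples to a planted per-subject "rest–task alignment" scalar: each
subject's deviation amplitude is log-normal, its log (standardized) is the
alignment, and accuracy is `coupling * alignment` plus independent noise
(default coupling 0.6). Subjects with large deviations depart further from
the group template, so the group-mean baseline's scores fall with alignment
while fitted models, which track individual structure, are penalized far
less — this separation is what the multi-split behavioral benchmark detects.

Default desk-scale dimensions — 120 subjects (60/60 splits), 600
grayordinates (500 cortical), two runs of 405 frames, 8 latent networks, 12
parcels — keep every validation property computable in minutes on one CPU
while preserving the full pipeline's structure. What the generator does *not*
emulate: realistic folded cortical meshes, head motion and physiological
artifacts, distance-dependent noise correlations, biophysical BOLD forward
models, and task-map noise that is spatially correlated. Passing tests
therefore certify the algebra, the selection machinery and the planted-signal
recovery — not performance on real acquisitions.

## Numerical choices and degenerate inputs

* Zero-variance rest rows, feature rows, design columns and targets are
  zeroed/dropped and counted, never silently propagated.
* GCV ties resolve to the largest penalty; the degenerate all-constant
  target takes the grid maximum with zero weights.
* The t-to-z conversion runs through log-tail probabilities; infinite or
  undefined vertices report 0 and are counted.
* The randomized SVD discards components below `1e-10` of the leading
  singular value before back-projection.
* Permutation p-values use the add-one convention, bounded away from zero.
* The corrected resampled t with zero-variance differences returns signed
  infinity with p in {0, 1} and a degeneracy flag.
* All randomness is seeded; a single benchmark seed fans out to
  stage-specific seeds by a stable string hash, so adding or reordering
  stages cannot silently change another stage's draws.

## Known limitations

The gap between the fitted models and the planted oracle ceiling on
association vertices is structural at the default scale: roughly a tenth of
the planted signal is outside the linear span of covariance features
(features are quadratic in the latent amplitudes, and row normalization adds
a further nonlinearity), and per-vertex ridge estimation from 60 noisy
training targets costs another several hundredths of R². The package reports
the measured ceiling proximity rather than tuning the cohort to flatter the
models. CIFTI-2 container parsing is not implemented (no reader exists in
the supported dependency set); real-data workflows enter through plain-text
matrices, NIfTI volumes, or the package's portable store.
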