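---
title: "Metabolic covariance pattern analysis with ssmpca: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance pattern analysis with ssmpca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmpca)
```

# The problem

Regional glucose metabolism imaged with FDG-PET reorganizes in characteristic,
spatially distributed ways in neurodegenerative disease. The Scaled Subprofile
Model (SSM) treats each subject's image as a multiplicative global factor times
a shared regional profile modulated by subject-specific expression of one or
more covariance patterns. Applying PCA to suitably log-transformed and
double-centered data yields those patterns (Group Invariant Subprofiles, GIS)
together with per-subject expression scores, and a disease-related pattern such
as the Parkinson's Disease-Related Pattern (PDRP) can then be scored
prospectively in individual new subjects — for example to ask whether
schizophrenia patients developing drug-induced parkinsonism under antipsychotic
treatment express a parkinsonism-like metabolic signature.

`ssmpca` implements this pipeline end to end: volume I/O and smoothing, the
SSM-PCA derivation, component selection and cross-validation, logistic
combination into a composite pattern, prospective scoring with Z-normalization,
a statistical battery for group comparison, and a synthetic phantom generator
with known ground truth so that every stage is testable without patient data.

# The model

For subject $i$ with raw intensity $y_i(v)$ at voxel $v$, the SSM assumes

$$ y_i(v) = g_i \, \exp\{\mu(v) + \sum_k s_{ik} \, \mathrm{GIS}_k(v) + \varepsilon_i(v)\}, $$

with $g_i$ a per-subject global scaling factor, $\mu$ a shared log mean
profile, $s_{ik}$ the expression score of pattern $k$ in subject $i$, and
$\varepsilon$ noise. The derivation proceeds as:

1. **Masking.** A voxel enters the analysis iff, for *every* subject, its
   intensity is at least a fixed fraction (default 0.35) of that subject's
   mean intensity over its strictly positive voxels. The relative threshold
   removes low-activity tissue (white matter, CSF) and is invariant to each
   subject's global scale; intersecting per-subject masks guarantees a valid
   log transform for all subjects.
2. **Log transform.** Natural log of the masked intensities. The base is
   fixed: a different base only rescales everything by a constant that the
   final Z-transformation removes, but fixing it makes results bit-stable.
3. **Double centering.** Subject (row) means are removed first — this absorbs
   $\log g_i$ exactly — and the column mean of the row-centered matrix, the
   *group mean profile* (GMP), is removed second. The residuals are the
   subject residual profiles (SRP). The ordering matters only for the stored
   GMP, which prospective scoring must reuse; the residuals themselves are
   order-independent.
4. **PCA in subject space.** With $n$ subjects and $V \gg n$ voxels, the
   eigendecomposition of the $n \times n$ matrix $RR^\top$ is exact and cheap;
   the nonzero spectrum coincides with that of the voxel-space covariance
   $R^\top R$ (verified against a direct decomposition in the test suite).
   Each GIS is unit-norm, and scores are plain projections of residual rows
   onto it — no eigenvalue weighting, the simplest convention consistent with
   the prospective-scoring equivalence below. Components with eigenvalue below
   $10^{-12}$ of the largest are numerical zeros and dropped.
5. **Component selection.** The smallest leading prefix of components whose
   cumulative variance fraction reaches the cutoff (default 50%) is kept; a
   component that crosses the boundary is included, and an exact tie stops
   there. Each candidate is then sign-oriented so the disease group's mean
   score is at least the control group's (higher expression = disease-like)
   and tested with a pooled-variance two-tailed Student t-test at
   $\alpha = 0.05$; candidates for the t-test are exactly the
   variance-selected prefix.

## Prospective scoring (TPR)

A new subject is scored against a stored pattern by restricting to the stored
mask, taking logs, subtracting the subject's own mean over the mask and the
stored GMP, and projecting onto the voxel weights. For derivation subjects
this reproduces their PCA scores exactly (to numerical precision) — the
central correctness property of the scoring path, asserted at $10^{-8}$
relative tolerance in the tests. The procedure is invariant to global
rescaling of the subject's volume.

## Cross-validation and combination

Selected components are re-tested on held-out cohorts: every disease-vs-
control pairing of derivation and validation groups (four pairs with one
validation cohort per role) is tested with the pooled t-test on expression
scores, and a component survives only if $p < \alpha$ in *all* pairs. With no
validation cohorts the conjunction is empty and the selection passes through.

Surviving components are combined linearly with weights from a binary
logistic regression of group membership on the derivation subjects' scores
(validation subjects stay held out — the conservative reading where the
regression set is not otherwise determined). Scores enter unstandardized, so
the coefficients carry the score scale and the composite remains a pure
linear combination of GIS maps. The intercept is stored for provenance but
excluded from the voxel weights: it shifts all scores equally and is absorbed
by Z-normalization. If the two classes are linearly separable — quite possible
with derivation groups of ~19 subjects each — the unpenalized fit diverges;
the model is then refitted with a small fixed ridge penalty
($\lambda = 10^{-4}$ on the slopes only) and the result is flagged.

Composite raw scores are Z-transformed against the derivation control group
(sample standard deviation), so derivation controls have Z mean 0 and sd 1 by
construction. The voxel-weight map is additionally Z-transformed over the
mask for display; this is done on the *combined* map, one of the places where
the published convention is ambiguous (before vs after combination); for a
single surviving component the two coincide up to scale.

# Group statistics

`compare_groups()` mirrors the standard decision logic for expression-score
comparisons. Normality per group (Lilliefors) and variance homogeneity across
groups (Levene on absolute deviations from group means) are gate tests at the
fixed level $p > 0.05$; only if *all* groups pass normality *and* variances
are homogeneous is the parametric branch taken (one-way ANOVA with pairwise
pooled-t post-hocs), otherwise Kruskal–Wallis with pairwise Mann–Whitney
post-hocs — the conventional nonparametric analogs. Post-hoc p-values are
Holm-adjusted as one family (six pairs for four groups); the omnibus test is
not part of the family.

Numerical choices worth knowing:

* **Lilliefors p by Monte Carlo.** The null distribution of the sup-distance
  statistic (normal CDF with estimated parameters) is simulated with a seeded
  Monte-Carlo sample (default 10 000 replicates) instead of tabulated critical
  values, making p-values exactly reproducible for a given seed. The
  statistic itself matches the classical implementation to machine precision
  (cross-checked against `nortest::lillie.test` in the tests).
* **Mann–Whitney.** Exact two-sided p by enumeration when the combined sample
  size is at most 12 and there are no ties; otherwise the normal
  approximation with tie-corrected variance, without continuity correction,
  so the approximate branch matches the plain large-sample formula.
* **Spearman.** Pearson correlation of average ranks with the t
  approximation for p; groups with degenerate ranks are an error, not a
  silent NA.
* If a gate test cannot run at all (e.g. a group smaller than 4 for
  Lilliefors), the comparison conservatively takes the nonparametric branch.

A small utility converts antipsychotic dose records to chlorpromazine
equivalents as $\sum_d \text{dose}_d \times m_d$ against a user-supplied
ratio table (the minimum-effective-dose / consensus ratios themselves are not
shipped; the packaged CSV is an illustrative example only).

# The synthetic generator

`simulate_cohort()` draws cohorts from exactly the generative model SSM-PCA
assumes, so correctness tests are well-specified by construction:

$$ y_i(v) = g_i \, B(v) \, \exp\{a_i P(v) + \varepsilon_i(v)\} \quad
   \text{on the brain mask, } 0 \text{ outside}, $$

with $\log g_i \sim N(0, \sigma_g^2)$, loading
$a_i \sim N(\mu_{\text{group}}, \sigma_a^2)$, $P$ a smooth zero-mean
unit-norm random field, $B$ a smooth strictly positive base profile
(quadratic radial falloff, 100 at the center to 50 at the ellipsoid surface),
and $\varepsilon_i$ a smoothed Gaussian field rescaled to per-voxel sd
`noise_sd` (the rescaling factor is the root energy of the smoothing kernel's
impulse response, computed by smoothing a unit impulse, so the single
smoothing implementation in `gaussian_smooth()` serves the pipeline and the
generator alike).

Default conditions: a 24-voxel cubic grid at 2 mm voxels with ellipsoid
semi-axes (9, 11, 9); 19 controls (loading mean 0) and 19 disease subjects
(mean 2.5), loading sd 1; $\sigma_g = 0.2$; `noise_sd` 0.05. Validation and
scored groups used in the end-to-end checks follow the same study shape:
15 + 18 validation subjects, and two scored groups of 14 with intermediate
loading means 1 and 2 — a generative stand-in for groups that express the
pattern partially, producing the expected monotone uptrend
control < intermediate < intermediate < disease. Pattern and noise smoothness
default to 6 and 3 voxels FWHM: at 2 mm voxels this puts the pattern at the
~12 mm effective smoothness typical of normalized, smoothed PET, with noise
somewhat rougher than the anatomical-scale signal. These values were fixed
once as realistic field choices and are freely configurable.

Because the generator emulates images *after* spatial normalization and
smoothing, the pipeline's own 12 mm smoothing step (the default for real
data) is disabled (`smooth_fwhm_mm: 0`) when analyzing synthetic cohorts in
the tests and the acceptance script; applying it is harmless but blurs the
embedded pattern relative to its recorded ground truth.

Noise is added in the log domain by default, making the SSM exactly
well-specified; `noise_domain = "raw"` switches to additive raw-domain noise
(clipped to keep intensities positive) to probe robustness under deliberate
misspecification. What the phantom does *not* emulate: anatomy (no tissue
classes, no ventricles), scanner physics (attenuation, reconstruction,
resolution nonuniformity), registration error, or inter-site effects. Passing
recovery tests therefore demonstrates correctness of the computation under
the model's own assumptions, not clinical performance on real scans.

# Numerical and design choices

* **Smoothing** is a separable discrete Gaussian, per-axis
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \text{voxel size}$, kernel
  truncated at $4\sigma$ and renormalized, zero padding at the boundary
  (outside-brain treated as zero signal). `fwhm = 0` is the exact identity.
  Smoothing is applied at load time, immediately after reading.
* **Masking** thresholds against each subject's *mean* positive-voxel
  activity (the wording followed here), not the maximum.
* **Analyze 7.5** files are read (for interoperability with toolboxes that
  exchange that dialect); all outputs the package writes are NIfTI-1.
  Orientation metadata is carried opaquely and never resampled — volumes must
  arrive on one grid.
* **Variance-cutoff tie:** a cumulative fraction exactly equal to the cutoff
  stops there (the boundary component is included).
* **Eigen-sign convention:** disease-minus-control mean score $\ge 0$ for
  every tested component, fixed before the t-test.
* **Degenerate inputs** error loudly and early: empty masks, nonpositive
  masked intensities (named subject and voxel), all-zero residual matrices,
  zero-variance samples, zero coefficient vectors.
* **Model and pattern persistence** uses double-precision NIfTI maps plus a
  JSON sidecar, so a save/load round trip preserves scoring to full
  precision and reruns are byte-identical.

# Problem sizes used in the packaged checks

The test suite derives from study-sized synthetic cohorts (24³ grid,
19 + 19 derivation, 15 + 18 validation) for the end-to-end properties —
pattern recovery $|r| \ge 0.9$ and loading–Z-score correlation $\ge 0.9$ in
at least 9 of 10 seeds — and from reduced cohorts (12–14-voxel grids, 8–10
subjects per group) for per-module checks and the null-calibration studies
(200 derivations for the component-selection rate, 500 replicates for the
omnibus type-I error, 1000 replicates for the univariate test calibrations),
sizes chosen so the whole suite runs in well under a minute while keeping
Monte-Carlo error comfortably inside the asserted bands.

# Known limitations

* Spatial normalization is out of scope; inputs must share one grid, and no
  resampling is attempted.
* No voxel-wise inference on pattern maps (no permutation or bootstrap
  thresholds); the voxel Z map is descriptive.
* The logistic combination assumes the surviving components jointly carry
  the group contrast; with many surviving components and small derivation
  groups the ridge-flagged separable case becomes common and coefficients
  should be interpreted with care.
* The phantom's simplicity means negative results on real data say nothing
  about the implementation, and vice versa.
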