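---
title: "Methods: quantifying and modelling social voice modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modelling social voice modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicemod)
```

## The measurement problem

Speakers differ in how well they can deliberately make their voice convey
a social trait. The design this package analyses operationalizes that
ability through naive listeners: each speaker records a neutral voice and
modulations intended to sound likeable, hostile, intelligent (and, as a
control, large-bodied); listeners rate every recording on each social
trait scale from 1 (*not at all*) to 7 (*very*). Two kinds of per-speaker
summaries follow.

**Δ-trait** is the mean, over listeners, of the rating of the
trait-modulated recording minus the rating of the neutral recording on
that trait's own scale. It measures how far the modulation moved listener
percepts, in Likert points. Listeners lacking either member of the pair
are dropped listwise (with a logged count); an error is raised only when
no complete pair remains, because imputing ratings would fabricate data.

**The social voice modulation index (ED)** measures *specificity* rather
than magnitude. For each speaker we form a 3×3 representational
similarity matrix (RSM) whose cell (i, j) is the Pearson correlation
between the scale-i and scale-j rating vectors, each vector stacking the
ratings over listeners × the three social recordings (length 3L for L
complete listeners). A perfectly specific speaker drives likeable and
hostile percepts in opposite directions (r = −1) and leaves intelligence
judgments uncorrelated with both (r = 0); that fixed matrix is the
theoretical maximal-discrimination RSM. The index is the Euclidean
distance over the three unique off-diagonal cells,
`ED = sqrt((r_LH + 1)^2 + r_LI^2 + r_HI^2)`, ranging from 0 (perfect
specificity) to √6 ≈ 2.45 (all three correlations at +1). Using the three
unique cells — not six or nine — is the only convention under which 2.45
is the attainable maximum, which is why the package fixes it.

The published description of the RSM cell admits a second reading
(correlating per-recording mean profiles instead of stacked scale
vectors). The stacked `"scalewise"` construction is the default because
it matches the stated vector composition ("ten ratings … for each of the
three trait recordings"); the `"profile"` alternative is available as
`build_rsm(..., mode = "profile")` so the choice is one flag, not a fork.
Likewise all listeners who completely rated a speaker are used, not
exactly ten: the design guarantees *at least* ten, and discarding raters
would waste information. Likert values enter Pearson correlations as
continuous numbers (no polychoric correction), matching standard practice
for 7-point scales.

## Association analyses

The primary model regresses ED on the four social-reactivity indices —
QCAE cognitive and affective empathy, SD3 Machiavellianism and
psychopathy — z-scored on the analysis sample, with raw age and
dummy-coded sex (female = 0, male = 1) as covariates of no interest.
With n speakers and 6 slope terms the overall F has (6, n − 7) degrees of
freedom: (6, 15) after excluding two of 24 speakers, (6, 17) on the full
sample.

The influence workflow mirrors the analysis narrative this package
implements: externally studentized residuals are tested two-sided against
t(n − k − 2), flagged at uncorrected p < .05, Bonferroni-corrected over
the n observations, and the flagged points are excluded — and the OLS
refit with predictors re-z-scored on the reduced sample — *only* when a
screen of the residual error distribution rejects at p < .001. The
original analysis does not name that screen; Shapiro–Wilk is used here as
the most common residual-normality test in this workflow, and the test is
pluggable (`resid_test = "none"` disables the rule) precisely to confine
that guess. The number of exclusions is data-driven, not hard-coded to
the two points reported for the original sample. For completeness a Huber
M-estimator regression always runs on the full sample: iteratively
reweighted least squares with tuning constant c = 1.345 (95% Gaussian
efficiency — the standard default where the source names only "an
M-estimator"), scale re-estimated each iteration by the
normal-consistent MAD about zero, convergence when the largest
coefficient change drops below 1e−8 (at most 200 iterations;
non-convergence is flagged with the change trace, not fatal). The
original analysis used the CRAN *robust* package; this implementation is
self-contained and is validated against `MASS::rlm` as an independent
oracle. Robust standard errors use the Huber asymptotic covariance with
the usual small-sample correction; the reported robust R² analogue is the
squared correlation between fitted and observed values and the residual
scale (RSE) is the final MAD.

Trait-level effects use partial Pearson correlations (residual-of-
residuals after OLS on age, sex and an intercept), with p from
t = r√((n − 2 − g)/(1 − r²)), g = 2 covariates. The FDR family is the 12
Δ-trait × index cells, adjusted by Benjamini–Hochberg step-up; the family
is configurable. Two-sided p-values are used throughout this module. One
caveat surfaced by the property suite: BH adjustment re-applied to its own
output is *not* the identity in general, so no idempotence is claimed or
tested. A degenerate partial correlation (a residual vector that is
numerically zero, e.g. an outcome that is an exact linear function of the
covariates) is reported as r = 0 with a warning and a `degenerate` flag
rather than NaN.

The one-sample Δ t-tests default to two-sided, with `tail = "greater"`
available; the pipeline prints both, because a reported ∆-Intelligence
of t(23) = 1.87 with p < .05 is consistent only with the one-sided
reading, and silently choosing the laxer test would hide that.

## Voxelwise covariate GLM and cluster inference

Per-speaker 3D contrast volumes are regressed voxelwise on an intercept,
the covariate of interest (ED or a reactivity index) and age/sex; the
covariate t-map (df = n − 4) is converted to z by the sign-retaining
p-preserving transform. Voxels constant across speakers (zero
between-speaker variance up to floating-point noise) carry no information
and are excluded with a logged count.

Cluster-extent correction follows the Monte-Carlo recipe: simulate
standard-normal white noise on the analysis grid, smooth to the nominal
FWHM (σ = FWHM/(2√(2 ln 2)) voxels per axis, separable kernel truncated
at 4σ), re-standardize to unit variance inside the mask so the
cluster-forming quantile stays calibrated after smoothing, threshold at
the one-tailed voxel-p normal quantile, and record the largest connected
component per iteration. `k_min` is the smallest k whose exceedance
probability among the simulated maxima is ≤ α. The simulation uses the
nominal smoothing kernel, not residual-estimated smoothness — the exact
variant behind the published thresholds is cited but not specified, so
the nominal-FWHM version is implemented and labelled as such. Thresholds
are derived and applied per direction (the one-tailed convention that
matches signed cluster tables); the false-positive calibration test
therefore checks the per-direction cluster-level error rate.

Clusters are labelled under 18-connectivity (faces + edges) by default —
the convention of the SPM software family — with 6 and 26 selectable, and
labelling is verified against an independent flood-fill oracle. Each
surviving cluster reports up to 3 local maxima separated by ≥ 8 mm
(greedy selection in descending t), with mm coordinates
`origin + index · voxel_size`; voxel indices are never exposed. The
default test grid is 32³ at 2 mm (desk scale); full MNI-sized grids work
but are not exercised by the suite. NIfTI-1 I/O (little-endian float32,
diagonal sform) is implemented directly because no NIfTI package is
available in the target environment; it round-trips byte-exactly and was
checked against nibabel during development.

## What the synthetic generator states, and what it does not

The generator's defaults *are* the study conditions: 24 speakers (age
≈ N(21.04, 3.26²) truncated at 18, 3/24 male), 24 listeners each hearing
10 speakers with every speaker covered by at least 10 listeners, five
recording conditions rated on the three social scales, 8 mm-FWHM volumes
on a 2 mm grid. Listener assignment is a balanced cyclic block design
(listener ℓ takes the block starting at ⌊ℓ·S/L⌋, with seed-driven
relabelling of listeners and speakers): the coverage guarantee holds by
construction and is re-tallied at run time, rather than hoped for by
rejection sampling. The published text does not state the original
assignment algorithm; this is a stand-in with the same margins.

Ratings arise from a latent linear model: neutral mean 4 (mid-scale),
plus `effect_gain · s` in the direction of a target pattern — matched
scale up, likeable and hostile mutually opposed, intelligence orthogonal
— plus Gaussian noise (SD 1 Likert point by default), rounded and clipped
to 1–7. `effect_gain = 3` makes a perfectly skilled speaker (s = 1) span
the scale exactly (7/1/4) in the noiseless limit, which realizes the
theoretical RSM; with unit noise the achievable r(L,H) attenuates to
about −0.9, so structural tests check bands, not the exact limit. Latent
skill s is uniform on [0, 1]: the generator must produce the full range
of specificity, and the published ED range (0.25–1.64) is comfortably
covered. Expected ED decreases monotonically in s — the property the
acceptance suite verifies by Spearman correlation.

Questionnaires come from a latent multivariate normal over the four
indices with the stated intercorrelation structure (Machiavellianism ×
psychopathy = 0.60 by default) and user-set loadings on standardized s
(default: cognitive empathy 0.45, so higher skill — hence lower ED — goes
with higher cognitive empathy, the direction of the headline effect).
Item responses are the index latent scaled by a per-subscale item
loading, plus item noise, thresholded into equal-width bins over ±2 SD;
sums then respect the instrument ranges by construction. The item
loadings (0.60/0.51/0.49/0.40 for cognitive/affective/Mach/psychopathy)
were chosen once so the implied Cronbach αs land near the reported
instrument αs (0.91/0.81/0.74/0.61) and are not revisited. The shipped
keymap is straight-keyed (no reverse items): the original item keying is
not reprinted in the source material, and the printed range endpoints are
reproduced by all-min/all-max responses only under straight keying;
reverse keying is supported through a user keymap.

Because ED computed from ratings is a nonlinear functional of s, no exact
regression coefficient can be planted through the ratings route. The
generator therefore also plants the questionnaire→ED model *directly*:
`plant_ed()` draws ED = 0.74 + Σβ_j z_j + N(0, 0.47²) on the z-scored
indices (intercept at the reported ED mean, residual SD at the reported
robust RSE, default β = −0.45 on cognitive empathy — the headline
coefficient). That surrogate is the recovery target for the association
suite; it may leave [0, √6] and never feeds the RSM stage. The ratings
route carries the monotonicity and structural criteria instead.

Volumes are `beta_map · centered(ED)` plus smoothed, re-standardized unit
noise; the planted β-map is a centered cube spanning the middle third of
the grid at height `beta_map_gain` (−1 by default, matching the reported
negative direction: more activation with lower ED). With
`beta_map_gain = 0` the generator is the planted null used for
false-positive calibration.

What a green test does **not** establish: the generator has no rater
response styles (halo, acquiescence), no acoustic content, no
speaker-by-listener interaction, no BOLD physiology, and Gaussian noise
everywhere — so passing calibration here says the *machinery* is correct
under its stated assumptions, not that the published coefficients are
reproduced. The published headline values (β = −.45, r_p = .66, the
cluster tables) depend on undeposited raw data and are deliberately not
acceptance targets beyond the analytic constants (ED bounds, df
structure, instrument ranges).

## Numerical choices and degenerate inputs

* Seeds: one integer seed drives every stage through
  `derive_seed(seed, stream)` (a fixed affine hash into [0, 2³¹));
  generators save and restore the caller's RNG state.
* RSM validation: symmetry tolerance 1e−9, |r| ≤ 1, unit diagonal; a
  zero-variance scale vector is an error naming the scale — never a
  silent substitution.
* Likert discretization rounds then clips, so clipping never moves a
  value by more than the pre-clip overshoot and mid-scale planted means
  are preserved.
* OLS is solved by Cholesky on the normal equations (designs here are
  tiny and well-conditioned); rank deficiency is an error naming the
  collinear term. Studentization uses the standard leave-one-out
  variance identity.
* Ties in peak selection resolve by descending t then first-found;
  cluster labels are renumbered by decreasing size (stable for ties).
* The Monte-Carlo threshold returns the per-iteration maxima as an
  attribute so the exceedance curve can be inspected.

## Known limitations

* The residual-distribution screen and the outlier-test identity are
  documented guesses (pluggable), as the source names neither.
* Robust-regression inference (SEs, p) uses an asymptotic approximation;
  at n = 24 treat those p-values as descriptive.
* The MC cluster simulation assumes stationary nominal smoothness and a
  rectangular mask unless a mask is supplied; anatomical masks and
  residual-based smoothness estimation are out of scope.
* Cluster tables leave region/hemisphere labels blank: no atlas is
  bundled, and anatomical labelling is out of scope.
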