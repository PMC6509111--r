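---
title: "Measuring the distinctiveness of mental-state representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the distinctiveness of mental-state representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindrsa)
```

## The model and its assumptions

The package quantifies how differentiated a person's mental-state
representations are, for targets at increasing social distance (the
self, a close other, a distant other). The measurement model has three
layers.

**Pattern estimation.** Each (target, state) condition is summarized by
a voxelwise GLM beta map: boxcar regressors at the event onsets,
convolved with a canonical double-gamma hemodynamic response (peak 6 s,
undershoot 16 s, unit dispersions, peak:undershoot ratio 6, 32 s
support — the de-facto standard parameterization), alongside per-run
intercepts, centered linear trends, and optional motion covariates.
Ordinary least squares is appropriate here because the synthetic noise
is white; real scanner data would need prewhitening, which is outside
this package's scope. Condition regressors are never orthogonalized, so
blocked designs leave a fingerprint in the estimator covariance — that
is deliberate, see "block-structure correction" below.

**Distinctiveness.** Within a voxel set (a searchlight sphere or an
ROI), the representational dissimilarity matrix (RDM) holds the Pearson
correlation distance `1 - r` between every pair of condition patterns.
The distinctiveness of target *t* is the mean of the within-target
lower-triangle entries — the average dissimilarity among that target's
states. Averaging is done on the raw distances (equivalently raw
correlations), not Fisher-z transformed values, matching how the
statistic is conventionally reported; a Fisher-z option exists
(`average_target_dissimilarity(..., fisher_z = TRUE)`) but is off by
default. Because Pearson correlation is invariant to affine rescaling,
so is the statistic — gain and offset differences between subjects or
sessions cannot masquerade as distinctiveness differences.

**Group inference.** Per-subject, per-target distinctiveness maps are
smoothed and compared with a paired t-test (two targets) or a one-way
repeated-measures ANOVA (three). Voxelwise multiplicity is handled by
threshold-free cluster enhancement combined with maximal-statistic
permutation: the observed enhanced map is referred to the permutation
distribution of the image-wide maximum, which controls the family-wise
error rate without choosing a cluster-forming threshold.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| searchlight radius | 4 voxels (~9 mm at 2 mm voxels) | sphere of 257 lattice voxels; radius is specified in voxel units |
| minimum searchlight size | 30 in-mask voxels | below this, correlations are too unstable; such centers yield NA and are excluded from group maps |
| constant-pattern rule | drop condition; skip center if >10% dropped | a zero-variance pattern has no defined correlation; dropping only the offending condition wastes the least data |
| smoothing FWHM | 6 mm | σ = FWHM / (2√(2 ln 2)) per axis, in voxel units; mirror-reflection boundaries conserve total mass; NA voxels are handled by normalized convolution |
| TFCE | E = 0.5, H = 2, dh = max/100, 26-connectivity | the field-standard enhancement parameters |
| permutations | 5000 default (500 in the bundled simulations); exhaustive when 2^n ≤ n_perms, with a warning | the identity permutation is always included, so the smallest attainable p is 1/n_perms |
| two-sided maps | enhance +t and −t separately, Bonferroni-combine tails | keeps each tail's maximal statistic exact |
| Bonferroni over target pairs | m = number of pairs | three pairwise tests in the three-target design |

Smoothing is applied to the per-subject distinctiveness maps *before*
the group test, and sign-flip permutations operate on the smoothed
difference maps, so observed and null statistics traverse the identical
pipeline.

## The synthetic-data generator

The generator is the package's ground truth, not a fixture. Each subject
draws a mean pattern per target and one latent direction per state
*shared across targets*; the state direction is scaled by the target's
dispersion inside a designated effect region and by a common baseline
outside, then white noise is added:

```
beta(target, state) = mean[target] + scale(target, voxel) * dir[state] + noise
```

Sharing state directions across targets makes "the same state for
different targets" meaningful, which the MDS visualization relies on.
Within-target pattern variance at an effect voxel equals dispersion², so
distinctiveness increases monotonically with planted dispersion — the
recovery tests check sign and ordering, not a closed-form value, because
the mapping from dispersion to mean correlation distance also depends on
the mean-pattern and noise variances.

Default study conditions: 20 subjects, 12×12×12 grid of 2 mm voxels, targets self/close/far with
dispersions 1.0 / 0.6 / 0.2, baseline 0.2, noise SD 0.5 ("moderate":
half the largest planted dispersion), effect region a central sphere of
radius 3 voxels (123 voxels, comfortably larger than one searchlight).
Null simulations use two targets with equal dispersion 0.6. Every
generator is a pure function of (config, seed); per-subject streams are
derived deterministically from the master seed, so datasets are
bit-reproducible and individual subjects can be regenerated in
isolation.

The rating generator mirrors the mixed model exactly: grand mean 3.5 on
the 1–6 scale, a fixed target-code effect, random intercepts and random
target slopes for participants and state pairs, Gaussian residuals.
Variance components are not published quantities; they were fixed once
(participant/pair intercept SDs 0.55, participant slope SD 0.3, pair
slope SD 0.15, residual SD 1) so that the implied conditional R² is near
0.4 and the marginal R² is small — the regime the behavioral analyses
report. Ratings are continuous by default: Likert data cannot be both
Gaussian and integer, and rounding to the 6-point scale attenuates the
fixed effect, so recovery tests use the continuous output and
`discretize = TRUE` exists for realism-oriented simulations.

**What the generator does not emulate:** BOLD autocorrelation,
physiological noise, scanner drift beyond linear trends, spatial
correlation of noise, inter-subject anatomical variability, or ordinal
response styles. Passing recovery tests therefore demonstrates that the
estimators are correct under the stated model, not that real data meet
that model.

## Block-structure correction

Blocked trial designs (all of one target's trials contiguous within a
run) induce correlations among condition-beta estimators through
`(X'X)^-1`. `design_induced_similarity()` returns that estimator
correlation matrix, and `correct_block_structure()` residualizes the
observed condition-similarity matrix on it by least squares across
condition pairs, before the per-target averaging. The exact published
form of this correction is not specified in detail anywhere we could
consult, so the residualization here is one defensible reading, isolated
behind a single function so it can be swapped without touching the rest
of the pipeline. With an orthogonal design it reduces to centering the
similarities, which leaves all target contrasts untouched.

## Mixed-model details

The maximal model is `rating ~ code + (1 + code | participant) +
(1 + code | pair)`, REML, with the target contrast coded 0/1 (reference:
the socially closest target). On a singular fit the random structure is
relaxed along a fixed ladder — drop slope–intercept correlations, drop
pair slopes, drop participant slopes — and the structure actually used
is recorded in the result. Satterthwaite degrees of freedom are the
reference behavior (they are fractional, as mixed-model t statistics
should be); `df_method = "residual"` is provided for large simulation
loops, where hundreds of grouping levels make the two indistinguishable,
and the flag is stored in the output. Standardized β is b rescaled by
sd(code)/sd(rating); it is invariant to affine rescaling of the rating
scale. Marginal and conditional R² follow the variance-partition
formulation, with the random-effect variance of each grouping term
computed as the mean over observations of x'Σx (the extension that
handles random slopes). The continuous social-distance model z-scores
the composite predictor across participant × target cells, so its b is
per standard deviation of social distance. The composite itself is the
raw arithmetic mean of similarity, familiarity, and closeness ratings
(larger = closer), with the mean pairwise correlation among the three
components reported alongside; a z-scored-entry variant was considered
and rejected as the default because the component scores share one
response scale.

## Geometry (MDS figure)

Per-target state geometries use classical (Torgerson) scaling of the
squared-distance matrix — deterministic and seed-free, unlike
stress-optimized MDS, which matters for reproducible figures. Each
non-reference target is aligned to the socially closest target's
configuration by orthogonal Procrustes rotation (reflection allowed, no
isotropic scaling, so the dotted circle radii — the mean within-target
dissimilarity — remain comparable across targets). Alignment never
changes within-target distances; that invariant is tested to 1e-10.

## Numerical choices and degenerate inputs

* TFCE integrates at threshold midpoints `(k − 0.5) dh`, which converges
  to the analytic integral as dh → 0; the implementation is checked
  against per-threshold connected-component enumeration on random maps.
* Sign-flip t statistics reuse the sign-flip-invariant Σd² per voxel, so
  the permutation loop costs one matrix product plus TFCE per flip.
* Voxels with zero-variance paired differences have no defined t; they
  are returned NA, counted, and excluded from inference (`keep` mask).
* Rank-deficient GLM designs raise an error naming the aliased columns
  rather than silently pivoting.
* Distances for searchlight membership are computed on the integer voxel
  lattice; world coordinates enter only through the NIfTI affine at IO
  time.

## Validation suite and problem sizes

The test suite validates each stage against independent oracles (hand
arithmetic, `aov`, `vegan::procrustes`, brute-force enumeration) and the
pipeline end to end: trial-design combinatorics (315- and 90-trial
designs; 60×60 and 75×75 RDMs), exact GLM recovery at zero noise,
searchlight sphere counts by lattice enumeration, TFCE against
brute-force labeling on fifty random 8×8×8 maps, planted dispersion
ordering recovered by ROI tests across twenty 20-subject datasets with
searchlight localization of the effect, fixed-effect coverage and
type-I error of the mixed model at 100 replicates of the 346-participant
two-target design, and the family-wise error rate of the full
permutation pipeline on 200 null datasets (12 subjects, 12×12×12, 500
permutations each). These sizes were chosen as the smallest at which
each property is sharply testable; `scripts/acceptance.R` re-runs the
FWER simulation from scratch.

## Known limitations

* No crossvalidated distance estimators (crossnobis / Mahalanobis); the
  pipeline deliberately uses the plain Pearson distance it is built to
  study.
* No ordinal model for Likert ratings; ratings are treated as
  continuous, consistent with the mixed-effects analysis it implements.
* Real-data preprocessing (motion correction, normalization, slice
  timing) is out of scope; inputs are assumed to be registered beta maps
  or clean BOLD-like series.
* The ANOVA permutation scheme assumes target exchangeability within
  subject under the null, which holds for the planted generative model
  but is an assumption for real data.
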