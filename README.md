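# mindrsa

Measure how distinctly mental states are represented — for oneself versus
for other people — in multivoxel fMRI activity patterns and in explicit
similarity judgments.

The scientific question: when a person thinks about their own mental
states (awe, sleepiness, embarrassment, ...) versus the states of a close
friend or a socially distant stranger, are the neural and judged
representations of those states more differentiated for the self? The
package provides the full analysis stack for that question, plus a
synthetic-data module with known ground truth so every stage can be
validated by parameter recovery and error-rate simulation.

## The core statistic

For each subject and target person *t*, let *b*(t, s) be the voxel
pattern evoked by mental state *s* (a first-level GLM beta map). Within a
searchlight sphere or region of interest, the pairwise pattern
dissimilarity is the Pearson correlation distance

    d(s_i, s_j) = 1 − r( b(t, s_i), b(t, s_j) )

and the **distinctiveness** of target *t* is the mean of d over the
C(n_states, 2) within-target pairs (the lower triangle of the
representational dissimilarity matrix; cross-target entries never
contribute). Its companion form is the mean pattern correlation
r̄ = 1 − distinctiveness, and Δr denotes the difference in r̄ between two
targets. Group inference on distinctiveness maps uses paired t-tests /
one-way repeated-measures ANOVA, threshold-free cluster enhancement
(TFCE, E = 0.5, H = 2), and maximal-statistic permutation control of the
family-wise error rate (sign flips for paired contrasts, within-subject
target relabeling for the ANOVA). Behavioral similarity ratings are
analyzed with linear mixed-effects models — `rating ~ target code +
(code | participant) + (code | state pair)` — with Satterthwaite degrees
of freedom, least-squares-means post-hocs, and Nakagawa marginal /
conditional R².

## Worked example

Simulate 12 subjects with planted dispersions (self 1.0, close 0.6,
far 0.2) inside a central effect region, then test the target ordering in
the region of interest:

```r
library(mindrsa)

cfg <- sim_config(n_subjects = 12, seed = 7)   # self/close/far, 12x12x12
subjects <- simulate_dataset(cfg)

roi <- t(vapply(subjects, function(ps)
  setNames(roi_distinctiveness(ps, cfg$effect_region)$mean_dissimilarity,
           cfg$targets), numeric(3)))
round(colMeans(roi), 3)
#>  self close   far
#> 0.553 0.389 0.218
pairwise_target_tests(roi)
#>   target_a target_b delta_r cohen_d        p p_bonferroni
#> 1     self    close  -0.164    2.91 6.94e-07     2.08e-06
#> 2     self      far  -0.335    8.22 1.18e-11     3.54e-11
#> 3    close      far  -0.171    3.89 3.50e-08     1.05e-07
```

Mean within-target dissimilarity falls with social distance exactly as
planted (self > close > far), every pairwise difference is significant
after Bonferroni correction over the three target pairs, and `delta_r`
reports the equivalent difference in mean pattern correlation (negative:
the first target's patterns are less inter-correlated, i.e. more
distinct). The behavioral arm mirrors this:

```r
rcfg <- rating_sim_config(n_participants = 46, n_states = 15, seed = 7)
fit_state_similarity_lmm(simulate_ratings(rcfg), fixed = "self_other")
#> <lmm_result> contrast 'self_other' (reference: self)
#>   term     b   beta     se    t df       p
#> 1 code 0.164 0.0589 0.0473 3.46 54 0.00105
#> marginal R2 = 0.0034, conditional R2 = 0.415; random structure:
#>   rating ~ code + (1 + code | participant) + (1 + code | pair)
```

The planted fixed effect (others' states rated 0.15 points more similar
than one's own, on the 6-point scale) is recovered as b = 0.164 with a
small marginal but large conditional R² — most rating variance sits in
participant and state-pair random effects, as expected for Likert data.

Whole-brain maps come from `searchlight_distinctiveness()` +
`smooth_map()` + `permutation_fwe()`; `run_pipeline()` chains every stage
(simulate → GLM → RSA → inference → behavior → MDS figure coordinates)
and writes NIfTI/CSV/JSON outputs with a seed-stamped manifest.

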