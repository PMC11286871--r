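---
title: "Methods: resilient psychosocial functioning and cortical myelin maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resilient psychosocial functioning and cortical myelin maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adolmat` implements a longitudinal analysis chain linking intra-individual
change in *resilient psychosocial functioning* — the residual of observed
psychosocial distress after removing the normative response to adversity
exposure — to the maturation of a cortical myelin proxy (magnetization
transfer saturation, MT) and of functional connectivity in adolescence
(ages 14–26, accelerated longitudinal design, two sessions per subject
roughly 1.26 ± 0.33 years apart, three acquisition sites).

This vignette documents the model at each stage, the tunable parameters and
their defaults, the synthetic-cohort generator used for validation, and the
numerical choices and limitations a user should know about.

## 1. Resilience scoring

**Latent distress.** A single-factor maximum-likelihood factor analysis
(`fit_distress_factor()`, via `stats::factanal`, no rotation — rotation is
undefined for one factor) summarizes questionnaire items spanning
depression, anxiety, antisocial behavior, obsessive–compulsive symptoms,
self-esteem, psychotic-like experiences and well-being. Loadings are
oriented so symptom items load positively; reverse-keyed well-being items
are expected to load negatively. The distress score is the loading-weighted
item sum (`score_distress()`), computed on the standardized item scale the
loadings were estimated on. Sessions missing more than 20% of items are
dropped (configurable); remaining gaps are mean-imputed.

**Normative prediction.** `predict_distress_nested_cv()` predicts distress
from adversity features (family environment, life events, socioeconomic
status) with a random-forest regressor under nested cross-validation:

* outer loop: leave-one-subject-out — all sessions of a subject are held
  out together;
* inner loop: 5-fold, grouped by subject, selecting the tree count
  (50–300) and depth (5–15) by minimal mean absolute error;
* features standardized inside each training fold only (leakage-safe; the
  alternative of global standardization is never used).

`mtry` is set to all features, matching the scikit-learn regression-forest
convention; with the feature-subsampling default the forest visibly
under-fits additive adversity signals and the residual scores retain
adversity variance, defeating the purpose of the correction.

**Residual extraction.** `compute_res_psf()` defines
`res_psf = predicted − observed`, so *positive = lower-than-expected
distress = resilient adaptation*. Per subject, `delta_res` is last minus
first session and `mean_res` the average of the two; both are `NA` (not an
error) for single-session subjects. Factor fitting and prediction should
be run on disjoint subsamples when both are estimated from the same pool;
the synthetic pipeline runs them on one sample and says so in its log.

## 2. Depth-resolved microstructure

**Equivolumetric sampling.** Intracortical surfaces are placed so that a
fixed *volume* fraction, not a fixed distance, lies between them and the
boundaries, compensating for cortical folding. With linear area
interpolation between the inner area $A_{in}$ and outer area $A_{out}$,
the surface enclosing volume fraction $\alpha$ from the white boundary
sits at

$$\rho(\alpha) = \frac{-A_{in} + \sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}}{A_{out}-A_{in}},$$

with $\rho = \alpha$ when the areas are equal. The implementation is
validated against direct numerical integration of the interpolated area
to 1e-6 over a grid of area ratios. Twelve surfaces are constructed at
interior fractions $i/13$ and the two pial-most are discarded against
partial-volume contamination, leaving the 10 analysis depths. Depth
arrays are stored **pial → white**, with the fraction grid recorded in the
bundle manifest, so orientation can never silently flip.

**CSF correction.** Per parcel, `csf_correct()` fits
`MT ~ b0 + b1 · CSF` and replaces the values by the residuals plus the
group-average (across sessions) profile at that parcel. The default fits
one model per parcel *pooled over all sessions' depth points*: the shared
intercept and CSF slope remove the depth-wise contamination while
session-level mean differences — the longitudinal signal — survive in
the residuals. A `method = "per_session"` variant refits within each
(session, parcel) profile; it is deliberately not the default because an
intercept fitted per profile forces every corrected profile's depth mean
to the group profile's mean (per-profile residuals sum to zero exactly),
which annihilates all intra-individual change in depth-averaged MT — a
degeneracy that would silently empty the downstream change GLM. Per-
session fitting remains appropriate for strictly cross-sectional profile
analyses. In both modes, parcels with (near) zero CSF variance are
passed through (nothing to correct; the slope would be undefined), exact
mean restoration across sessions should not be assumed, and
re-correction is a no-op exactly when the restored group profile carries
no CSF-correlated component.

## 3. Microstructural profile covariance (MPC)

Edge $(i,j)$ of a session's MPC matrix is the partial Pearson correlation
between the depth profiles of parcels $i$ and $j$, controlling for the
cortex-average *profile* (depth-wise mean over parcels). We interpret the
controller as a profile rather than a scalar because depth-resolved mean
intensity is what drives shared laminar structure; a scalar-mean variant
would change edge values but cannot change the rank-based maturational
index downstream. Partial correlations are clipped at $1 - 10^{-7}$ and
Fisher-transformed by default (`transform = "raw_r"` available): the
variance-stabilized scale is what the edge-wise mixed models assume, and
it matches the treatment of functional connectivity. Negative edges are
retained; no thresholding is applied at construction. Constant profiles
and profiles collinear with the controller are excluded (rows/columns set
to missing) rather than producing undefined correlations.

## 4. Functional connectivity operations

FC matrices enter as parcel × parcel correlation (or Fisher-z) matrices.
The package provides: `fisher_z()` (with clipping); `regress_fd()` —
per-edge simple regression on the session's mean framewise displacement,
removing residual motion effects (residuals are exactly orthogonal to
motion; re-application is a no-op); `exclude_low_snr()` — a region is
dropped when its standardized signal summary falls below 1.96 for *at
least one* participant, and the mask is applied to every session;
`seed_fc()` and `degree_centrality()` — the mean over seed parcels of
edges to each target, and its sum over targets (the definitional identity
`degree = sum(seed map)` is asserted in tests). The per-region signal
summary is consumed as an input column; computing it from time series
(band-pass 0.025–0.111 Hz, parcel-mean time courses) is outside the
matrix-mode scope of this package.

## 5. Longitudinal change GLM

Change is always **last minus first** session (`compute_delta()`), per
subject and parcel. Changes are winsorized at ±3 SD per parcel (moments
computed before clipping; note that re-winsorizing can clip further when
a gross outlier inflated the original SD — winsorization is not a
projection) and adjusted for the inter-session interval by regression on
Δage (`adjust_interval()`), done separately for imaging and behavioral
intervals because visits happen on different days. The order
winsorize-then-adjust is a package choice (the reverse is available by
calling the functions in the other order).

Each parcel is then fit by OLS:

$$\Delta MT \sim 1 + \beta_{\Delta Res}\,\Delta Res + \beta_{meanRes}\,meanRes
  + \beta_{age}\,\overline{age} + \beta_{sex}\,sex + \beta_{site}\,site + \varepsilon,$$

with mean age across the two sessions, sex as a 0/1 indicator and site as
two dummy columns — seven design columns, so 141 subjects give t
statistics on 134 degrees of freedom. `mean_res` is not interval-adjusted
(only the change scores are; the mean is not an interval-scaled
quantity). Standardized coefficients come from refitting with z-scored
response and predictor.

**Inference.** `permute_glm()` permutes the (ΔRes, meanRes) *pair* jointly
across subjects (10,000 permutations in the headline setting; tests use
199–1000), holding the other covariates fixed, and computes two-sided
p-values as `(1 + #{|t*| ≥ |t|}) / (B + 1)`. Internally the fixed
covariates are projected out once (Frisch–Waugh), so each permutation
costs two small regressions while producing exactly the full-model t —
this is verified against a brute-force `lm()` refit loop in the tests.
FDR control is Benjamini–Hochberg at α = 0.05 (`bh_fdr()`). Post-hoc
tools: `depthwise_glm()` refits the model at each of the 10 depths within
an ROI, and `stratify_map()` summarizes unthresholded t maps over atlas
labels (cortical types, functional networks).

## 6. Edge-wise mixed models and the maturational index

Every included edge of the session-wise MPC (or FC) stack is fit with a
subject random-intercept model

$$edge \sim 1 + \beta_{age}\,age + \beta_{sex}\,sex + \beta_{site}\,site + (1\,|\,subject) + \varepsilon.$$

Because thousands of edges share one design, `fit_edge_lme()` uses a
purpose-built REML solver: rows are rotated subject-block-wise into
between (mean) and within (Helmert) components, in which the covariance
is diagonal with weights $1/(1+\theta n_i)$; the profiled REML criterion
in the single variance ratio θ is evaluated on a log-spaced grid for all
edges simultaneously and refined by local quadratic interpolation. The
solver is exact for this model class; tests assert agreement with
`lme4::lmer` per edge and, on designs with no between-subject age
variation, equality with subject-dummy OLS to 1e-6. A `engine = "lmer"`
option fits each edge with lme4 instead.

Two matrices summarize each fit: the predicted **baseline at age 14**
(demographic marginalization: intercept + 14·β_age + β_sex/2 + each site
dummy at 1/3 — i.e. the prediction for a demographically balanced
14-year-old; the single age term is used) and the **rate of change**
(β_age itself). The **maturational index** of a node is the Spearman
correlation between its baseline row and its change row across all edges
to other nodes: positive = "conservative" (baseline-strong edges
strengthen), negative = "disruptive" (reorganization). Nodes are
classified at BH-FDR q < 0.05; the index is invariant to any strictly
monotone transform of either input, which also means the choice of edge
transform (Fisher z vs raw r) provably cannot change it.

A caveat the user should know: baseline-at-14 and slope *estimates* share
sampling error (prediction at the left edge of the age range
anti-correlates with the slope estimate), so when true change is zero and
baseline structure is weak, estimated MIs acquire a negative bias. With
realistic baseline heterogeneity (as in the generator defaults) the bias
is second-order; it disappears entirely in the noiseless validation
cases.

## 7. Age axis by diffusion-map embedding

`embed_age_axis()` takes the symmetric matrix of per-edge age-effect
t-values, keeps each row's top 10% (row-wise thresholding keeps every
node connected; a global variant would let weakly aging nodes drop out),
re-symmetrizes by the elementwise maximum, builds a normalized-angle
affinity between row profiles, and computes the diffusion-map embedding
with anisotropic diffusion parameter 0.5 and diffusion time 0 (components
scaled by λ/(1−λ)). The first nontrivial component is the cortex-wide
axis of synchronized age effects. Signs are fixed by correlation with the
input row sums; group-level axes should be aligned by orthogonal
Procrustes (`align_axes()`) before comparing loading distributions.
Validation: on planted two-block matrices the first component separates
the blocks and correlates > 0.99 with a dense eigensolve of the Markov
operator computed by an independent code path.

## 8. Group comparison of maturational indices

Subjects are split by the sign of their change in resilient functioning
(`split_groups()`; exact zeros are excluded). `compare_mi_groups()`
recomputes the full edge-LME → MI chain per group and tests per-node
differences two ways, both required for significance:

1. a z-test on Fisher-transformed Spearman correlations with the
   Fieller-corrected standard error $1.06/\sqrt{m-3}$ (m = edges per
   node), BH-FDR corrected; Cohen's q = atanh(ρ₊) − atanh(ρ₋) is the
   effect size;
2. a demography-preserving permutation: group labels are shuffled within
   sex × age-tertile strata (singleton strata merged into the nearest age
   stratum within sex), preserving group sizes, and the whole
   LME → MI chain is recomputed per permutation.

Significant nodes are categorized as *less conservative* (both groups
conservative, +Δ weaker), *more disruptive* (both disruptive, +Δ more
negative), or *tipping point* (+Δ disruptive where the −Δ group shows no
significant coupling).

The per-permutation refit is the expensive step; the package's solver
makes one permutation of a 360-parcel problem feasible, but the headline
10,000-permutation setting is still hours of CPU — the default `n_perm`
is 1,000 with the full count behind the flag.

## 9. The synthetic-cohort generator

`simulate_cohort()` generates the study conditions the analysis assumes,
with a ground-truth record for recovery tests:

* **Design:** five age strata (14–15 … 22–25) with equal weights, sex
  balanced, three sites, two sessions per subject with interval
  ~ Normal(1.26, 0.33) truncated to [0.5, 2.5] years; behavioral visit
  ages jittered (SD 0.08 y) off imaging ages so the separate
  interval-adjustment code paths are exercised. Follow-up ages are capped
  at 26 (the design's age range).
* **Behavior:** adversity instruments are ordinal severity bands 0–3
  (latent normal cut at the 50/75/90th percentiles, subject-correlated at
  0.7), with exponentially decaying weights — a few instruments dominate,
  as with real trauma/life-event/SES measures, and a tree ensemble can
  fit the normative response nearly unbiasedly. The systematic part
  explains 21% of latent distress variance; the remaining 79% is the
  resilience residual *r*, with within-subject correlation 0.5 (the
  stability of *r* is not an empirical claim — it is a free parameter).
  Items load on the latent distress factor with loadings 0.45–0.85, the
  last two reverse-keyed.
* **Myelin proxy:** MT(parcel, depth) = baseline profile increasing
  toward the white boundary + β_age(parcel, depth) · age + subject
  intercept + noise, with β_age following a posterior-to-anterior
  gradient (0.003–0.010 units/year) peaking at mid depth. In ~10 planted
  parcels the change score additionally couples to Δr with target
  standardized strength γ = 0.36; γ is specified on the correlation scale
  and converted to a raw slope from the configured noise variances
  (`planted_coupling_theory()` gives the closed form used as the test
  oracle).
* **CSF:** logistic ramp from ~0 at the white boundary to 0.35 at the
  pial-most depth, monotone, with per-session scale jitter.
* **FC:** block-community structure (4 blocks; within/between Fisher-z
  levels 0.35/0.05) with subject and session noise, a planted seed-FC
  coupling to Δr, and planted low-signal regions for the exclusion rule.
* **Matrix-mode maturation:** `simulate_mpc_series()` plants
  conservative/disruptive structure directly at the matrix level,
  M(age) = M0 + age·B with B coupling each node's edges to its baseline
  pattern at per-node strength κ. M0 is a symmetric circulant (constant
  row means) plus a deterministic rank-one texture that removes the
  circulant's exact ties; this construction keeps B symmetric *and* makes
  the noiseless κ = ±1 cases exactly MI = ±1. Profile-level and
  matrix-level effects are planted separately because synthesizing depth
  profiles that realize an arbitrary covariance trajectory is ill-posed.

All randomness flows through one seed; identical (config, seed) pairs
reproduce every array bit for bit. What the generator does **not**
emulate: vertex-level images, scanner noise physics, non-MCAR item
missingness, site-dependent effects, or skewed SES sampling — passing
recovery tests on these cohorts demonstrates correctness of the
estimators under the assumed generative structure, not robustness to
real-data pathologies.

## 10. Problem sizes and numerical choices

Validation runs use simulation sizes chosen for a single CPU: cohorts of
up to 250 subjects (500 sessions), 12–40 parcels, permutation counts
199–1,000, 120–500 Monte-Carlo replicates per calibration claim — rather
than the 360-parcel, 10,000-permutation headline configuration, which the
same code paths handle given proportionally more time. Key tolerances:
correlation clipping at 1 − 10⁻⁷ before Fisher transforms; REML θ grid
10⁻⁴–10⁴ (49 points, quadratically refined; a boundary hit is recorded
per edge); zero-variance guards in CSF correction, winsorization,
motion regression and MPC exclusion; permutation p-values use the
add-one convention so they are never zero. Degenerate inputs error
loudly (rank-deficient GLM designs, disconnected affinity graphs,
degenerate spectra, single-session-only cohorts) rather than returning
numbers.

## 11. Known limitations

* The residual-based resilience score inherits any bias of the normative
  model; with under-fit predictions the score retains exposure variance
  (this drove the generator's ordinal-feature design and the all-features
  `mtry` choice).
* The MI's estimation-noise bias (Section 6) argues for interpreting
  group *differences* rather than absolute MI levels — which is how the
  group comparison is built.
* Real-data mode consumes parcel-level TSV matrices; surface processing,
  fMRI denoising, and atlas derivation are upstream of this package.
* With two sessions per subject, subject random intercepts and residuals
  are only just identified; the REML grid's lower boundary (θ → 0)
  absorbs edges with no detectable subject variance, which is recorded
  in the `boundary` flag.
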