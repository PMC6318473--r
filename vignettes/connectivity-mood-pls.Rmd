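---
title: "Methods: behavioural PLS for connectivity–mood covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural PLS for connectivity-mood covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodconn)
```

## The model

`moodconn` asks a within-person question: across repeated scan sessions, do
configurations of functional connectivity (FC) covary with self-reported
mood? Each session contributes one row to two blocks:

- **X** (sessions × edges): the upper triangle of the session's FC matrix,
  where FC is the zero-lag Pearson correlation between two regions' activity
  time series. With $k$ regions there are $p = k(k-1)/2$ edges, stored in a
  frozen row-major order $(1,2), (1,3), \dots$ that every edge vector in the
  package follows.
- **Y** (sessions × scales): mood ratings on the 13 PANAS-X scales (2
  general-dimension scales plus 11 specific ones), or any other numeric
  behavioural battery.

Both blocks are standardized column-wise (mean 0, sd 1, denominator
$n-1$) and cross-correlated, $R = X_z' Y_z / (n-1)$, so every entry of $R$
is a plain Pearson correlation. The behavioural-PLS decomposition is the
SVD

$$ R = U S V', $$

whose $i$-th latent variable pairs an edge pattern $u_i$ with a scale
pattern $v_i$; their session projections $X_z u_i$ and $Y_z v_i$ have the
largest possible covariance among unit-norm direction pairs. The effect
size of a latent variable is $\eta_i = \sigma_i^2 / \sum_j \sigma_j^2$,
the fraction of cross-block covariance it accounts for. Loadings are
correlations of the raw scales with the session network scores.

The method assumes sessions are exchangeable rows. No session-to-session
autocorrelation model is fitted; if the real data carry temporal
autocorrelation across sessions, resampling-based reliability estimates are
fixed-effect statements for this individual and may be optimistic.

### Sign convention

SVD signs are arbitrary, so each $(u_i, v_i)$ pair is flipped jointly until
the sum of $v_i$ over an anchor set of scales is non-negative. The default
anchor is the `positive_affect` scale when present (all scales otherwise),
which makes "positive edge weight ↔ positive mood" reproducible across
fits, machines and resamples.

## Inference

All resampling p-values use $(\text{count}+1)/(n_{\text{perm}}+1)$: a valid
finite-sample p that is never exactly zero, so a very strong effect reports
the achievable floor $1/(n_{\text{perm}}+1)$ rather than 0.

- **Permutation test** (`permutation_test`): rows of X are permuted,
  breaking the session pairing; the singular values are recomputed per
  replicate and compared rank-for-rank with the observed ones. Column means
  and sds are invariant to row order, so permuting the standardized block
  is exactly equivalent to re-standardizing the permuted raw block. A
  `max_sigma_null` flag compares every observed singular value against the
  null of the largest one instead.
- **Bootstrap** (`pls_bootstrap`): sessions are resampled jointly with
  replacement; each replicate's decomposition is reflected (joint sign
  flip) onto the original fit, and the bootstrap ratio divides the
  *original* weight by the bootstrap sd (a `numerator` option substitutes
  the bootstrap mean). Replicates that collapse to fewer than two distinct
  sessions, or that produce a zero-variance column, are discarded and
  counted; more than 1% discards raises a warning. Resamples are
  re-standardized by default (`re_standardize = FALSE` reuses the original
  standardization).
- **Split-half stability** (`split_half_stability`): sessions are split
  into halves of sizes $\lceil n/2 \rceil$ and $\lfloor n/2 \rfloor$; each
  half's cross-correlation $R_h$ is projected through the full-sample
  vectors, $U_h = R_h V S^{-1}$, $V_h = R_h' U S^{-1}$, and the two halves'
  projected patterns are correlated per latent variable. Because the
  full-sample $V, S$ enter both halves' projections, this scheme is
  optimistic under the null when a block is low-dimensional: with only 13
  scales, the null v-pattern split correlation sits far above zero (~0.7 in
  our null simulations), while the edge-pattern correlation collapses
  toward zero at realistic edge counts. Split-half numbers should therefore
  be read as *relative* stability (edge vs scale patterns, signal vs null),
  not as absolute reliability coefficients. Latent variables whose singular
  value is numerically zero (rank is capped at $n-1$) are excluded with a
  notice.
- **Cross-validation** (`out_of_sample_cv`): repeated random train/test
  splits with test size $\lceil \text{fraction} \cdot n \rceil$ (25% of 73
  sessions → 19). The model — including the standardization parameters —
  is fit on training rows only; held-out rows are projected with the
  training means/sds, so no information leaks from test to train.
  Significance comes from permuting X and repeating the whole procedure.

## Network statistics

Edge statistics (typically bootstrap ratios) are mapped back to a symmetric
node × node matrix and summarized against a node partition into
communities (in practice a resting-state-network atlas; the package never
detects communities itself):

- regional contribution = mean of a node's $k-1$ incident edge values;
  top-fraction selection uses $\lceil \text{fraction} \cdot k \rceil$ nodes
  with ties broken by node index.
- community-block means are sign-restricted: `positive` averages only
  positive entries, `negative` averages only negative entries and reports
  magnitudes; blocks with no qualifying edge are `NA`, never silently zero.
- **modularity** uses the weighted Newman–Girvan form under the
  configuration model, $Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} -
  \frac{s_i s_j}{2m}\right]\delta(c_i, c_j)$, with negative weights zeroed
  (the configuration model is defined for positive weights). The $1/2m$
  normalization is included so that $Q$ is comparable across sessions of
  different overall connectivity; `normalize = FALSE` returns the bare sum.
- **system segregation** is $S = (Z_w - Z_b)/Z_w$, the normalized
  difference of mean within- and between-community weight. Densities and
  $Z_w, Z_b$ use raw signed means (no positivity restriction), so $S$ and
  $Q$ probe related but distinct constructs.

Two label-permuting null models are provided. `label_permutation_null`
permutes node labels independently per replicate and z-scores any
partition-dependent statistic. `session_consistent_label_null` draws one
permutation per replicate and applies it to *every* session before
recomputing the four per-session measures and their Spearman correlations
with behaviour — this tests whether measure–behaviour coupling depends on
the actual community assignment rather than non-specific density
fluctuations. In the seed-fingerprint analysis
(`seed_fingerprint_analysis`) the seed keeps its own label, is excluded
from every community average, and observed per-community correlations are
z-scored against the pooled null distribution.

## Covariate analyses

Fasting-type contrasts use the pooled-variance Student t
(df $= n_1 + n_2 - 2$); per-group score correlations are compared with the
standard Fisher z statistic
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$; lifestyle variables enter one simple
regression each per score type, with Benjamini–Hochberg FDR correction
across the whole covariate × score-type family.

## The synthetic generators

Two generators provide ground truth at different levels, decoupling unit
tests of the decomposition from integration tests of the FC pipeline.

**Edge-level** (`generate_edge_dataset`): plants the exact rank-1 structure
the decomposition assumes,
$X = d\, t\, u_\star' + E$, $Y = d\, t\, v_\star' + F$, with i.i.d.
standard-normal latent scores $t_s$ and noise. Defaults: 73 sessions, 13
scales, and a unit-norm edge pattern $u_\star$ spread over the whole
connectome — mood-related connectivity patterns are brain-wide, and a
fully distributed pattern also avoids the standardization attenuation that
selectively shrinks large sparse weights. `support_fraction < 1` plants a
sparse pattern instead, used for on/off-support bootstrap contrasts. The
scale pattern $v_\star$ has a dominant positive-affect weight, positive
weights on the positive-valence scales and negative weights on the
negative-valence ones.

**Time-series level** (`generate_session_timeseries`,
`generate_timeseries_study`): draws stationary multivariate AR(1) series
whose cross-sectional correlation targets a block structure —
`within_coupling` (default 0.35) inside communities and
`between_coupling + modulation_gain × latent` (defaults 0.1 and 0.1)
across communities. The planted ground truth is therefore *integration
tracks positive mood*: sessions with higher latent mood have higher
between-community FC. Defaults emulate the emulated study design: 73
sessions, 518 time points, lag-1 autocorrelation 0.4 (typical of bandpass-
filtered BOLD at a ~1 s sampling interval), four communities, and a
desk-scale 60 regions (the full-size recordings in this literature use
several hundred). Positive definiteness of the target correlation is
enforced by clipping eigenvalues at $10^{-8}$ and renormalizing to unit
diagonal; an effective between-coupling outside $(-1, 1)$ is rejected with
the offending value.

The generators deliberately omit much of what makes real fMRI hard:
hemodynamics, motion and physiological artifacts, session-to-session
autocorrelation (latent scores are i.i.d.), scanner drift, and spatially
heterogeneous parcel sizes. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated — not that real
recordings satisfy its assumptions.

`generate_covariates` emulates the study design's alternating fasting
schedule (split sizes differ by at most one) plus lifestyle, sleep and
weather columns drawn independently of the latent mood signal.

## Numerical and degenerate-input policy

- Zero-variance columns are a hard error naming the column — never a
  silent drop. Real data must be cleaned explicitly.
- All generators and resampling procedures are pure functions of
  (inputs, seed); the pipeline derives stage seeds deterministically from
  one master seed, and seeds are kept within the 32-bit integer range.
- Degenerate statistics (zero null sd, seed-only communities, empty
  sign-restricted blocks, all-zero singular values) are flagged as `NA`
  with a warning or attribute, or raised as errors where no sensible value
  exists.

## Problem sizes in the test suite

The test and acceptance simulations run at deliberately desk-scale sizes —
73 sessions with 10–60 nodes for the decomposition and calibration studies
(200–500 replicate data sets for null calibration), and 73 sessions ×
40 nodes × 300 time points for the integration-detection study (50
replicates) — sizes at which every null calibration and power property is
measurable in minutes while preserving the session count, scale count and
design structure being emulated.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_sessions = 73, n_nodes = 40, n_timepoints = 300, seed = 1)
study <- generate_timeseries_study(cfg)
cov <- generate_covariates(cfg$n_sessions, seed = 2)
run <- run_pipeline(series = study$series, mood = study$mood,
                    partition = study$partition, covariates = cov,
                    n_perm = 1000, n_boot = 500, n_splits = 500,
                    cv_splits = 100, seed = 3, output_dir = "results")
print(run)
```

## Known limitations

- With far more edges than sessions the problem is ill-posed; the
  decomposition is a descriptive maximum-covariance pattern, and all
  reliability statements are resampling-based, not parametric.
- The split-half projection scheme is optimistic for low-dimensional
  blocks (see above).
- The bootstrap treats sessions as exchangeable; autocorrelated sessions
  would require a block bootstrap, which is out of scope.
- Communities are always user-supplied; no community detection, spatial
  null models, or FC thresholding is performed anywhere.
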