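---
title: "Motion-inclusive connectivity and brain-behavior association: models and choices"
author: "motionfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-inclusive connectivity and brain-behavior association: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`motionfc`, the assumptions behind them, the tunable parameters, and the
design choices made where the methodology left genuine freedom. The
package targets resting-state functional-connectivity cohorts in which
head motion is both a nuisance (it inflates connectivity) and a selection
force (motion-based exclusion rules disproportionately remove some
demographic groups).

## Framewise displacement and scrubbing

Framewise displacement for frame $i$ is the sum of absolute backward
differences of the six rigid-body realignment parameters, with rotations
(radians) converted to arc length on a sphere of radius $r$:

$$FD_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}| +
  r\,(|\Delta\alpha_i| + |\Delta\beta_i| + |\Delta\gamma_i|),$$

with $r = 50$ mm (the approximate cortex-to-head-center distance in
youth and adults) and $FD = 0$ at the first frame of each run. Three
conventions are worth making explicit:

- **Absolute differences.** Some write-ups print the equation without
  absolute-value bars; without them FD could be negative, contradicting
  its definition as a displacement. We use absolute differences
  throughout, which is the convention of the FD literature this
  definition comes from.
- **Run boundaries.** Backward differences never span runs; the
  between-scan "jump" is physically meaningless. Likewise, censoring
  windows (below) are clipped at run boundaries.
- **Mean FD.** The per-scan summary averages all frames including the
  per-run leading zeros (`mean_fd(include_first = FALSE)` excludes them;
  with 375-frame runs the difference is below 0.1%).

Rotations are assumed to be radians on input, the FSL/HCP convention; a
`degrees = TRUE` switch converts other dialects. Respiratory filtering of
realignment parameters is an upstream preprocessing concern and is out of
scope: FD is computed from the parameters as given.

Scrubbing flags every frame with $FD > 0.20$ mm — strictly greater, so a
frame exactly at threshold is retained — and censors it together with 1
preceding and 2 succeeding frames (4 frames per isolated excursion).
Overlapping windows form a union. Both window widths and the threshold
are configurable (`censor_config()`).

Note that the 0.20 mm *frame-flagging* threshold and the 0.20 mm
*participant-level mean-FD cutoff* are distinct rules that happen to share
a value; they are deliberately separate parameters (`fd_threshold` governs
frames; the eligibility mode governs participants), and the package never
collapses them.

## minTP matching and eligibility

Participants differ in how many frames survive scrubbing, and effective
scan length itself drives connectivity reliability. The minTP rule
equalizes it: retained frames are ranked by ascending FD (ties broken by
earlier frame index, so the ordering is reproducible) and exactly
`min_tp = 100` lowest-FD frames are kept, in temporal order. Pearson
correlation is order-invariant, so temporal ordering is purely for
inspectability.

Eligibility then admits two modes:

- `mean_fd_cutoff`: the classical rule, mean FD < 0.20 mm;
- `min_tp`: at least 100 retained frames — this keeps "high-motion"
  participants whose traces contain 100 clean frames, the package's
  central inclusive variant.

A participant with fewer retained frames than `min_tp` is flagged
ineligible (a value, not an exception: cohort code must be able to count
these). No further minimum-data rule is imposed on the concatenated
series.

## Connectivity estimators

All three estimators produce Fisher-z edge vectors in canonical row-major
upper-triangle order with an explicit edge → (ROI$_i$, ROI$_j$) map
(`edge_index_map()`): the methodology never prescribes an edge order, but
downstream edge selection must be stable across methods, so one order is
fixed and serialized. Degenerate correlations $|r| = 1$ are clipped to
$1 - 10^{-7}$ before `arctanh` with an audited clip count.

The bagged estimator draws `B` frame resamples (i.i.d. uniform with
replacement, no block structure — plain resampling of the minTP-matched
set is what is being emulated) and keeps every replicate; the mean bagged
matrix is also produced, but the brain-behavior engine consumes the
per-replicate values, since the full-scale design's evaluation count
(11 × 500 × 500) only arises per-replicate. Per-replicate RNG streams are
derived from (seed, replicate index), so results do not depend on
evaluation order. Replicates whose resample leaves an ROI constant are
excluded from the mean and counted.

## Partial Spearman, FDR, and edge selection

The association statistic is a partial Spearman correlation, defined as
Pearson-on-rank-residuals: every variable is rank-transformed (average
ranks on ties), the x- and y-ranks are residualized on the covariate
ranks plus intercept by least squares, and Rs is the Pearson correlation
of the residuals. This is the standard construction and makes the
no-covariate case reduce *exactly* to the plain Spearman coefficient
(verified against an explicit projection-matrix oracle in the tests).
P-values use the $t$ approximation with $n - 2 - k$ degrees of freedom.
Default covariates are sex (binary-coded) and mean FD; arbitrary numeric
covariates (age, deprivation index, puberty) pass through unchanged and
categorical ones (site) are expanded to indicator columns with the
reference level dropped.

The mean-FD covariate is the full-timeseries mean FD for all three
methods, not a per-method recomputation over retained frames: one value
keeps the methods comparable, and the choice is exposed rather than
hidden (compute it differently and pass your own column if desired).

Edges are corrected by Benjamini–Hochberg FDR at $q = 0.05$
(`stats::p.adjust` under the hood; the tests check the step-up rule
against a brute-force oracle). Among surviving edges, selection is by
|Rs| — magnitude, not sign, so an edge at Rs = −0.16 beats one at +0.15 —
with `strongest` and `weakest` modes and a lower-edge-id tie-break. When
no edge survives (a real outcome for weakly coupled behaviors), the
result is explicitly empty, not an error.

## Reproducibility curves, AUC and ΔAUC

Sampling variability is profiled on `k = 11` sample sizes equally spaced
in $\log_{10}$ between `n_min = 25` and the group maximum, rounded to the
nearest integer with exact endpoints — this reproduces all six published
interval sequences the implementation was checked against. At each size,
`B = 500` subsamples are drawn *without* replacement; each yields one Rs
(for the bagged method, the mean Rs across timepoint replicates). The
curve records mean, percentile 95% CI (2.5/97.5), minimum and maximum. At
the full cohort size every draw is the same set, so the CI width is
exactly zero there.

The AUC is the trapezoidal area of CI width against raw N (not log N).
The methodology never writes this formula down; this definition was
adopted because it numerically reproduces the published reference AUC
from that table's printed CI bounds to within their two-decimal rounding
(249.93 vs 250.01, 0.03%), which no log-N variant does. ΔAUC is the
percent absolute change relative to the standard method;
the signed variant is positive when the comparison method's CIs are
tighter.

Method comparison is **paired**: subsample draws are generated once per
(size, iteration) and shared across methods, so identical inputs give
ΔAUC = 0 exactly and concordance below is computed on genuinely paired
draws. The evaluation ledger (`schedule_evaluations()`) enumerates the
cost of a design without executing it: 11 × 500 = 5,500 partial
correlations for the standard or motion-ordered method, 11 × 500 × 500 =
2.75 million for the full-scale bagged design. The default `bag_B = 50`
runs the bagged engine at a tractable scale while the ledger keeps the
full-scale count auditable.

## Concordance

Agreement between two methods' paired bootstrap estimates is summarized by
Pearson's $r$ and Lin's concordance coefficient

$$\rho_c = \frac{2\,\mathrm{cov}(x_1, x_2)}
  {\mathrm{var}(x_1) + \mathrm{var}(x_2) + (\bar x_1 - \bar x_2)^2},$$

evaluated with population ($1/n$) moments — Lin's original convention;
$\rho_c(x, x) = 1$ holds under either convention, so the choice is
recorded but not load-bearing. $\rho_c = r \cdot C_b$ with
$C_b \in (0, 1]$, so $\rho_c$ additionally penalizes mean and variance
shifts; both are reported because $r = 1$ with $\rho_c < 1$ is exactly
the signature of a calibrated-but-biased method. Default evaluation sizes
are N = 25 (typical study) and N = 250 (large study); N is a free
parameter.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the physics of the scanner. Its defaults are the study
conditions used throughout the tests:

- **Groups and motion.** Three groups whose FD distributions have medians
  0.16, 0.20 and 0.19 mm. Per-frame FD is log-normal with dispersion
  0.35 applied both between participants and frame-to-frame, an AR(1)
  temporal correlation of 0.85 on the log scale, and supra-threshold
  bursts (2 per run on average, geometric lengths of mean 3 frames,
  amplitudes uniform on 0.30–0.60 mm). Temporal persistence matters:
  with independent frame noise, scattered excursions and their censor
  windows would annihilate the retained set of any median-0.20
  participant, which is not how real traces behave. The log-normal
  baseline location is calibrated against the realized burst mask so the
  group median of mean FD hits the configured target (the Monte-Carlo
  check in the tests verifies ±0.01 mm).
- **Rigid-body traces.** Parameter increments are drawn with random signs
  and a random split across the six parameters, scaled so their weighted
  absolute sum (rotations × 50 mm) equals the target FD exactly — FD
  computed downstream therefore matches the generator's intent to
  machine precision.
- **Timeseries.** Latent unit-variance Gaussian ROIs, independent except
  the designated signal pair (ROIs 1–2) whose true correlation is
  $\tanh(\mathrm{atanh}(0.3) + 0.3\,g_i)$ for participant latent
  $g_i \sim N(0,1)$, plus a global artifact with per-frame amplitude
  $0.5 \times FD(t)$ shared by all ROIs — high-FD frames inflate every
  edge, giving the motion confound its positive FD-connectivity
  correlation across participants.
- **Behavior.** A Gaussian copula: the behavior latent is
  $\rho_z g_i + \sqrt{1-\rho_z^2}\,\varepsilon$ with
  $\rho_z = 2\sin(\pi\rho_{\mathrm{true}}/6)$, so the *population
  Spearman* correlation between the (monotone-in-$g_i$) true edge and the
  behavior equals $\rho_{\mathrm{true}}$ — chosen because the analysis
  statistic is rank-based, so the planted effect should be a rank
  correlation. Sex (0.3 latent SD) and mean-FD (−0.3 SD per SD) effects
  are added, then each score is affinely rescaled to the T-score
  convention (mean 50, SD 10) per cohort. With a scalar
  `rho_true = ρ`, the three scores carry effects (ρ, ρ/2, 0): a strong
  cognition effect, a weaker externalizing one, and a null — mirroring
  the typical ordering of such measures.

What the generator does **not** emulate: raw images, spatial structure,
physiological noise, site/scanner effects, item-level instruments, and
any non-Gaussian dependence beyond the single planted edge. Passing tests
therefore demonstrate that the *pipeline* recovers what was planted under
motion confounding and group-skewed eligibility — not that real data meet
these assumptions.

## Numerical choices and degenerate inputs

- Fisher-z clip at $1 - 10^{-7}$ (warned and counted); correlations
  beyond $|r| = 1$ are errors, not clips.
- Rank ties use average ranks everywhere, in both implementation and test
  oracles.
- The Kruskal–Wallis wrapper returns $H = 0$, $p = 1$ for the all-ties
  degenerate case where the textbook statistic is 0/0.
- tSNR with a zero-variance ROI is flagged-undefined (`NA` with the
  offending columns attached), not an exception.
- All RNG flows through per-purpose child seeds derived from one master
  seed (a multiplicative mixing kept below $2^{31}-1$), so cohorts,
  bagging and bootstrap draws are reproducible independently of
  evaluation order, and the caller's RNG state is always restored.

## Problem sizes used by the test-suite

The package's own simulations run at deliberately reduced scale: 20 or
fewer ROIs (190 edges), cohorts of up to 2,000 participants for the
parameter-recovery check (planted $\rho = 0.10$ recovered within ±0.03
by the full-sample motion-ordered partial Spearman), and a scaled-down
reproducibility study (3 × 300 participants, grid 25→300, B = 200,
bagged `bag_B = 50`) that reproduces the qualitative claims: monotone CI
narrowing, ΔAUC under 10% between methods, and $\rho_c > 0.6$ at N = 25.
The full-scale design (352 ROIs, 500 × 500 bootstraps) is supported by
the same code paths; only the evaluation ledger, not execution, is needed
to audit its cost.

## Known limitations

- Connectivity is plain Pearson/Fisher-z; no partial-correlation,
  tangent-space or regularized estimators.
- No contiguity-based censoring variants (e.g. minimum-run-length rules
  or FD-ordered sliding windows).
- The $t$ approximation for partial-Spearman p-values is asymptotic; an
  exact permutation option exists only in spirit for very small n — at
  the sample sizes the pipeline targets the approximation is standard.
- The generator's noise model is a stand-in chosen for testability; its
  parameters are recorded in the ground-truth sidecar rather than claimed
  faithful to any particular cohort.
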