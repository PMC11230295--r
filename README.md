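# motionfc

Head-motion-aware functional connectivity and brain-behavior association
for resting-state fMRI cohorts.

## The problem

In developmental cohorts, head motion is the dominant quality-control
variable: frames with high motion inflate functional connectivity, and the
conventional remedy — excluding every participant whose mean framewise
displacement (FD) exceeds a threshold — discards a large, demographically
skewed fraction of the sample. `motionfc` implements an inclusive
alternative built around three connectivity estimators and a common
brain-behavior analysis engine:

- **standard**: Pearson correlation between every ROI pair over the full
  concatenated timeseries, Fisher z transformed
  (`z = arctanh(r)`; P ROIs give P(P−1)/2 edges, so 352 ROIs give 61,776);
- **motion-ordered**: frames with FD > 0.20 mm are scrubbed together with 1
  preceding and 2 succeeding frames, the retained frames are ranked by
  ascending FD, and connectivity is computed from exactly the `minTP`
  (default 100) lowest-FD frames — every participant with at least `minTP`
  clean frames is eligible, regardless of their mean FD;
- **bagged**: bootstrap aggregation over the minTP-matched frames — B
  (default 500) resamples of size `minTP` drawn with replacement, one
  connectivity matrix per replicate.

FD for frame *i* sums the absolute backward differences of the six
rigid-body realignment parameters, rotations converted to arc length on an
r = 50 mm sphere:

    FD_i = |Δd_x| + |Δd_y| + |Δd_z| + r·(|Δα| + |Δβ| + |Δγ|)

with FD = 0 at each run's first frame.

Brain-behavior associations are edgewise **partial Spearman rank
correlations** (Rs) controlling sex and mean FD, corrected across edges by
Benjamini–Hochberg FDR (q = 0.05); the strongest (or weakest) surviving
edge is selected by |Rs|. Sampling variability is mapped by bootstrapping
each of 11 log-spaced sample sizes N without replacement (B = 500
iterations), summarizing mean Rs, percentile 95% CI, and extremes per N.
Methods are compared by the trapezoidal area under the CI-width curve
(AUC) and its percent rate of change (ΔAUC), and by Lin's concordance
correlation coefficient

    ρ_c = 2·cov(x₁,x₂) / [var(x₁) + var(x₂) + (x̄₁ − x̄₂)²]

between paired bootstrap estimates of two methods.

Because the motivating cohort data are access-restricted, the package ships
a synthetic cohort generator (`cohort_spec()`, `generate_cohort()`) that
emulates the relevant statistical structure: group-dependent FD
distributions (group medians near 0.16/0.20/0.19 mm), autocorrelated FD
with supra-threshold bursts, motion-inflated connectivity, and a planted
edge-behavior rank correlation of configurable size with sex and mean-FD
covariate structure. Every downstream stage is testable end-to-end with no
download.

## Worked example

```r
library(motionfc)

spec <- cohort_spec(n_per_group = 150, n_rois = 20, rho_true = 0.3, seed = 7)
me   <- compute_method_edges(spec, eligibility = "min_tp", bag_B = 25, seed = 7)
nrow(me$behavior)
#> [1] 411        # eligible participants (of 450) under the minTP rule

scan <- edgewise_scan(me$edges$standard, me$behavior, "nih_tbx")
sel  <- select_edge(scan, "strongest")
sel$edge_id; round(sel$rs, 3)
#> [1] 1          # the planted signal edge
#> [1] 0.335

grid <- log_spaced_sizes(25, nrow(me$behavior), 11)
grid$sizes
#> [1]  25  33  44  58  77 101 134 177 235 311 411

rp <- run_reproducibility(
  list(standard       = me$edges$standard[, sel$edge_id],
       motion_ordered = me$edges$motion_ordered[, sel$edge_id],
       bagged         = me$edges$bagged[, , sel$edge_id]),
  me$behavior, "nih_tbx", grid = grid, B = 200, seed = 7)

rp$curves$standard$summary[c(1, 6, 11), ]
#>      method   n mean ci_low ci_high    min  max
#> 1  standard  25 0.31  -0.12    0.63 -0.239 0.75
#> 6  standard 101 0.33   0.17    0.48  0.094 0.52
#> 11 standard 411 0.33   0.33    0.33  0.335 0.33

rp$auc
#>           method  auc delta_percent signed_percent
#> 1       standard 77.2         0.000          0.000
#> 2 motion_ordered 76.6         0.725          0.725
#> 3         bagged 73.8         4.451          4.451

concordance_table(rp, grid, at_n = c(25, 250))
#>           method   N rho_c     r n_draws
#> 1 motion_ordered  25 0.917 0.922     200
#> 2 motion_ordered 235 0.785 0.944     200
#> 3         bagged  25 0.913 0.931     200
#> 4         bagged 235 0.640 0.943     200
```

Reading the output: the edgewise scan recovers the planted edge; the 95%
CI of the brain-behavior Rs tightens from [−0.12, 0.63] at N = 25 to width
zero at the full sample (without-replacement draws of the whole cohort are
identical); the motion-ordered and bagged estimators track the standard one
closely (ΔAUC below 5%, ρ_c above 0.9 at N = 25) while using only the 100
least-motion-corrupted frames per participant — which is what makes the
inclusive `min_tp` eligibility rule viable. `run_pipeline(pipeline_config(...))`
chains all stages (eligibility → connectivity → scan/FDR/edge selection →
reproducibility curves → concordance) and writes CSV/JSON outputs plus a
manifest.

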