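test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(group_labels = c("a", "a")), "unique")
  expect_error(cohort_spec(n_per_group = 0), "positive")
  expect_error(cohort_spec(fd_median_per_group = c(0.1, -0.2, 0.1)),
               "positive")
  expect_error(cohort_spec(rho_true = 1.2), "rho_true")
  expect_error(cohort_spec(n_runs = 5), "1..4")
  sp <- cohort_spec(rho_true = 0.3)
  expect_equal(sp$rho_true, c(0.3, 0.15, 0))
})

test_that("degenerate noise gives constant FD at the group median", {
  sp <- cohort_spec(n_per_group = 1, fd_dispersion = 0, burst_rate = 0,
                    n_runs = 2, frames_per_run = 12, n_rois = 4)
  for (g in sp$group_labels) {
    fd <- framewise_displacement(generate_motion_trace(sp, g, seed = 5))
    med <- sp$fd_median_per_group[match(g, sp$group_labels)]
    first <- !duplicated(fd$run)
    expect_equal(fd$fd[first], c(0, 0))
    expect_equal(fd$fd[!first], rep(med, sum(!first)))
  }
  expect_error(generate_motion_trace(sp, "nosuch", seed = 1),
               "unknown group label: 'nosuch'")
})

test_that("motion traces are deterministic given spec and seed", {
  sp <- cohort_spec(n_per_group = 2, n_rois = 4, n_runs = 2,
                    frames_per_run = 50)
  t1 <- generate_motion_trace(sp, "groupB", seed = 9)
  t2 <- generate_motion_trace(sp, "groupB", seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_motion_trace(sp, "groupB", seed = 10)
  expect_false(identical(t1, t3))
})

test_that("derived FD reproduces the configured group medians", {
  # Monte-Carlo check of the generator against its own targets: the median
  # over participants of mean FD must sit within 0.01 mm of each group's
  # configured median. Moderate n keeps the run fast; the MC standard error
  # of the median here is about 0.003 mm.
  sp <- cohort_spec(n_per_group = 400, n_rois = 4, seed = 17)
  frame <- motionfc:::cohort_frame(sp)
  mfd <- vapply(seq_len(nrow(frame)), function(i) {
    tr <- generate_motion_trace(sp, frame$group[i],
                                seed = motionfc:::derive_seed(sp$seed, 2L, i))
    mean_fd(framewise_displacement(tr))
  }, numeric(1))
  med <- as.numeric(tapply(mfd, frame$group, median)[sp$group_labels])
  expect_true(all(abs(med - sp$fd_median_per_group) < 0.01))
  # supra-threshold excursions are present at the configured burst rate
  expect_gt(mean(mfd > 0.2), 0.1)
})

test_that("timeseries converge to the latent covariance without motion coupling", {
  sp <- cohort_spec(n_per_group = 1, n_rois = 6, n_runs = 1,
                    frames_per_run = 4000, motion_inflation = 0,
                    edge_base_r = 0.4)
  fd <- fd_trace(c(0, runif(3999, 0, 0.15)))
  target <- diag(6); target[1, 2] <- target[2, 1] <- 0.4

  frob <- vapply(c(500, 4000), function(len) {
    ts <- generate_timeseries(sp, fd, seed = 3)[seq_len(len), ]
    sqrt(sum((cor(ts) - target)^2))
  }, numeric(1))
  expect_lt(frob[2], frob[1])  # error shrinks with series length
  expect_lt(frob[2], 0.25)

  # identity latent covariance: mean |off-diagonal| near zero
  sp0 <- cohort_spec(n_per_group = 1, n_rois = 6, n_runs = 1,
                     frames_per_run = 4000, motion_inflation = 0,
                     edge_base_r = 0)
  ts0 <- generate_timeseries(sp0, fd, edge_corr = 0, seed = 4)
  c0 <- cor(ts0)
  expect_lt(mean(abs(c0[upper.tri(c0)])), 0.05)

  expect_error(generate_timeseries(sp, fd_trace(rep(0.1, 10))), "frames")
})

test_that("high-FD frames inflate correlations when motion coupling is on", {
  sp <- cohort_spec(n_per_group = 1, n_rois = 6, n_runs = 1,
                    frames_per_run = 2000, motion_inflation = 2,
                    edge_base_r = 0)
  fd_v <- c(0, rep(0.05, 999), rep(0.6, 1000))
  ts <- generate_timeseries(sp, fd_trace(fd_v), edge_corr = 0, seed = 6)
  mean_off <- function(m) { cc <- cor(m); mean(abs(cc[upper.tri(cc)])) }
  expect_gt(mean_off(ts), mean_off(ts[fd_v <= 0.2, ]))
})

test_that("behavior hits the target Spearman correlation and T-score scale", {
  sp <- cohort_spec(n_per_group = 1, rho_true = 0.10,
                    covariate_effects = list(sex = 0, mean_fd = 0))
  n <- 10000
  set.seed(71)
  g <- rnorm(n); sex <- rbinom(n, 1, 0.5); mfd <- rlnorm(n, -1.7, 0.35)
  beh <- generate_behavior(sp, g, sex, mfd, seed = 8)
  rs <- cor(g, beh$nih_tbx, method = "spearman")
  expect_gt(rs, 0.08); expect_lt(rs, 0.12)
  expect_equal(mean(beh$nih_tbx), 50, tolerance = 1e-8)
  expect_equal(sd(beh$nih_tbx), 10, tolerance = 1e-8)

  # null planted effect
  sp0 <- cohort_spec(n_per_group = 1, rho_true = 0,
                     covariate_effects = list(sex = 0, mean_fd = 0))
  beh0 <- generate_behavior(sp0, g, sex, mfd, seed = 9)
  expect_lt(abs(cor(g, beh0$nih_tbx, method = "spearman")), 0.02)
  # third behavior carries no planted effect by default
  expect_lt(abs(cor(g, beh0$cbcl_int, method = "spearman")), 0.03)

  expect_error(generate_behavior(cohort_spec(), g, sex, mfd)
               , NA)  # defaults are valid
})

test_that("cohort assembly is deterministic with correct bookkeeping", {
  sp <- tiny_spec(n_per_group = 5L, n_rois = 20L)
  co <- generate_cohort(sp)
  expect_length(co$participants, 15L)
  expect_equal(ncol(co$participants[[1]]$ts), 20L)
  expect_equal(nrow(co$participants[[1]]$ts),
               sp$n_runs * sp$frames_per_run)
  expect_equal(nrow(co$behavior), 15L)
  expect_equal(co$truth$signal_edge_id, 1L)
  expect_equal(signal_edge_id(sp),
               which(edge_index_map(20)$roi_i == 1 &
                     edge_index_map(20)$roi_j == 2))

  co2 <- generate_cohort(sp)
  expect_identical(co$behavior, co2$behavior)
  expect_identical(co$participants[[7]]$ts, co2$participants[[7]]$ts)
})

test_that("motion confound: mean FD tracks mean edge strength across participants", {
  sp <- cohort_spec(n_per_group = 60, n_rois = 8, n_runs = 2,
                    frames_per_run = 100, motion_inflation = 1,
                    seed = 23)
  me <- compute_method_edges(sp, censor_config(min_tp = 50),
                             methods = "standard", eligibility = "min_tp",
                             seed = 23)
  strength <- rowMeans(me$edges$standard)
  expect_gt(cor(me$behavior$mean_fd, strength, method = "spearman"), 0)
})

test_that("planted effects are recovered from scrubbed frames across effect sizes", {
  # partial Spearman at the signal edge, minTP frames only, against the
  # planted rho; n = 300/group keeps this quick while 3 MC SEs still
  # separate rho = 0 from rho = 0.3
  for (rho in c(0, 0.3)) {
    sp <- cohort_spec(n_per_group = 300, n_rois = 6, rho_true = rho,
                      seed = 31 + round(10 * rho))
    me <- compute_method_edges(sp, methods = "motion_ordered",
                               eligibility = "min_tp", seed = 1)
    n_elig <- nrow(me$behavior)
    got <- partial_spearman(me$edges$motion_ordered[, signal_edge_id(sp)],
                            me$behavior$nih_tbx,
                            me$behavior[c("sex", "mean_fd")])$rs
    expect_lt(abs(got - rho), 3 / sqrt(n_elig - 3))
  }
})
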