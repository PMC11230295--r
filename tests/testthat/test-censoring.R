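test_that("one isolated supra-threshold frame censors exactly four frames", {
  fd <- fd_trace(c(0, .05, .50, .05, .05, .05, .05, .05, .05, .05))
  res <- scrub(fd, censor_config())
  expect_equal(which(!res$keep_mask), 2:5)  # T-1, T, T+1, T+2
  expect_equal(sum(!res$keep_mask), 4L)
  expect_equal(res$n_retained, 6L)
  expect_true(all(res$retained_fd <= 0.20))
})

test_that("scrubbing handles no-op, window unions and run boundaries", {
  # nothing above threshold: everything retained (values at threshold kept)
  fd <- fd_trace(c(0, rep(0.20, 9)))
  res <- scrub(fd, censor_config())
  expect_equal(res$n_retained, 10L)

  # adjacent excursions: union of the two windows spans 5 frames
  v <- rep(0.05, 10); v[4:5] <- 0.5
  res <- scrub(fd_trace(v), censor_config())
  expect_equal(which(!res$keep_mask), 3:7)

  # windows clip at run boundaries: an excursion at a run's last frame
  # must not spill its trailing window into the next run
  fd <- fd_trace(c(0, .05, .50, 0, .05, .05),
                 run = c(1, 1, 1, 2, 2, 2))
  res <- scrub(fd, censor_config())
  expect_equal(which(!res$keep_mask), 2:3)
  expect_true(all(res$keep_mask[4:6]))
})

test_that("scrubbing equals the brute-force window oracle and is monotone", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    runs <- sort(sample(1:2, n, replace = TRUE))
    v <- rlnorm(n, log(0.12), 0.6)
    v[!duplicated(runs)] <- 0
    fd <- fd_trace(v, runs)
    cfg <- censor_config(n_before = sample(0:2, 1), n_after = sample(0:3, 1))
    res <- scrub(fd, cfg)
    expect_equal(res$keep_mask,
                 scrub_oracle(v, runs, cfg$fd_threshold,
                              cfg$n_before, cfg$n_after))

    # raising the threshold never censors more; widening windows never less
    looser <- censor_config(fd_threshold = 0.30, n_before = cfg$n_before,
                            n_after = cfg$n_after)
    expect_gte(scrub(fd, looser)$n_retained, res$n_retained)
    wider <- censor_config(n_before = cfg$n_before + 1,
                           n_after = cfg$n_after + 1)
    base <- censor_config(n_before = cfg$n_before, n_after = cfg$n_after)
    expect_lte(scrub(fd, wider)$n_retained, scrub(fd, base)$n_retained)
  }
})

test_that("motion ranking sorts by FD with stable index tie-break", {
  fd <- fd_trace(c(0.19, 0.01, 0.05))
  expect_equal(rank_by_motion(scrub(fd, censor_config())), c(2L, 3L, 1L))

  # pure ties preserve temporal order
  fd <- fd_trace(rep(0.1, 6))
  expect_equal(rank_by_motion(scrub(fd, censor_config())), 1:6)

  # oracle: argsort with index tie-break on a random trace
  set.seed(5)
  v <- round(rlnorm(80, log(0.1), 0.5), 2)  # rounding forces ties
  res <- scrub(fd_trace(v), censor_config())
  oracle <- res$retained_indices[order(res$retained_fd,
                                       res$retained_indices)]
  expect_equal(rank_by_motion(res), oracle)
})

test_that("minTP selection returns the lowest-FD frames or an ineligible flag", {
  set.seed(9)
  v <- runif(150, 0, 0.19)
  res <- scrub(fd_trace(v), censor_config(min_tp = 100))
  sel <- select_min_tp(rank_by_motion(res), censor_config(min_tp = 100))
  expect_true(sel$eligible)
  expect_length(sel$frames, 100)
  expect_false(is.unsorted(sel$frames))  # temporal order
  expect_lte(max(v[sel$frames]), sort(v)[100])  # all among 100 smallest

  short <- select_min_tp(seq_len(99), censor_config(min_tp = 100))
  expect_false(short$eligible)
  expect_length(short$frames, 0)

  # min_tp equal to the retained count selects the whole retained set
  all_sel <- select_min_tp(rank_by_motion(res),
                           censor_config(min_tp = res$n_retained))
  expect_equal(all_sel$frames, sort(res$retained_indices))
})

test_that("minTP eligibility retains at least as many as the mean-FD cutoff", {
  # uniform low motion: both rules keep everyone
  low <- list(participants = lapply(1:6, function(i)
    list(id = paste0("s", i), group = "g1",
         fd = fd_trace(c(0, rep(0.10, 119))))))
  for (m in c("mean_fd_cutoff", "min_tp")) {
    el <- cohort_eligibility(low, censor_config(), m)
    expect_equal(el$retention$pct_retained, 100)
  }

  # a participant with high mean FD but >= min_tp clean frames is excluded
  # by the cutoff yet included by the minTP rule
  v <- c(0, rep(0.05, 120), rep(0.9, 80))
  mixed <- list(participants = list(
    list(id = "s1", group = "g1", fd = fd_trace(v))))
  expect_gt(mean_fd(fd_trace(v)), 0.20)
  expect_false(cohort_eligibility(mixed, censor_config(),
                                  "mean_fd_cutoff")$table$eligible)
  expect_true(cohort_eligibility(mixed, censor_config(),
                                 "min_tp")$table$eligible)

  # motion-skewed synthetic cohorts: minTP retention dominates in every
  # group, across seeds
  for (seed in c(21, 22)) {
    co <- generate_cohort(cohort_spec(n_per_group = 25, n_rois = 4,
                                      seed = seed),
                          keep_timeseries = FALSE)
    r_fd <- cohort_eligibility(co, censor_config(), "mean_fd_cutoff")
    r_tp <- cohort_eligibility(co, censor_config(), "min_tp")
    expect_true(all(r_tp$retention$pct_retained >=
                    r_fd$retention$pct_retained))
  }
})

test_that("censoring report carries both eligibility flags", {
  co <- generate_cohort(cohort_spec(n_per_group = 4, n_rois = 4, seed = 2),
                        keep_timeseries = FALSE)
  f <- tempfile(fileext = ".csv")
  rep <- write_censor_report(co, censor_config(), f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("id", "n_frames", "n_retained", "mean_fd",
                 "eligible_meanfd", "eligible_mintp"))
  expect_equal(nrow(back), 12L)
  expect_equal(back$n_retained, rep$n_retained)
})
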