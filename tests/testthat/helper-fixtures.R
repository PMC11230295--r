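# Small builders shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays fast.

# A tiny cohort spec for smoke/round-trip tests: 2 short runs, few ROIs,
# a strong planted effect so edge selection succeeds at small n.
tiny_spec <- function(n_per_group = 6L, n_rois = 10L, rho_true = 0.8,
                      seed = 101L, ...) {
  cohort_spec(n_per_group = n_per_group, n_rois = n_rois,
              rho_true = rho_true, n_runs = 2L, frames_per_run = 80L,
              seed = seed, ...)
}

# Censor config matched to the tiny spec's short runs.
tiny_censor <- function(min_tp = 60L) censor_config(min_tp = min_tp)

# A random rigid-body trace with controllable run structure.
random_trace <- function(n_frames, n_runs = 1L, seed = 1L, scale = 0.05) {
  set.seed(seed)
  data.frame(tx = cumsum(rnorm(n_frames, sd = scale)),
             ty = cumsum(rnorm(n_frames, sd = scale)),
             tz = cumsum(rnorm(n_frames, sd = scale)),
             rx = cumsum(rnorm(n_frames, sd = scale / 50)),
             ry = cumsum(rnorm(n_frames, sd = scale / 50)),
             rz = cumsum(rnorm(n_frames, sd = scale / 50)),
             run = rep(seq_len(n_runs), each = n_frames / n_runs))
}

# Brute-force scrubbing oracle: censor every frame within the window of any
# supra-threshold frame of the same run, by direct enumeration.
scrub_oracle <- function(fd, run, threshold, n_before, n_after) {
  keep <- rep(TRUE, length(fd))
  for (t in which(fd > threshold)) {
    same <- which(run == run[t])
    win <- intersect((t - n_before):(t + n_after), same)
    keep[win] <- FALSE
  }
  keep
}

# Explicit-projection partial Spearman oracle: rank everything, build the
# hat matrix from the covariate ranks, correlate the residuals.
partial_spearman_oracle <- function(x, y, Z = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (!is.null(Z)) {
    D <- cbind(1, apply(as.matrix(Z), 2, rank))
    H <- D %*% solve(t(D) %*% D) %*% t(D)
    rx <- rx - H %*% rx
    ry <- ry - H %*% ry
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# Step-up BH oracle by direct enumeration of the rejection threshold.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_ok <- which(ps <= seq_len(m) * q / m)
  if (length(k_ok) == 0L) return(rep(FALSE, m))
  p[seq_len(m)] <= ps[max(k_ok)] & seq_len(m) > 0  # reject all p <= p_(k*)
}
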