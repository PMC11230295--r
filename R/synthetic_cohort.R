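#' Synthetic cohort specification
#'
#' Parameters of the synthetic resting-state cohort generator. Defaults
#' emulate the statistical structure the downstream analysis assumes:
#' three groups with group-dependent motion (median mean-FD near 0.16, 0.20
#' and 0.19 mm), four 5-minute runs of 375 frames (TR 0.8 s), 352 ROIs,
#' motion-inflated connectivity, and a planted rank correlation between one
#' designated "signal edge" and the first behavior score.
#'
#' @param n_per_group participants per group (scalar recycled, or one value
#'   per group label).
#' @param group_labels unique group names (default three generic groups).
#' @param fd_median_per_group target group medians of framewise displacement
#'   in mm (defaults 0.16, 0.20, 0.19).
#' @param fd_dispersion log-scale SD of the FD baseline, applied both
#'   between participants and frame-to-frame (default 0.35). Zero gives a
#'   constant FD at the group median.
#' @param fd_ar1 lag-1 autocorrelation of the log-FD baseline (default
#'   0.85). Temporal persistence makes supra-threshold excursions
#'   contiguous, as in real traces, so censoring removes blocks rather than
#'   scattering single-frame windows across the run.
#' @param burst_rate expected number of supra-threshold motion bursts per run
#'   (default 2).
#' @param burst_len_mean mean burst length in frames (geometric, default 3).
#' @param burst_amp range of burst FD amplitudes in mm (default 0.30-0.60,
#'   above the 0.20 mm scrubbing threshold).
#' @param n_runs runs per participant, at most 4 (default 4).
#' @param frames_per_run frames per run (default 375).
#' @param n_rois number of ROIs (default 352; reduce for tests).
#' @param rho_true target population Spearman correlation between the signal
#'   edge and the behaviors. Length 1 (applied to the first behavior, with
#'   half that for the second and 0 for the third) or length 3.
#' @param motion_inflation coefficient coupling per-frame FD to a global
#'   artifact component shared by all ROIs (default 0.5; 0 disables the
#'   motion confound).
#' @param edge_base_r population-median true correlation of the signal ROI
#'   pair (default 0.3).
#' @param edge_z_sd between-participant SD of the signal-edge Fisher z
#'   (default 0.3).
#' @param covariate_effects list with `sex` and `mean_fd`: additive effects
#'   on the behavior latent, in latent-SD units (per unit of the binary sex
#'   code and per SD of cohort mean FD).
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100L,
                        group_labels = c("groupA", "groupB", "groupC"),
                        fd_median_per_group = c(0.16, 0.20, 0.19),
                        fd_dispersion = 0.35,
                        fd_ar1 = 0.85,
                        burst_rate = 2,
                        burst_len_mean = 3,
                        burst_amp = c(0.30, 0.60),
                        n_runs = 4L,
                        frames_per_run = 375L,
                        n_rois = 352L,
                        rho_true = 0.10,
                        motion_inflation = 0.5,
                        edge_base_r = 0.3,
                        edge_z_sd = 0.3,
                        covariate_effects = list(sex = 0.3, mean_fd = -0.3),
                        seed = 1L) {
  if (anyDuplicated(group_labels)) stop_mfc("group labels must be unique")
  n_groups <- length(group_labels)
  n_per_group <- rep_len(as.integer(n_per_group), n_groups)
  fd_median_per_group <- rep_len(fd_median_per_group, n_groups)
  if (any(n_per_group <= 0L)) stop_mfc("n_per_group must be positive")
  if (any(fd_median_per_group <= 0)) stop_mfc("FD medians must be positive")
  if (fd_dispersion < 0) stop_mfc("fd_dispersion must be non-negative")
  if (abs(fd_ar1) >= 1) stop_mfc("|fd_ar1| must be < 1")
  if (n_runs < 1L || n_runs > 4L) stop_mfc("n_runs must be in 1..4")
  if (frames_per_run < 2L) stop_mfc("frames_per_run must be at least 2")
  if (n_rois < 2L) stop_mfc("need at least 2 ROIs")
  if (length(rho_true) == 1L) rho_true <- c(rho_true, rho_true / 2, 0)
  if (length(rho_true) != 3L) stop_mfc("rho_true must have length 1 or 3")
  if (any(abs(rho_true) >= 1)) stop_mfc("|rho_true| must be < 1")
  if (abs(edge_base_r) >= 1) stop_mfc("|edge_base_r| must be < 1")
  structure(list(n_per_group = n_per_group, group_labels = group_labels,
                 fd_median_per_group = fd_median_per_group,
                 fd_dispersion = fd_dispersion, fd_ar1 = fd_ar1,
                 burst_rate = burst_rate,
                 burst_len_mean = burst_len_mean, burst_amp = burst_amp,
                 n_runs = as.integer(n_runs),
                 frames_per_run = as.integer(frames_per_run),
                 n_rois = as.integer(n_rois), rho_true = rho_true,
                 motion_inflation = motion_inflation,
                 edge_base_r = edge_base_r, edge_z_sd = edge_z_sd,
                 covariate_effects = covariate_effects,
                 signal_edge = c(1L, 2L),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %s participants (%s), %d x %d frames, %d ROIs, rho_true = %s, seed %d\n",
    paste(x$n_per_group, collapse = "+"),
    paste(x$group_labels, collapse = "/"),
    x$n_runs, x$frames_per_run, x$n_rois,
    paste(signif(x$rho_true, 2), collapse = "/"), x$seed))
  invisible(x)
}

# Target per-frame FD for one participant across runs (first frame of each
# run = 0). `z` is the participant's motion level on the standard-normal
# scale. The supra-threshold burst frames are drawn first; the log-normal
# baseline is then calibrated against the realized burst mask so that the
# expected mean FD over the non-first frames equals
# fd_median * exp(fd_dispersion * z) - hence the group median of mean FD
# matches the configured target (up to the per-run leading zero).
generate_fd_target <- function(spec, fd_median, z) {
  target <- fd_median * exp(spec$fd_dispersion * z)
  tpr <- spec$frames_per_run
  fd <- numeric(0)
  run <- integer(0)
  for (r in seq_len(spec$n_runs)) {
    burst <- rep(FALSE, tpr)
    amps <- numeric(tpr)
    n_burst <- stats::rpois(1L, spec$burst_rate)
    if (n_burst > 0L && tpr > 2L) {
      starts <- sample(2:tpr, min(n_burst, tpr - 1L))
      for (s in starts) {
        len <- 1L + stats::rgeom(1L, prob = 1 / spec$burst_len_mean)
        idx <- s:min(s + len - 1L, tpr)
        burst[idx] <- TRUE
      }
      amps[burst] <- stats::runif(sum(burst), spec$burst_amp[1L],
                                  spec$burst_amp[2L])
    }
    burst[1L] <- FALSE
    m <- (tpr - 1L) - sum(burst)  # baseline frames beyond the first
    mu <- (target * (tpr - 1L) - sum(amps)) /
      max(m * exp(spec$fd_dispersion^2 / 2), 1)
    if (mu <= 0) mu <- 1e-4  # burst-dominated run: floor the baseline
    # AR(1) log-FD baseline with stationary unit-variance innovations:
    # the marginal stays log-normal(log mu, fd_dispersion), so the mean
    # calibration is unaffected by the temporal persistence.
    a <- stats::rnorm(tpr)
    if (spec$fd_ar1 != 0 && tpr > 1L) {
      phi <- spec$fd_ar1
      for (t in 2:tpr) a[t] <- phi * a[t - 1L] + sqrt(1 - phi^2) * a[t]
    }
    base <- exp(log(mu) + spec$fd_dispersion * a)
    base[burst] <- amps[burst]
    base[1L] <- 0
    fd <- c(fd, base)
    run <- c(run, rep(r, tpr))
  }
  fd_trace(fd, run)
}

#' Generate a rigid-body motion trace for one participant
#'
#' Produces per-run 6-parameter realignment traces whose derived framewise
#' displacement follows a calibrated log-normal baseline (group-specific
#' median) with sparse supra-threshold bursts. Per-frame parameter increments
#' are drawn with random sign and a random split over the six parameters, and
#' scaled so the weighted absolute sum (translations in mm, rotations times
#' the 50 mm head radius) equals the target FD exactly - so FD computed
#' downstream matches the generator's intent.
#'
#' @param spec a [cohort_spec].
#' @param group one of `spec$group_labels`.
#' @param seed integer seed (deterministic trace given spec + seed).
#' @param head_radius head radius in mm (default 50).
#' @return rigid-body trace data frame (columns tx..rz, run).
#' @export
generate_motion_trace <- function(spec, group, seed, head_radius = 50) {
  gi <- match(group, spec$group_labels)
  if (is.na(gi)) stop_mfc("unknown group label: '", group, "'")
  with_seed(seed, {
    z <- stats::rnorm(1L)
    target <- generate_fd_target(spec, spec$fd_median_per_group[gi], z)
    n <- length(target$fd)
    p <- matrix(0, nrow = n, ncol = 6L)
    for (r in unique(target$run)) {
      sel <- which(target$run == r)
      nf <- length(sel)
      inc <- matrix(0, nrow = nf, ncol = 6L)
      if (nf > 1L) {
        w <- matrix(stats::rexp(6L * (nf - 1L)), ncol = 6L)
        w <- w / rowSums(w)
        s <- matrix(sample(c(-1, 1), 6L * (nf - 1L), replace = TRUE),
                    ncol = 6L)
        d <- s * w * target$fd[sel[-1L]]
        d[, 4:6] <- d[, 4:6] / head_radius
        inc[-1L, ] <- d
      }
      p[sel, ] <- apply(inc, 2L, cumsum)
    }
    out <- as.data.frame(p)
    names(out) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    out$run <- target$run
    out
  })
}

#' Generate a parcellated BOLD timeseries for one participant
#'
#' Latent Gaussian timeseries with unit-variance ROIs, independent except for
#' the designated signal ROI pair whose true correlation is `edge_corr`, plus
#' a global artifact component with per-frame amplitude
#' `motion_inflation x FD(t)` shared by all ROIs - so high-FD frames inflate
#' every pairwise correlation.
#'
#' @param spec a [cohort_spec].
#' @param fd an [fd_trace] with `n_runs x frames_per_run` frames.
#' @param edge_corr true correlation of the signal ROI pair for this
#'   participant (default `spec$edge_base_r`).
#' @param seed integer seed.
#' @return numeric matrix, frames x `spec$n_rois`.
#' @export
generate_timeseries <- function(spec, fd, edge_corr = spec$edge_base_r,
                                seed = spec$seed) {
  fdv <- if (inherits(fd, "fd_trace")) fd$fd else as.numeric(fd)
  n <- spec$n_runs * spec$frames_per_run
  if (length(fdv) != n)
    stop_mfc("FD trace length ", length(fdv), " != total frames ", n)
  if (any(!is.finite(fdv))) stop_mfc("non-finite FD values")
  if (abs(edge_corr) >= 1) stop_mfc("|edge_corr| must be < 1")
  p <- spec$n_rois
  i1 <- spec$signal_edge[1L]; i2 <- spec$signal_edge[2L]
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    x[, i2] <- edge_corr * x[, i1] + sqrt(1 - edge_corr^2) * x[, i2]
    if (spec$motion_inflation != 0) {
      art <- spec$motion_inflation * fdv * stats::rnorm(n)
      x <- x + art  # recycled column-wise: same artifact for every ROI
    }
    x
  })
}

#' Generate behavior scores for a cohort
#'
#' Builds three T-scaled behavior scores from the participants' signal-edge
#' latent values by a Gaussian copula: the latent behavior is
#' `rho_z * u + sqrt(1 - rho_z^2) * noise` with
#' `rho_z = 2 sin(pi rho_true / 6)`, so the population Spearman correlation
#' between the true signal-edge connectivity (any monotone function of `u`)
#' and the behavior equals `rho_true`. Sex and mean-FD effects are then added
#' on the latent scale and each score is affinely rescaled to mean 50, SD 10.
#'
#' @param spec a [cohort_spec].
#' @param signal_edge_score standard-normal per-participant latent driving
#'   the signal edge.
#' @param sex binary covariate per participant (0/1).
#' @param mean_fd mean FD per participant (mm).
#' @param seed integer seed.
#' @return data frame with columns `nih_tbx`, `cbcl_ext`, `cbcl_int`.
#' @export
generate_behavior <- function(spec, signal_edge_score, sex, mean_fd,
                              seed = spec$seed) {
  if (any(abs(spec$rho_true) >= 1)) stop_mfc("|rho_true| must be < 1")
  u <- signal_edge_score
  n <- length(u)
  ce <- spec$covariate_effects
  fd_c <- if (stats::sd(mean_fd) > 0) as.numeric(scale(mean_fd))
          else rep(0, n)
  with_seed(seed, {
    out <- lapply(spec$rho_true, function(rho) {
      rho_z <- 2 * sin(pi * rho / 6)
      b <- rho_z * u + sqrt(1 - rho_z^2) * stats::rnorm(n)
      b <- b + ce$sex * (sex - mean(sex)) + ce$mean_fd * fd_c
      if (stats::sd(b) > 0) 50 + 10 * (b - mean(b)) / stats::sd(b)
      else rep(50, n)
    })
  })
  stats::setNames(as.data.frame(out), c("nih_tbx", "cbcl_ext", "cbcl_int"))
}

# Cohort-level frame: group assignment, sex, and the standard-normal
# signal-edge latent per participant, drawn deterministically from the
# master seed.
cohort_frame <- function(spec) {
  n <- sum(spec$n_per_group)
  group <- rep(spec$group_labels, spec$n_per_group)
  with_seed(derive_seed(spec$seed, 1L), {
    data.frame(id = sprintf("sub-%05d", seq_len(n)),
               group = group,
               sex = stats::rbinom(n, 1L, 0.5),
               g = stats::rnorm(n),
               stringsAsFactors = FALSE)
  })
}

# True signal-edge correlation for a participant latent g: Fisher-z linear
# in g, bounded back through tanh.
edge_corr_from_latent <- function(spec, g) {
  tanh(atanh(spec$edge_base_r) + spec$edge_z_sd * g)
}

# Generate one participant's motion trace, FD and (optionally) timeseries.
generate_participant <- function(spec, frame_row, keep_timeseries = TRUE) {
  seed_m <- derive_seed(spec$seed, 2L, frame_row$row)
  seed_t <- derive_seed(spec$seed, 3L, frame_row$row)
  trace <- generate_motion_trace(spec, frame_row$group, seed_m)
  fd <- framewise_displacement(trace)
  r_i <- edge_corr_from_latent(spec, frame_row$g)
  ts <- generate_timeseries(spec, fd, edge_corr = r_i, seed = seed_t)
  list(id = frame_row$id, group = frame_row$group, sex = frame_row$sex,
       trace = trace, fd = fd,
       ts = if (keep_timeseries) ts else NULL,
       mean_fd = mean_fd(fd), edge_corr = r_i)
}

#' Generate a synthetic cohort
#'
#' Assembles a full cohort from the motion, timeseries and behavior
#' generators: per participant a rigid-body trace, FD trace, parcellated
#' timeseries and mean FD; cohort-level behavior scores with sex and mean-FD
#' covariate structure; and a ground-truth record (signal edge, planted
#' correlations, per-participant latent values, seed) sufficient to
#' regenerate the cohort bit-identically.
#'
#' @param spec a [cohort_spec].
#' @param keep_timeseries store each participant's timeseries matrix
#'   (default TRUE; set FALSE to save memory in large cohorts, e.g. when only
#'   connectivity is needed via [compute_method_edges()]).
#' @return object of class `synthetic_cohort`: list with `participants`,
#'   `behavior` (data frame: id, group, sex, mean_fd, nih_tbx, cbcl_ext,
#'   cbcl_int), `truth`, `spec`.
#' @export
generate_cohort <- function(spec, keep_timeseries = TRUE) {
  frame <- cohort_frame(spec)
  frame$row <- seq_len(nrow(frame))
  parts <- lapply(seq_len(nrow(frame)), function(i) {
    generate_participant(spec, frame[i, ], keep_timeseries)
  })
  mfd <- vapply(parts, `[[`, numeric(1), "mean_fd")
  beh <- generate_behavior(spec, frame$g, frame$sex, mfd,
                           seed = derive_seed(spec$seed, 4L))
  behavior <- cbind(frame[c("id", "group", "sex")],
                    data.frame(mean_fd = mfd), beh)
  truth <- list(signal_edge = spec$signal_edge,
                signal_edge_id = signal_edge_id(spec),
                rho_true = spec$rho_true,
                edge_corr = vapply(parts, `[[`, numeric(1), "edge_corr"),
                latent = frame$g,
                seed = spec$seed)
  structure(list(participants = parts, behavior = behavior,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %d ROIs, signal edge %d (ROIs %d-%d)\n",
              length(x$participants), x$spec$n_rois,
              x$truth$signal_edge_id,
              x$truth$signal_edge[1L], x$truth$signal_edge[2L]))
  invisible(x)
}

#' Canonical edge id of the planted signal edge
#'
#' @param spec a [cohort_spec].
#' @return integer edge id in the upper-triangle edge order.
#' @export
signal_edge_id <- function(spec) {
  map <- edge_index_map(spec$n_rois)
  map$edge_id[map$roi_i == spec$signal_edge[1L] &
              map$roi_j == spec$signal_edge[2L]]
}
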