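#' Logarithmically spaced sample-size grid
#'
#' k sizes equally spaced in log10 between `n_min` and `n_max`, rounded to
#' the nearest integer, endpoints exact.
#'
#' @param n_min smallest sample size (default 25).
#' @param n_max largest sample size (the group maximum).
#' @param k number of sizes (default 11).
#' @return object of class `sample_size_grid`: list with `sizes`, `n_min`,
#'   `n_max`, `k`.
#' @export
#' @examples
#' log_spaced_sizes(25, 2266)$sizes
#' # 25 39 62 97 152 238 374 586 920 1444 2266
log_spaced_sizes <- function(n_min = 25L, n_max, k = 11L) {
  if (n_min >= n_max) stop_mfc("n_min must be smaller than n_max")
  if (k < 2L) stop_mfc("k must be at least 2")
  sizes <- round(10^seq(log10(n_min), log10(n_max), length.out = k))
  sizes[1L] <- n_min
  sizes[k] <- n_max
  structure(list(sizes = as.integer(sizes), n_min = as.integer(n_min),
                 n_max = as.integer(n_max), k = as.integer(k)),
            class = "sample_size_grid")
}

#' Number of correlation evaluations a reproducibility design schedules
#'
#' The full design computes one partial correlation per (grid size,
#' participant bootstrap) pair, times the number of timepoint-bootstrap
#' replicates for the bagged method. The count is enumerated, not executed:
#' an 11-size grid with 500 participant bootstraps schedules 5,500
#' evaluations for the standard and motion-ordered methods, and
#' 11 x 500 x 500 = 2,750,000 for the full-scale bagged design.
#'
#' @param k number of grid sizes.
#' @param B participant bootstraps per size.
#' @param bag_B timepoint-bootstrap replicates per participant (default 1,
#'   i.e. an unbagged method).
#' @return the evaluation count.
#' @export
#' @examples
#' schedule_evaluations(11, 500)        # 5500
#' schedule_evaluations(11, 500, 500)   # 2750000
schedule_evaluations <- function(k, B, bag_B = 1L) {
  as.double(k) * as.double(B) * as.double(bag_B)
}

# Shared subsample draws: for each grid size, a B x N matrix of participant
# row indices drawn without replacement. Drawn once so that method
# comparisons are paired at every (size, iteration).
make_subsample_draws <- function(n_participants, grid, B, seed) {
  lapply(seq_along(grid$sizes), function(gi) {
    N <- grid$sizes[gi]
    if (N > n_participants)
      stop_mfc("grid size ", N, " exceeds cohort size ", n_participants)
    t(vapply(seq_len(B), function(b) {
      with_seed(derive_seed(seed, gi, b),
                sample.int(n_participants, N, replace = FALSE))
    }, integer(N)))
  })
}

# Mean partial-Spearman Rs of each column of `xmat` against y given
# covariates Z, over the rows `idx`. Covariate/behavior ranking and
# residualization are done once per draw; each column is ranked and
# projected against the same QR factorization.
rs_for_draw <- function(xmat, y, Z, idx) {
  ys <- rank(y[idx])
  if (!is.null(Z)) {
    qrz <- qr(cbind(1, apply(Z[idx, , drop = FALSE], 2L, rank)))
    ys <- qr.resid(qrz, ys)
  } else {
    qrz <- NULL
    ys <- ys - mean(ys)
  }
  yn <- sqrt(sum(ys^2))
  vals <- vapply(seq_len(ncol(xmat)), function(cc) {
    xs <- rank(xmat[idx, cc])
    xs <- if (is.null(qrz)) xs - mean(xs) else qr.resid(qrz, xs)
    sn <- sqrt(sum(xs^2))
    if (sn == 0 || yn == 0) return(NA_real_)
    sum(xs * ys) / (sn * yn)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Bootstrap sampling-variability curve for a brain-behavior association
#'
#' For each sample size N on the grid, draws `B` subsamples of N participants
#' without replacement, computes the partial Spearman Rs between the edge
#' value and the behavior in each subsample, and records the mean, percentile
#' 95% CI (2.5/97.5), minimum and maximum. At the full cohort size every
#' draw is the same participant set, so the CI width there is exactly 0.
#'
#' @param edge numeric vector of edge values per participant, or a matrix
#'   (participants x bootstrap replicates) for the bagged method, in which
#'   case the per-draw statistic is the mean Rs across replicate columns.
#' @param behavior data frame with the behavior and covariate columns.
#' @param behavior_col behavior column name.
#' @param covariate_cols covariate column names (default sex + mean FD).
#' @param grid a [log_spaced_sizes()] grid.
#' @param B subsample draws per size (default 500).
#' @param seed integer seed.
#' @param method label stored with the curve.
#' @param draws optional precomputed draws from shared sampling (used by
#'   [run_reproducibility()] for paired method comparison).
#' @return object of class `repro_curve`: list with `summary` (data frame:
#'   method, n, mean, ci_low, ci_high, min, max), `draws` (B x k matrix of
#'   per-draw Rs), `B`, `seed`, `n_evaluations`.
#' @export
bootstrap_curve <- function(edge, behavior, behavior_col,
                            covariate_cols = c("sex", "mean_fd"),
                            grid, B = 500L, seed = 1L,
                            method = "standard", draws = NULL) {
  xmat <- if (is.matrix(edge)) edge else matrix(edge, ncol = 1L)
  if (nrow(xmat) != nrow(behavior))
    stop_mfc("edge values and behavior table differ in length")
  y <- behavior[[behavior_col]]
  Z <- encode_covariates(behavior, covariate_cols)
  if (is.null(draws))
    draws <- make_subsample_draws(nrow(xmat), grid, B, seed)
  k <- length(grid$sizes)
  rs_draws <- matrix(NA_real_, nrow = B, ncol = k)
  for (gi in seq_len(k)) {
    for (b in seq_len(B)) {
      rs_draws[b, gi] <- rs_for_draw(xmat, y, Z, draws[[gi]][b, ])
    }
  }
  summary <- data.frame(
    method = method,
    n = grid$sizes,
    mean = colMeans(rs_draws),
    ci_low = apply(rs_draws, 2L, stats::quantile, probs = 0.025),
    ci_high = apply(rs_draws, 2L, stats::quantile, probs = 0.975),
    min = apply(rs_draws, 2L, min),
    max = apply(rs_draws, 2L, max))
  rownames(summary) <- NULL
  structure(list(summary = summary, draws = rs_draws, method = method,
                 B = B, seed = seed,
                 n_evaluations = schedule_evaluations(k, B, ncol(xmat))),
            class = "repro_curve")
}

#' @export
print.repro_curve <- function(x, ...) {
  cat(sprintf("<repro_curve> method = %s, %d sizes x B = %d (%d evaluations)\n",
              x$method, nrow(x$summary), x$B, x$n_evaluations))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Area under the CI-width curve
#'
#' Trapezoidal area of the 95% CI width (ci_high - ci_low) against sample
#' size N, in Rs-width x participants units.
#'
#' @param curve a `repro_curve`, or a data frame with columns `n`, `ci_low`,
#'   `ci_high`.
#' @return the area (non-negative scalar).
#' @export
curve_auc <- function(curve) {
  s <- if (inherits(curve, "repro_curve")) curve$summary else curve
  if (nrow(s) < 2L) stop_mfc("need at least 2 sizes")
  if (is.unsorted(s$n, strictly = TRUE)) stop_mfc("sizes must be increasing")
  w <- s$ci_high - s$ci_low
  sum(diff(s$n) * (head(w, -1L) + tail(w, -1L)) / 2)
}

#' AUC rate of change between methods
#'
#' Percent change in CI-width AUC relative to the standard method. The
#' unsigned `delta_percent` is the reported \eqn{\Delta}AUC; `signed_percent`
#' is positive when the comparison method's CIs are tighter (smaller AUC)
#' than the standard method's.
#'
#' @param auc_standard AUC of the standard method (> 0).
#' @param auc_method AUC of the comparison method.
#' @return list with `delta_percent` and `signed_percent`.
#' @export
#' @examples
#' delta_auc(250.01, 250.55)$delta_percent  # 0.22 (to 2 decimals)
delta_auc <- function(auc_standard, auc_method) {
  if (auc_standard <= 0) stop_mfc("standard AUC must be positive")
  list(delta_percent = 100 * abs(auc_method - auc_standard) / auc_standard,
       signed_percent = 100 * (auc_standard - auc_method) / auc_standard)
}

#' Reproducibility curves and AUC comparison across methods
#'
#' Runs [bootstrap_curve()] for each method with shared subsample draws (so
#' the comparison is paired at every size and iteration), then computes the
#' CI-width AUC per method and \eqn{\Delta}AUC against the standard method.
#'
#' @param edges named list of per-method edge values (vector per participant,
#'   or participants x replicates matrix for the bagged method); must contain
#'   a `standard` entry and all entries must cover the same participants.
#' @param behavior behavior/covariate data frame.
#' @param behavior_col behavior column name.
#' @param covariate_cols covariate column names.
#' @param grid a [log_spaced_sizes()] grid.
#' @param B subsample draws per size (default 500).
#' @param seed integer seed.
#' @return list with `curves` (named list of `repro_curve`), `auc` (data
#'   frame: method, auc, delta_percent, signed_percent), `ledger` (data
#'   frame: method, n_evaluations).
#' @export
run_reproducibility <- function(edges, behavior, behavior_col,
                                covariate_cols = c("sex", "mean_fd"),
                                grid, B = 500L, seed = 1L) {
  if (!"standard" %in% names(edges))
    stop_mfc("`edges` must contain a 'standard' entry")
  n_per <- vapply(edges, NROW, integer(1))
  if (length(unique(n_per)) != 1L)
    stop_mfc("participant sets differ across methods")
  draws <- make_subsample_draws(n_per[[1L]], grid, B, seed)
  curves <- lapply(names(edges), function(m) {
    bootstrap_curve(edges[[m]], behavior, behavior_col, covariate_cols,
                    grid, B = B, seed = seed, method = m, draws = draws)
  })
  names(curves) <- names(edges)
  aucs <- vapply(curves, curve_auc, numeric(1))
  deltas <- lapply(aucs, function(a) delta_auc(aucs[["standard"]], a))
  auc_tab <- data.frame(
    method = names(curves),
    auc = unname(aucs),
    delta_percent = vapply(deltas, `[[`, numeric(1), "delta_percent"),
    signed_percent = vapply(deltas, `[[`, numeric(1), "signed_percent"))
  rownames(auc_tab) <- NULL
  ledger <- data.frame(
    method = names(curves),
    n_evaluations = vapply(curves, `[[`, numeric(1), "n_evaluations"))
  rownames(ledger) <- NULL
  list(curves = curves, auc = auc_tab, ledger = ledger)
}

#' Plot reproducibility curves
#'
#' Mean Rs with 95% CI ribbon and min/max envelope as a function of sample
#' size, one panel style per method. Requires ggplot2.
#'
#' @param curves named list of `repro_curve` objects (e.g. from
#'   [run_reproducibility()]`$curves`).
#' @return a ggplot object.
#' @export
plot_repro_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_mfc("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(curves, `[[`, "summary"))
  ggplot2::ggplot(df, ggplot2::aes(x = n, y = mean,
                                   colour = method, fill = method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = min, ymax = max),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sample size N", y = "brain-behavior Rs")
}
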