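#' Edge index map for the upper-triangle edge order
#'
#' Edges are stored in canonical row-major upper-triangle order: (1,2), (1,3),
#' ..., (1,P), (2,3), ..., (P-1,P). For P ROIs there are P(P-1)/2 edges.
#'
#' @param n_roi number of ROIs (P >= 2).
#' @return data frame with columns `edge_id`, `roi_i`, `roi_j` (roi_i < roi_j).
#' @export
#' @examples
#' nrow(edge_index_map(352))  # 61776
edge_index_map <- function(n_roi) {
  stopifnot(n_roi >= 2)
  i <- rep(seq_len(n_roi - 1L), times = (n_roi - 1L):1L)
  j <- unlist(lapply(seq_len(n_roi - 1L), function(k) (k + 1L):n_roi))
  data.frame(edge_id = seq_along(i), roi_i = i, roi_j = j)
}

# row-major upper triangle of a symmetric matrix, matching edge_index_map
upper_tri_vec <- function(m) t(m)[lower.tri(m)]

#' Fisher z transform of a correlation
#'
#' z = arctanh(r). Correlations with |r| = 1 are clipped to 1 - 1e-7 before
#' the transform; the number of clipped values is attached as attribute
#' `n_clipped` (with a warning) so degenerate edges remain auditable.
#'
#' @param r correlation value(s), |r| <= 1.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12))
    stop_mfc("correlations must be finite with |r| <= 1")
  eps <- 1e-7
  clip <- abs(r) >= 1 - .Machine$double.eps
  if (any(clip)) {
    r[clip] <- sign(r[clip]) * (1 - eps)
    warning(sum(clip), " correlation(s) at |r| = 1 clipped before arctanh",
            call. = FALSE)
  }
  z <- atanh(pmin(pmax(r, -1 + eps), 1 - eps))
  if (any(clip)) attr(z, "n_clipped") <- sum(clip)
  z
}

#' Functional connectivity edge vector from selected frames
#'
#' Pearson correlation between every ROI pair over exactly the selected
#' frames, Fisher z transformed, vectorized in canonical upper-triangle order.
#'
#' @param ts numeric matrix, frames x ROIs (P >= 2).
#' @param frame_indices integer frame indices to use (default: all frames).
#' @return numeric edge vector of length P(P-1)/2 with attributes `n_roi` and
#'   `n_frames`.
#' @export
fc_from_frames <- function(ts, frame_indices = seq_len(nrow(ts))) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2L) stop_mfc("need at least 2 ROIs")
  if (length(frame_indices) < 3L)
    stop_mfc("need at least 3 frames to estimate correlations, got ",
             length(frame_indices))
  x <- ts[frame_indices, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop_mfc("constant ROI over the selected frames: column ",
             which(sds == 0)[1L])
  z <- suppressWarnings(fisher_z(upper_tri_vec(stats::cor(x))))
  structure(as.numeric(z), n_roi = ncol(ts), n_frames = length(frame_indices))
}

#' Standard functional connectivity (all frames)
#'
#' The conventional estimator: Pearson + Fisher z over the full concatenated
#' timeseries.
#'
#' @param ts numeric matrix, frames x ROIs.
#' @return edge vector, as [fc_from_frames()].
#' @export
standard_fc <- function(ts) fc_from_frames(ts)

#' Motion-ordered functional connectivity
#'
#' Connectivity from exactly the `min_tp` least motion-corrupted retained
#' frames (the minTP-matched set).
#'
#' @param ts numeric matrix, frames x ROIs.
#' @param censor a `censor_result` from [scrub()].
#' @param cfg a [censor_config].
#' @return edge vector, as [fc_from_frames()].
#' @export
motion_ordered_fc <- function(ts, censor, cfg = censor_config()) {
  sel <- select_min_tp(rank_by_motion(censor), cfg)
  if (!sel$eligible)
    stop_mfc("participant ineligible: ", sel$n_retained,
             " retained frames < min_tp = ", cfg$min_tp)
  fc_from_frames(ts, sel$frames)
}

#' Bagged functional connectivity
#'
#' Draws `B` bootstrap samples of size `min_tp` with replacement from the
#' minTP-matched frame set and computes a connectivity edge vector per
#' replicate, plus their elementwise mean. Per-replicate RNG streams are
#' derived from `(seed, replicate)` so results are independent of evaluation
#' order. Replicates in which resampling produces a constant ROI are flagged
#' and excluded from the mean (count reported in `n_degenerate`).
#'
#' @param ts numeric matrix, frames x ROIs.
#' @param censor a `censor_result` from [scrub()].
#' @param cfg a [censor_config].
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param identity_resample testing flag: when TRUE every replicate uses the
#'   unresampled minTP frame set.
#' @return object of class `bagged_fc`: list with `replicates` (B x n_edges
#'   matrix), `mean` (edge vector averaged over valid replicates), `B`,
#'   `seed`, `n_degenerate`.
#' @export
bagged_fc <- function(ts, censor, cfg = censor_config(), B = 500L,
                      seed = 1L, identity_resample = FALSE) {
  sel <- select_min_tp(rank_by_motion(censor), cfg)
  if (!sel$eligible)
    stop_mfc("participant ineligible: ", sel$n_retained,
             " retained frames < min_tp = ", cfg$min_tp)
  frames <- sel$frames
  n_edges <- ncol(ts) * (ncol(ts) - 1L) / 2L
  reps <- matrix(NA_real_, nrow = B, ncol = n_edges)
  ok <- rep(TRUE, B)
  for (b in seq_len(B)) {
    draw <- if (identity_resample) frames else
      with_seed(derive_seed(seed, b),
                sample(frames, length(frames), replace = TRUE))
    v <- tryCatch(fc_from_frames(ts, draw), error = function(e) NULL)
    if (is.null(v)) ok[b] <- FALSE else reps[b, ] <- v
  }
  structure(list(replicates = reps,
                 mean = colMeans(reps[ok, , drop = FALSE]),
                 B = B, seed = seed,
                 n_degenerate = sum(!ok)),
            class = "bagged_fc")
}

#' @export
print.bagged_fc <- function(x, ...) {
  cat(sprintf("<bagged_fc> B = %d replicates, %d edges, %d degenerate\n",
              x$B, ncol(x$replicates), x$n_degenerate))
  invisible(x)
}

#' Write an edge index map to CSV
#'
#' @param n_roi number of ROIs.
#' @param path output CSV path.
#' @export
write_edge_map <- function(n_roi, path) {
  utils::write.table(edge_index_map(n_roi), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
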