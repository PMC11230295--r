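#' Censoring configuration
#'
#' Parameters of the scrubbing and minTP-matching rules. A frame is flagged
#' when its FD strictly exceeds `fd_threshold`; frames exactly at threshold
#' are retained. For every flagged frame, `n_before` preceding and `n_after`
#' succeeding frames of the same run are censored as well.
#'
#' @param fd_threshold FD flagging threshold in mm (default 0.20).
#' @param n_before frames censored before each flagged frame (default 1).
#' @param n_after frames censored after each flagged frame (default 2).
#' @param min_tp number of least-motion-corrupted frames each participant
#'   must contribute to be eligible (default 100).
#' @return An object of class `censor_config`.
#' @export
censor_config <- function(fd_threshold = 0.20, n_before = 1L, n_after = 2L,
                          min_tp = 100L) {
  stopifnot(fd_threshold > 0, n_before >= 0, n_after >= 0, min_tp >= 1)
  structure(list(fd_threshold = fd_threshold,
                 n_before = as.integer(n_before),
                 n_after = as.integer(n_after),
                 min_tp = as.integer(min_tp)),
            class = "censor_config")
}

#' Scrub motion-corrupted frames
#'
#' Flags every frame with FD > threshold and censors it together with
#' `n_before` preceding and `n_after` succeeding frames. Censor windows are
#' clipped at run boundaries and overlapping windows form a union.
#'
#' @param fd an [fd_trace].
#' @param cfg a [censor_config].
#' @return An object of class `censor_result`: list with `keep_mask` (logical
#'   per frame), `retained_indices` (ascending frame indices), `retained_fd`,
#'   `n_retained`, and the `config` used.
#' @export
#' @examples
#' fd <- fd_trace(c(0, .05, .50, .05, .05, .05, .05, .05, .05, .05))
#' res <- scrub(fd, censor_config())
#' which(!res$keep_mask)  # frames 2,3,4,5: one preceding, T, two succeeding
scrub <- function(fd, cfg = censor_config()) {
  stopifnot(inherits(fd, "fd_trace"), inherits(cfg, "censor_config"))
  n <- length(fd$fd)
  if (n == 0L) stop_mfc("empty FD trace")
  keep <- rep(TRUE, n)
  for (r in unique(fd$run)) {
    sel <- which(fd$run == r)
    flagged <- sel[fd$fd[sel] > cfg$fd_threshold]
    for (t in flagged) {
      lo <- max(min(sel), t - cfg$n_before)
      hi <- min(max(sel), t + cfg$n_after)
      keep[lo:hi] <- FALSE
    }
  }
  retained <- which(keep)
  structure(list(keep_mask = keep,
                 retained_indices = retained,
                 retained_fd = fd$fd[retained],
                 n_retained = length(retained),
                 run = fd$run,
                 config = cfg),
            class = "censor_result")
}

#' @export
print.censor_result <- function(x, ...) {
  cat(sprintf("<censor_result> %d/%d frames retained (FD <= %.2f mm)\n",
              x$n_retained, length(x$keep_mask), x$config$fd_threshold))
  invisible(x)
}

#' Rank retained frames by motion
#'
#' Orders the retained frames by ascending FD; ties are broken by earlier
#' frame index (stable sort).
#'
#' @param res a `censor_result` from [scrub()].
#' @return integer vector of frame indices, lowest FD first.
#' @export
rank_by_motion <- function(res) {
  stopifnot(inherits(res, "censor_result"))
  if (res$n_retained < 1L) stop_mfc("no retained frames to rank")
  res$retained_indices[order(res$retained_fd, res$retained_indices)]
}

#' Select the minTP-matched frame set
#'
#' Takes the `min_tp` lowest-FD frames from the motion-ranked retained set and
#' returns them in ascending temporal order. Participants with fewer retained
#' frames than `min_tp` are flagged ineligible rather than raising an error.
#'
#' @param ordered integer frame indices from [rank_by_motion()].
#' @param cfg a [censor_config] (only `min_tp` is used).
#' @return list with `eligible` (logical), `frames` (sorted frame indices, or
#'   `integer(0)` when ineligible) and `n_retained`.
#' @export
select_min_tp <- function(ordered, cfg = censor_config()) {
  n <- length(ordered)
  if (n < cfg$min_tp) {
    return(list(eligible = FALSE, frames = integer(0), n_retained = n))
  }
  list(eligible = TRUE,
       frames = sort(ordered[seq_len(cfg$min_tp)]),
       n_retained = n)
}

#' Participant eligibility under mean-FD cutoff or minTP rule
#'
#' Evaluates, per participant, either the classical exclusion rule
#' (mean FD below the threshold) or the inclusive minTP rule (at least
#' `min_tp` retained frames after scrubbing), and summarizes retention per
#' group.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()], or any list
#'   with elements `participants` (each with `fd` and `group`).
#' @param cfg a [censor_config].
#' @param mode `"mean_fd_cutoff"` or `"min_tp"`.
#' @return list with `table` (per-participant data frame: id, group, mean_fd,
#'   n_retained, eligible) and `retention` (per-group data frame with counts
#'   and percentage retained).
#' @export
cohort_eligibility <- function(cohort, cfg = censor_config(),
                               mode = c("mean_fd_cutoff", "min_tp")) {
  mode <- match.arg(mode)
  parts <- cohort$participants
  tab <- do.call(rbind, lapply(parts, function(p) {
    cres <- scrub(p$fd, cfg)
    data.frame(id = p$id, group = p$group,
               mean_fd = mean_fd(p$fd),
               n_frames = length(p$fd$fd),
               n_retained = cres$n_retained,
               stringsAsFactors = FALSE)
  }))
  tab$eligible <- if (mode == "mean_fd_cutoff") {
    tab$mean_fd < cfg$fd_threshold
  } else {
    tab$n_retained >= cfg$min_tp
  }
  ret <- do.call(rbind, lapply(split(tab, tab$group), function(g) {
    data.frame(group = g$group[1L], n = nrow(g),
               n_retained = sum(g$eligible),
               pct_retained = 100 * mean(g$eligible),
               stringsAsFactors = FALSE)
  }))
  rownames(ret) <- NULL
  list(mode = mode, table = tab, retention = ret)
}

#' Write a per-participant censoring report
#'
#' @param cohort a `synthetic_cohort`.
#' @param cfg a [censor_config].
#' @param path output CSV path.
#' @return the report data frame, invisibly.
#' @export
write_censor_report <- function(cohort, cfg, path) {
  e_fd <- cohort_eligibility(cohort, cfg, "mean_fd_cutoff")$table
  e_tp <- cohort_eligibility(cohort, cfg, "min_tp")$table
  rep <- data.frame(id = e_fd$id, n_frames = e_fd$n_frames,
                    n_retained = e_fd$n_retained,
                    mean_fd = e_fd$mean_fd,
                    eligible_meanfd = e_fd$eligible,
                    eligible_mintp = e_tp$eligible)
  utils::write.table(rep, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(rep)
}
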