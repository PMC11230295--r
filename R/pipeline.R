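#' Per-method connectivity edge matrices for a cohort
#'
#' Streams over participants, applies scrubbing and eligibility, and computes
#' the requested connectivity estimators. Participants failing the chosen
#' eligibility rule (or lacking `min_tp` retained frames when a scrubbed
#' method is requested) are dropped, with their ids reported.
#'
#' @param cohort a `synthetic_cohort` (timeseries are regenerated on the fly
#'   when the cohort was built with `keep_timeseries = FALSE`), or a
#'   [cohort_spec] to generate participants one at a time without holding the
#'   whole cohort in memory.
#' @param cfg a [censor_config].
#' @param methods subset of `c("standard", "motion_ordered", "bagged")`.
#' @param eligibility `"mean_fd_cutoff"` (classical mean-FD exclusion) or
#'   `"min_tp"` (inclusive rule: enough low-motion frames).
#' @param bag_B bootstrap replicates per participant for the bagged method
#'   (default 50; the full-scale design uses 500).
#' @param seed integer seed for the bagged resampling.
#' @param first_run_only use only the first run (single-scan variant).
#' @return list with `edges` (named list: participants x edges matrix per
#'   method; for `bagged` a 3-d array participants x replicates x edges plus
#'   a `bagged_mean` matrix), `behavior` (rows aligned to the retained
#'   participants), `dropped` (ids), `eligibility` (per-participant table).
#' @export
compute_method_edges <- function(cohort, cfg = censor_config(),
                                 methods = c("standard", "motion_ordered",
                                             "bagged"),
                                 eligibility = c("mean_fd_cutoff", "min_tp"),
                                 bag_B = 50L, seed = 1L,
                                 first_run_only = FALSE) {
  eligibility <- match.arg(eligibility)
  methods <- match.arg(methods, several.ok = TRUE)
  from_spec <- inherits(cohort, "cohort_spec")
  spec <- if (from_spec) cohort else cohort$spec
  frame <- cohort_frame(spec)
  frame$row <- seq_len(nrow(frame))
  n_all <- nrow(frame)
  behavior <- if (from_spec) NULL else cohort$behavior
  need_scrub <- any(c("motion_ordered", "bagged") %in% methods)

  n_edges <- spec$n_rois * (spec$n_rois - 1L) / 2L
  std <- if ("standard" %in% methods)
    matrix(NA_real_, n_all, n_edges) else NULL
  mo <- if ("motion_ordered" %in% methods)
    matrix(NA_real_, n_all, n_edges) else NULL
  bag <- if ("bagged" %in% methods)
    array(NA_real_, dim = c(n_all, bag_B, n_edges)) else NULL
  bag_mean <- if ("bagged" %in% methods)
    matrix(NA_real_, n_all, n_edges) else NULL

  elig <- data.frame(id = frame$id, group = frame$group,
                     mean_fd = NA_real_, n_retained = NA_integer_,
                     eligible = NA)
  mfd_all <- numeric(n_all)
  for (i in seq_len(n_all)) {
    p <- if (from_spec || is.null(cohort$participants[[i]]$ts)) {
      generate_participant(spec, frame[i, ], keep_timeseries = TRUE)
    } else cohort$participants[[i]]
    ts <- p$ts
    fd <- p$fd
    if (first_run_only) {
      sel <- fd$run == 1L
      ts <- ts[sel, , drop = FALSE]
      fd <- fd_trace(fd$fd[sel], fd$run[sel], fd$head_radius)
    }
    mfd_all[i] <- mean_fd(p$fd)  # full-series mean FD, the covariate
    cres <- scrub(fd, cfg)
    elig$mean_fd[i] <- mean_fd(fd)
    elig$n_retained[i] <- cres$n_retained
    ok_mode <- if (eligibility == "mean_fd_cutoff")
      elig$mean_fd[i] < cfg$fd_threshold else cres$n_retained >= cfg$min_tp
    ok <- ok_mode && (!need_scrub || cres$n_retained >= cfg$min_tp)
    elig$eligible[i] <- ok
    if (!ok) next
    if (!is.null(std)) std[i, ] <- standard_fc(ts)
    if (!is.null(mo)) mo[i, ] <- motion_ordered_fc(ts, cres, cfg)
    if (!is.null(bag)) {
      bf <- bagged_fc(ts, cres, cfg, B = bag_B,
                      seed = derive_seed(seed, i))
      bag[i, , ] <- bf$replicates
      bag_mean[i, ] <- bf$mean
    }
  }
  keep <- which(elig$eligible)
  if (length(keep) == 0L) stop_mfc("no eligible participants in cohort")
  edges <- list()
  if (!is.null(std)) {
    edges$standard <- std[keep, , drop = FALSE]
    rownames(edges$standard) <- frame$id[keep]
  }
  if (!is.null(mo)) {
    edges$motion_ordered <- mo[keep, , drop = FALSE]
    rownames(edges$motion_ordered) <- frame$id[keep]
  }
  if (!is.null(bag)) {
    edges$bagged <- bag[keep, , , drop = FALSE]
    edges$bagged_mean <- bag_mean[keep, , drop = FALSE]
    rownames(edges$bagged_mean) <- frame$id[keep]
  }
  if (is.null(behavior)) {
    beh <- generate_behavior(spec, frame$g, frame$sex, mfd_all,
                             seed = derive_seed(spec$seed, 4L))
    behavior <- cbind(frame[c("id", "group", "sex")],
                      data.frame(mean_fd = mfd_all), beh)
  }
  list(edges = edges,
       behavior = behavior[keep, , drop = FALSE],
       dropped = frame$id[-keep],
       eligibility = elig)
}

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Either a `cohort_spec`
#' (synthetic mode) or input paths (timeseries/motion directories + behavior
#' CSV) must be supplied.
#'
#' @param spec optional [cohort_spec] for synthetic mode.
#' @param censor a [censor_config].
#' @param methods connectivity estimators to run.
#' @param behavior_cols behavior columns to scan.
#' @param covariate_cols covariate columns for the partial correlation.
#' @param eligibility `"mean_fd_cutoff"` or `"min_tp"`.
#' @param edge_mode `"strongest"` or `"weakest"` FDR-surviving edge.
#' @param n_min smallest grid sample size (default 25).
#' @param grid_k number of grid sizes (default 11).
#' @param B participant-bootstrap iterations per size (default 500).
#' @param bag_B timepoint-bootstrap replicates per participant (default 50;
#'   the full-scale design uses 500).
#' @param q FDR level (default 0.05).
#' @param concordance_n sample sizes for the method-agreement comparison.
#' @param first_run_only single-scan variant.
#' @param seed integer seed.
#' @param out_dir optional output directory; when set, result tables are
#'   written as CSV/JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, censor = censor_config(),
                            methods = c("standard", "motion_ordered",
                                        "bagged"),
                            behavior_cols = c("nih_tbx", "cbcl_ext"),
                            covariate_cols = c("sex", "mean_fd"),
                            eligibility = "mean_fd_cutoff",
                            edge_mode = "strongest",
                            n_min = 25L, grid_k = 11L,
                            B = 500L, bag_B = 50L, q = 0.05,
                            concordance_n = c(25, 250),
                            first_run_only = FALSE,
                            seed = 1L, out_dir = NULL) {
  structure(list(spec = spec, censor = censor, methods = methods,
                 behavior_cols = behavior_cols,
                 covariate_cols = covariate_cols,
                 eligibility = eligibility, edge_mode = edge_mode,
                 n_min = as.integer(n_min), grid_k = as.integer(grid_k),
                 B = as.integer(B), bag_B = as.integer(bag_B), q = q,
                 concordance_n = concordance_n,
                 first_run_only = first_run_only,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full brain-behavior pipeline
#'
#' Executes, in order: motion metrics and scrubbing/eligibility; per-method
#' connectivity; edgewise partial-Spearman scan with BH-FDR and edge
#' selection on the standard method; bootstrap reproducibility curves with
#' AUC/\eqn{\Delta}AUC per method (shared subsample draws, so comparisons
#' are paired); and method concordance at the requested sample sizes. A
#' manifest records the configuration and seed.
#'
#' @param config a [pipeline_config].
#' @param cohort optional pre-generated `synthetic_cohort` (otherwise
#'   `config$spec` is used to generate participants on the fly).
#' @return result bundle: list with `eligibility`, `retention`, `scan` (per
#'   behavior), `selected_edge`, `repro`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  src <- if (!is.null(cohort)) cohort else config$spec
  if (is.null(src)) stop_mfc("pipeline needs a cohort or a cohort_spec")

  me <- compute_method_edges(src, config$censor, config$methods,
                             eligibility = config$eligibility,
                             bag_B = config$bag_B, seed = config$seed,
                             first_run_only = config$first_run_only)
  behavior <- me$behavior
  n_elig <- nrow(behavior)
  retention <- do.call(rbind, lapply(split(me$eligibility,
                                           me$eligibility$group),
    function(g) data.frame(group = g$group[1L], n = nrow(g),
                           n_retained = sum(g$eligible),
                           pct_retained = 100 * mean(g$eligible))))
  rownames(retention) <- NULL

  scan_edges <- if ("standard" %in% names(me$edges)) me$edges$standard
                else me$edges$motion_ordered
  results <- list()
  for (bcol in config$behavior_cols) {
    scan <- edgewise_scan(scan_edges, behavior, bcol,
                          config$covariate_cols, q = config$q)
    sel <- select_edge(scan, config$edge_mode)
    res <- list(scan = scan, selected_edge = sel)
    if (length(sel$edge_id) == 1L) {
      grid <- log_spaced_sizes(min(config$n_min, n_elig - 1L), n_elig,
                               config$grid_k)
      edge_vals <- list()
      for (m in intersect(c("standard", "motion_ordered"),
                          names(me$edges)))
        edge_vals[[m]] <- me$edges[[m]][, sel$edge_id]
      if ("bagged" %in% names(me$edges))
        edge_vals$bagged <- me$edges$bagged[, , sel$edge_id]
      if (!"standard" %in% names(edge_vals))
        names(edge_vals)[1L] <- "standard"  # compare against first method
      res$repro <- run_reproducibility(edge_vals, behavior, bcol,
                                       config$covariate_cols, grid,
                                       B = config$B, seed = config$seed)
      res$concordance <- concordance_table(res$repro, grid,
                                           at_n = config$concordance_n)
      res$grid <- grid
    }
    results[[bcol]] <- res
  }

  manifest <- list(n_participants = nrow(me$eligibility),
                   n_eligible = n_elig,
                   eligibility_mode = config$eligibility,
                   methods = config$methods,
                   B = config$B, bag_B = config$bag_B,
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("motionfc")))
  bundle <- list(eligibility = me$eligibility, retention = retention,
                 behaviors = results, manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config, me)
  bundle
}

# Write pipeline outputs as CSV/JSON under config$out_dir.
write_bundle <- function(bundle, config, me) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  utils::write.table(bundle$eligibility, file.path(od, "eligibility.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$retention, file.path(od, "retention.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  n_roi <- if (!is.null(config$spec)) config$spec$n_rois else NULL
  for (bcol in names(bundle$behaviors)) {
    res <- bundle$behaviors[[bcol]]
    if (!is.null(n_roi))
      write_associations(res$scan, n_roi,
                         file.path(od, paste0("scan_", bcol, ".csv")))
    if (!is.null(res$repro)) {
      curves <- do.call(rbind, lapply(res$repro$curves, `[[`, "summary"))
      utils::write.table(curves, file.path(od, paste0("curves_", bcol,
                                                      ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(res$repro$auc,
                           file.path(od, paste0("auc_", bcol, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.table(res$concordance,
                         file.path(od, paste0("concordance_", bcol, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
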