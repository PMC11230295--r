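#' Write a parcellated timeseries to TSV
#'
#' Tab-separated, one frame per row; a leading `run` column records run
#' boundaries, remaining columns are ROI labels.
#'
#' @param ts numeric matrix, frames x ROIs.
#' @param path output path.
#' @param run integer run id per frame (default: single run).
#' @param roi_labels ROI column labels (default ROI001...).
#' @export
write_timeseries <- function(ts, path, run = rep(1L, nrow(ts)),
                             roi_labels = sprintf("ROI%03d", seq_len(ncol(ts)))) {
  stopifnot(length(run) == nrow(ts), length(roi_labels) == ncol(ts))
  df <- data.frame(run = as.integer(run), ts, check.names = FALSE)
  names(df) <- c("run", roi_labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a parcellated timeseries from TSV/CSV
#'
#' Expects a header row; an optional `run` column gives run boundaries
#' (otherwise a single run is assumed). Every remaining cell must be numeric.
#'
#' @param path input path (delimiter inferred from extension: .csv uses
#'   comma, otherwise tab/whitespace).
#' @return list with `ts` (frames x ROIs matrix, ROI labels as colnames) and
#'   `run` (integer per frame).
#' @export
read_timeseries <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = NA)
  run <- if ("run" %in% names(df)) {
    r <- df$run; df$run <- NULL; as.integer(r)
  } else rep(1L, nrow(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (any(is.na(v) & !is.na(df[[j]])) || any(is.na(v)))
      stop_mfc("non-numeric cell in ", path, " at row ",
               which(is.na(v))[1L], ", column '", names(df)[j], "'")
    df[[j]] <- v
  }
  if (nrow(df) == 0L) stop_mfc("empty timeseries file: ", path)
  list(ts = as.matrix(df), run = run)
}

#' Write a cohort behavior/covariate table to CSV
#'
#' @param behavior data frame (id, group, sex, mean_fd, behavior columns).
#' @param path output CSV path.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.table(behavior, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

#' Read a cohort behavior/covariate table from CSV
#'
#' @param path input CSV path.
#' @param required columns that must be present (default id, group, sex,
#'   mean_fd).
#' @return data frame.
#' @export
read_behavior <- function(path,
                          required = c("id", "group", "sex", "mean_fd")) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_mfc("behavior table ", path, " lacks columns: ",
             paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop_mfc("duplicate participant ids")
  df
}

#' Write a synthetic cohort as pipeline-format fixture files
#'
#' Writes, under `dir`: one timeseries TSV and one 6-column realignment text
#' file per participant per run, the cohort behavior CSV, and a ground-truth
#' JSON sidecar recording the generator's planted parameters.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), recursive = TRUE,
             showWarnings = FALSE)
  for (p in cohort$participants) {
    if (is.null(p$ts))
      stop_mfc("cohort was generated without timeseries; regenerate with ",
               "keep_timeseries = TRUE")
    write_timeseries(p$ts, file.path(dir, "timeseries",
                                     paste0(p$id, "_timeseries.tsv")),
                     run = p$fd$run)
    for (r in unique(p$trace$run)) {
      sel <- p$trace$run == r
      utils::write.table(
        format(p$trace[sel, c("tx", "ty", "tz", "rx", "ry", "rz")],
               digits = 10),
        file.path(dir, "motion", sprintf("%s_run-%d.par", p$id, r)),
        sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  write_behavior(cohort$behavior, file.path(dir, "behavior.csv"))
  truth <- cohort$truth
  truth$spec <- unclass(cohort$spec)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
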