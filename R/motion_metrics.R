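#' Framewise displacement trace
#'
#' Container for per-frame framewise displacement (FD, mm) with run labels.
#' The first frame of each run carries FD = 0 by convention (backward
#' differences are undefined there).
#'
#' @param fd numeric vector of non-negative FD values (mm).
#' @param run integer vector of run ids, same length as `fd` (default: one run).
#' @param head_radius head radius in mm used for the rotation-to-arc
#'   conversion (recorded for provenance; default 50).
#' @return An object of class `fd_trace`: a list with elements `fd`, `run`,
#'   `head_radius`.
#' @export
fd_trace <- function(fd, run = rep(1L, length(fd)), head_radius = 50) {
  fd <- as.numeric(fd)
  run <- as.integer(run)
  if (length(fd) == 0L) stop_mfc("FD trace must be non-empty")
  if (length(run) != length(fd)) stop_mfc("`run` must match `fd` in length")
  if (any(!is.finite(fd))) stop_mfc("non-finite FD at frame ",
                                    which(!is.finite(fd))[1L])
  if (any(fd < 0)) stop_mfc("FD must be non-negative (frame ",
                            which(fd < 0)[1L], ")")
  structure(list(fd = fd, run = run, head_radius = head_radius),
            class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("<fd_trace> %d frames, %d run(s), mean FD %.4f mm\n",
              length(x$fd), length(unique(x$run)), mean(x$fd)))
  invisible(x)
}

#' Framewise displacement from rigid-body realignment parameters
#'
#' FD for frame i is the sum of absolute backward differences of the six
#' rigid-body parameters, with the three rotations (radians) converted to arc
#' length on a sphere of radius `head_radius`:
#' \deqn{FD_i = |\Delta d_x| + |\Delta d_y| + |\Delta d_z| +
#'   r(|\Delta\alpha| + |\Delta\beta| + |\Delta\gamma|)}
#' The first frame of each run is assigned FD = 0; differences never span run
#' boundaries.
#'
#' @param trace data frame with numeric columns `tx`, `ty`, `tz` (mm), `rx`,
#'   `ry`, `rz` (radians unless `degrees = TRUE`), and optionally `run`
#'   (integer run id; default a single run). Frames must be in temporal order
#'   within run.
#' @param head_radius sphere radius in mm for the rotation conversion
#'   (default 50).
#' @param degrees set `TRUE` if rotations are in degrees; they are converted
#'   to radians before use.
#' @return An [fd_trace] object.
#' @export
#' @examples
#' tr <- data.frame(tx = c(0, 0.1, 0.1), ty = 0, tz = 0,
#'                  rx = 0, ry = 0, rz = 0)
#' framewise_displacement(tr)$fd  # 0, 0.1, 0
framewise_displacement <- function(trace, head_radius = 50, degrees = FALSE) {
  cols <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!is.data.frame(trace) || !all(cols %in% names(trace)))
    stop_mfc("`trace` must be a data frame with columns ",
             paste(cols, collapse = ", "))
  if (nrow(trace) == 0L) stop_mfc("empty rigid-body trace")
  run <- if ("run" %in% names(trace)) as.integer(trace$run)
         else rep(1L, nrow(trace))
  p <- as.matrix(trace[cols])
  if (any(!is.finite(p)))
    stop_mfc("non-finite realignment parameter at frame ",
             which(rowSums(!is.finite(p)) > 0L)[1L])
  if (degrees) p[, 4:6] <- p[, 4:6] * pi / 180
  fd <- numeric(nrow(p))
  for (r in unique(run)) {
    sel <- which(run == r)
    if (length(sel) > 1L) {
      d <- abs(diff(p[sel, , drop = FALSE]))
      fd[sel[-1L]] <- rowSums(d[, 1:3, drop = FALSE]) +
        head_radius * rowSums(d[, 4:6, drop = FALSE])
    }
  }
  fd_trace(fd, run, head_radius = head_radius)
}

#' Mean framewise displacement
#'
#' Arithmetic mean FD over all frames of all runs. The per-run leading zeros
#' are included by default; `include_first = FALSE` drops the first frame of
#' each run from the average.
#'
#' @param fd an [fd_trace].
#' @param include_first include the per-run first-frame zeros (default TRUE).
#' @return mean FD in mm.
#' @export
mean_fd <- function(fd, include_first = TRUE) {
  stopifnot(inherits(fd, "fd_trace"))
  if (include_first) return(mean(fd$fd))
  first <- !duplicated(fd$run)
  if (all(first)) stop_mfc("no frames left after dropping first frames")
  mean(fd$fd[!first])
}

#' Temporal signal-to-noise ratio
#'
#' Per-ROI temporal mean divided by temporal SD, averaged over ROIs. ROIs with
#' zero temporal variance make the summary undefined; in that case `NA` is
#' returned with attribute `undefined_rois` listing the offending columns
#' (no exception is raised).
#'
#' @param ts numeric matrix, frames x ROIs, with at least 2 frames.
#' @return average tSNR, or `NA` flagged with `undefined_rois`.
#' @export
tsnr <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop_mfc("tSNR needs at least 2 frames")
  m <- colMeans(ts)
  s <- apply(ts, 2L, stats::sd)
  if (any(s == 0)) {
    return(structure(NA_real_, undefined_rois = unname(which(s == 0))))
  }
  mean(m / s)
}

#' Read a 6-column rigid-body realignment parameter file
#'
#' Whitespace-delimited text, one frame per row, six numeric columns. The
#' column order is configurable; the default is translations (mm) then
#' rotations.
#'
#' @param path file path, or a character vector of per-run paths (runs are
#'   concatenated and labelled 1, 2, ...).
#' @param col_order character vector naming the six columns in file order
#'   (default `c("tx","ty","tz","rx","ry","rz")`).
#' @param degrees rotations in degrees (default FALSE: radians).
#' @return rigid-body trace data frame (columns tx..rz, run) suitable for
#'   [framewise_displacement()]; rotation unit conversion is applied here so
#'   the returned trace is always in radians.
#' @export
read_motion_params <- function(path,
                               col_order = c("tx", "ty", "tz",
                                             "rx", "ry", "rz"),
                               degrees = FALSE) {
  if (!setequal(col_order, c("tx", "ty", "tz", "rx", "ry", "rz")))
    stop_mfc("col_order must be a permutation of tx,ty,tz,rx,ry,rz")
  runs <- lapply(seq_along(path), function(i) {
    m <- utils::read.table(path[i], header = FALSE)
    if (ncol(m) != 6L)
      stop_mfc("expected 6 columns in ", path[i], ", found ", ncol(m))
    names(m) <- col_order
    m <- m[c("tx", "ty", "tz", "rx", "ry", "rz")]
    if (degrees) m[c("rx", "ry", "rz")] <- m[c("rx", "ry", "rz")] * pi / 180
    m$run <- i
    m
  })
  do.call(rbind, runs)
}

#' Read a precomputed one-column FD trace file
#'
#' @param path file path, or vector of per-run paths.
#' @param head_radius recorded head radius (mm).
#' @return An [fd_trace].
#' @export
read_fd <- function(path, head_radius = 50) {
  vals <- lapply(seq_along(path), function(i) {
    v <- utils::read.table(path[i], header = FALSE)[[1L]]
    list(fd = v, run = rep(i, length(v)))
  })
  fd_trace(unlist(lapply(vals, `[[`, "fd")),
           unlist(lapply(vals, `[[`, "run")),
           head_radius = head_radius)
}
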