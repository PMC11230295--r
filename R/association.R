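#' Encode covariate columns as a numeric matrix
#'
#' Numeric columns pass through; factor/character columns (e.g. site) are
#' expanded into indicator columns with the reference level dropped.
#'
#' @param behavior data frame holding the covariates.
#' @param cols covariate column names (may be empty).
#' @return numeric matrix with one row per participant, or `NULL` when
#'   `cols` is empty.
#' @export
encode_covariates <- function(behavior, cols) {
  if (length(cols) == 0L) return(NULL)
  miss <- setdiff(cols, names(behavior))
  if (length(miss))
    stop_mfc("missing covariate columns: ", paste(miss, collapse = ", "))
  blocks <- lapply(cols, function(cc) {
    v <- behavior[[cc]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1L, dimnames = list(NULL, cc))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L)
        stop_mfc("covariate '", cc, "' has a single level")
      m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(m) <- paste0(cc, levels(f)[-1L])
    }
    m
  })
  do.call(cbind, blocks)
}

#' Partial Spearman rank correlation
#'
#' All variables are rank-transformed (average ranks for ties); the x and y
#' ranks are residualized on the covariate ranks plus an intercept by least
#' squares, and Rs is the Pearson correlation of the residuals. With no
#' covariates this reduces exactly to the plain Spearman correlation. The
#' p-value uses the t approximation with n - 2 - k degrees of freedom, k the
#' number of covariate columns.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates optional numeric matrix/data frame with n rows (zero or
#'   more columns).
#' @return list with `rs`, `p`, `n`, `k`.
#' @export
#' @examples
#' partial_spearman(1:5, c(5, 4, 3, 2, 1))$rs  # -1
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_mfc("x and y must have equal length")
  Z <- if (is.null(covariates)) NULL
       else if (is.data.frame(covariates))
         encode_covariates(covariates, names(covariates))
       else as.matrix(covariates)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < k + 4L) stop_mfc("need n >= k + 4 observations (n = ", n,
                           ", k = ", k, ")")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_mfc("zero variance after rank transform")
  if (k > 0L) {
    rz <- apply(Z, 2L, rank)
    qrz <- qr(cbind(1, rz))
    if (qrz$rank < k + 1L) stop_mfc("rank-deficient covariate matrix")
    rx <- qr.resid(qrz, rx)
    ry <- qr.resid(qrz, ry)
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rs <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  p <- if (abs(rs) >= 1) 0 else
    2 * stats::pt(abs(rs) * sqrt(df / (1 - rs^2)), df, lower.tail = FALSE)
  list(rs = rs, p = p, n = n, k = k)
}

#' Edgewise brain-behavior association scan
#'
#' Computes a partial Spearman correlation between every edge and a behavior
#' score, controlling the given covariates, then applies Benjamini-Hochberg
#' FDR across edges.
#'
#' @param edges numeric matrix, participants x edges, with participant ids as
#'   row names (or in the same order as `behavior`).
#' @param behavior data frame with column `id` plus the behavior and covariate
#'   columns, one row per participant.
#' @param behavior_col name of the behavior column.
#' @param covariate_cols character vector of covariate column names (default
#'   `c("sex", "mean_fd")`).
#' @param q FDR level (default 0.05).
#' @return data frame with `edge_id`, `rs`, `p`, `fdr_significant`.
#' @export
edgewise_scan <- function(edges, behavior, behavior_col,
                          covariate_cols = c("sex", "mean_fd"), q = 0.05) {
  edges <- as.matrix(edges)
  if (!is.null(rownames(edges))) {
    miss <- setdiff(rownames(edges), behavior$id)
    extra <- setdiff(behavior$id, rownames(edges))
    if (length(miss) || length(extra))
      stop_mfc("participant ids do not align: missing [",
               paste(miss, collapse = ","), "] extra [",
               paste(extra, collapse = ","), "]")
    behavior <- behavior[match(rownames(edges), behavior$id), ]
  } else if (nrow(edges) != nrow(behavior)) {
    stop_mfc("edge matrix and behavior table differ in length")
  }
  y <- behavior[[behavior_col]]
  Z <- encode_covariates(behavior, covariate_cols)
  n <- nrow(edges)
  # shared residualization: rank y and covariates once, project each edge
  ry <- rank(y)
  if (!is.null(Z)) {
    qrz <- qr(cbind(1, apply(Z, 2L, rank)))
    ry <- qr.resid(qrz, ry)
  } else {
    qrz <- NULL
    ry <- ry - mean(ry)
  }
  ryn <- sqrt(sum(ry^2))
  k <- if (is.null(Z)) 0L else ncol(Z)
  rs <- vapply(seq_len(ncol(edges)), function(e) {
    rx <- rank(edges[, e])
    rx <- if (is.null(qrz)) rx - mean(rx) else qr.resid(qrz, rx)
    s <- sqrt(sum(rx^2))
    if (s == 0) return(NA_real_)
    sum(rx * ry) / (s * ryn)
  }, numeric(1))
  df <- n - 2L - k
  p <- ifelse(abs(rs) >= 1, 0,
              2 * stats::pt(abs(rs) * sqrt(df / pmax(1 - rs^2, 1e-300)),
                            df, lower.tail = FALSE))
  data.frame(edge_id = seq_len(ncol(edges)), rs = rs, p = p,
             fdr_significant = bh_fdr(p, q))
}

#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up rule at level `q`: reject all hypotheses with p at or
#' below the largest ordered p-value satisfying p_(k) <= k q / m.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NAs allowed; they
#'   are never rejected).
#' @param q FDR level (default 0.05).
#' @return logical vector of rejection flags.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_mfc("p-values must lie in [0, 1]")
  flags <- rep(FALSE, length(p_values))
  flags[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= q
  flags
}

#' Select the strongest or weakest FDR-significant edge
#'
#' Among FDR-significant edges, picks the one with the largest (strongest) or
#' smallest (weakest) |Rs| - magnitude, not sign, so negative associations are
#' not penalized. Ties break toward the lower edge id. When no edge survives
#' FDR an empty result is returned, not an error.
#'
#' @param associations data frame from [edgewise_scan()].
#' @param mode `"strongest"` or `"weakest"`.
#' @return list with `edge_id` (integer, length 0 when none significant),
#'   `rs`, and `mode`.
#' @export
select_edge <- function(associations, mode = c("strongest", "weakest")) {
  mode <- match.arg(mode)
  sig <- associations[which(associations$fdr_significant), , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(edge_id = integer(0), rs = numeric(0), mode = mode))
  a <- abs(sig$rs)
  best <- if (mode == "strongest") which(a == max(a)) else which(a == min(a))
  pick <- best[which.min(sig$edge_id[best])]
  list(edge_id = sig$edge_id[pick], rs = sig$rs[pick], mode = mode)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()]),
#' df = number of groups - 1, chi-square p-value. The fully degenerate case
#' in which every observation is identical returns H = 0 with p = 1 rather
#' than NaN.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop_mfc("need at least 2 groups")
  if (any(table(groups) == 0L)) stop_mfc("empty group")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Write an edge association table to CSV
#'
#' @param associations data frame from [edgewise_scan()].
#' @param n_roi ROI count, used to attach the (roi_i, roi_j) pair per edge.
#' @param path output CSV path.
#' @export
write_associations <- function(associations, n_roi, path) {
  map <- edge_index_map(n_roi)
  out <- merge(map, associations, by = "edge_id")
  utils::write.table(out[order(out$edge_id), ], path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
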