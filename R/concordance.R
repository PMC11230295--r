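#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired measurements:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x_1, x_2)}
#'   {\mathrm{var}(x_1) + \mathrm{var}(x_2) + (\bar x_1 - \bar x_2)^2}}
#' with population (1/n) moments. Unlike Pearson's r, \eqn{\rho_c} penalizes
#' mean and variance shifts: identical vectors give 1, a pure location shift
#' gives a value strictly below the (unchanged) r.
#'
#' @param x1,x2 numeric vectors of equal length >= 2, finite.
#' @return \eqn{\rho_c} in \[-1, 1\].
#' @export
#' @examples
#' lins_ccc(1:10, 1:10)       # 1
#' lins_ccc(1:10, 1:10 + 2)   # < 1 (location-shift penalty)
lins_ccc <- function(x1, x2) {
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  n <- length(x1)
  if (length(x2) != n) stop_mfc("x1 and x2 must have equal length")
  if (n < 2L) stop_mfc("need at least 2 paired values")
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    stop_mfc("inputs must be finite")
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- mean((x1 - m1)^2); v2 <- mean((x2 - m2)^2)
  cv <- mean((x1 - m1) * (x2 - m2))
  denom <- v1 + v2 + (m1 - m2)^2
  if (denom == 0) stop_mfc("concordance undefined: both vectors constant")
  2 * cv / denom
}

#' Concordance between paired bootstrap brain-behavior estimates
#'
#' Given the per-draw Rs values of two methods computed on the *same*
#' subsample draws at one sample size N, reports Lin's \eqn{\rho_c} and
#' Pearson's r. Pairing is structural: both vectors must come from shared
#' draws (as produced by [run_reproducibility()]), indexed identically.
#'
#' @param standard_draws numeric vector of per-draw Rs for the reference
#'   (standard) method.
#' @param method_draws numeric vector of per-draw Rs for the comparison
#'   method, same length and draw order.
#' @param N the subsample size the draws were taken at (recorded).
#' @param labels character pair naming the two methods.
#' @return object of class `concordance_result`: list with `rho_c`, `r`,
#'   `n` (number of paired draws), `N`, `labels`.
#' @export
paired_method_concordance <- function(standard_draws, method_draws, N,
                                      labels = c("standard", "method")) {
  if (length(standard_draws) != length(method_draws))
    stop_mfc("draws are not paired: lengths differ")
  structure(list(rho_c = lins_ccc(standard_draws, method_draws),
                 r = stats::cor(standard_draws, method_draws),
                 n = length(standard_draws),
                 N = N, labels = labels),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> %s vs %s at N = %s: rho_c = %.3f, r = %.3f (%d draws)\n",
              x$labels[1L], x$labels[2L], format(x$N), x$rho_c, x$r, x$n))
  invisible(x)
}

#' Concordance of reproducibility curves at chosen sample sizes
#'
#' Convenience wrapper: extracts the paired per-draw Rs columns at the grid
#' sizes closest to the requested N values and computes
#' [paired_method_concordance()] for every non-standard method.
#'
#' @param repro result of [run_reproducibility()].
#' @param grid the grid the curves were computed on.
#' @param at_n sample sizes to evaluate (default c(25, 250)).
#' @return data frame: method, N, rho_c, r, n_draws.
#' @export
concordance_table <- function(repro, grid, at_n = c(25, 250)) {
  std <- repro$curves[["standard"]]
  methods <- setdiff(names(repro$curves), "standard")
  rows <- list()
  for (m in methods) {
    for (N in at_n) {
      gi <- which.min(abs(grid$sizes - N))
      cc <- paired_method_concordance(std$draws[, gi],
                                      repro$curves[[m]]$draws[, gi],
                                      N = grid$sizes[gi],
                                      labels = c("standard", m))
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, N = grid$sizes[gi], rho_c = cc$rho_c,
                   r = cc$r, n_draws = cc$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
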