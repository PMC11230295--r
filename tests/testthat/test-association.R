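test_that("partial Spearman reduces to plain Spearman and matches the projection oracle", {
  expect_equal(partial_spearman(1:5, (1:5)^3)$rs, 1)
  expect_equal(partial_spearman(1:5, c(5, 4, 3, 2, 1))$rs, -1)

  set.seed(61)
  for (i in 1:20) {
    n <- 30
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    Z <- cbind(rnorm(n), x + rnorm(n))
    got <- partial_spearman(x, y, Z)
    expect_equal(got$rs, partial_spearman_oracle(x, y, Z),
                 tolerance = 1e-12)
    # no covariates: exactly cor(method = "spearman")
    expect_equal(partial_spearman(x, y)$rs,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }

  # ties handled by average ranks in both routes
  x <- c(1, 1, 2, 3, 3, 4, 5, 6)
  y <- c(2, 1, 1, 4, 4, 5, 5, 8)
  z <- c(1, 2, 2, 3, 4, 4, 5, 5)
  expect_equal(partial_spearman(x, y, cbind(z))$rs,
               partial_spearman_oracle(x, y, cbind(z)), tolerance = 1e-12)
})

test_that("partial Spearman is invariant under monotone transforms and robust to noise covariates", {
  set.seed(62)
  n <- 200
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); Z <- cbind(rnorm(n))
  base <- partial_spearman(x, y, Z)$rs
  expect_equal(partial_spearman(exp(x), y, Z)$rs, base, tolerance = 1e-12)
  expect_equal(partial_spearman(x, y^3 + 5 * y, Z)$rs, base,
               tolerance = 1e-12)

  n <- 1000
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  plain <- partial_spearman(x, y)$rs
  with_noise <- partial_spearman(x, y, cbind(rnorm(n)))$rs
  expect_lt(abs(plain - with_noise), 4 / sqrt(n))

  expect_error(partial_spearman(rep(1, 20), rnorm(20)), "zero variance")
  expect_error(partial_spearman(rnorm(20), rnorm(20),
                                cbind(1:20, 2 * (1:20))), "rank-deficient")
  expect_error(partial_spearman(rnorm(4), rnorm(4), cbind(rnorm(4))),
               "k \\+ 4")
})

test_that("p-values follow the t approximation with n - 2 - k df", {
  set.seed(63)
  n <- 40
  x <- rnorm(n); y <- rnorm(n); Z <- cbind(rnorm(n), rnorm(n))
  got <- partial_spearman(x, y, Z)
  tstat <- got$rs * sqrt((n - 4) / (1 - got$rs^2))
  expect_equal(got$p, 2 * pt(abs(tstat), n - 4, lower.tail = FALSE))
  expect_equal(partial_spearman(1:10, 1:10)$p, 0)
})

test_that("the edgewise scan localizes a planted effect and is null-calibrated", {
  set.seed(64)
  n <- 500
  behavior <- data.frame(id = sprintf("s%03d", 1:n),
                         sex = rbinom(n, 1, 0.5), mean_fd = rlnorm(n, -1.7, 0.3))
  y <- rnorm(n)
  edges <- matrix(rnorm(n * 10), ncol = 10)
  edges[, 3] <- 0.5 * y + rnorm(n)  # planted association at edge 3
  edges[, 7] <- edges[, 3]          # duplicate column
  rownames(edges) <- behavior$id
  behavior$beh <- y
  scan <- edgewise_scan(edges, behavior, "beh")
  expect_equal(scan$edge_id[which.max(abs(scan$rs))], 3L)
  expect_equal(scan$rs[3], scan$rs[7])
  expect_true(scan$fdr_significant[3])

  # independent behavior: p-values are uniform (KS not rejected at 1%)
  null_edges <- matrix(rnorm(n * 60), ncol = 60)
  rownames(null_edges) <- behavior$id
  null_scan <- edgewise_scan(null_edges, behavior, "beh")
  expect_gt(ks.test(null_scan$p, "punif")$p.value, 0.01)
  expect_lte(mean(null_scan$fdr_significant), 0.05)

  # misaligned ids are reported
  bad <- behavior; bad$id[1] <- "someone_else"
  expect_error(edgewise_scan(edges, bad, "beh"), "do not align")
})

test_that("BH flags equal the brute-force step-up oracle", {
  expect_equal(bh_fdr(rep(0.001, 50)), rep(TRUE, 50))
  expect_true(bh_fdr(0.04))
  expect_false(bh_fdr(0.06))
  expect_error(bh_fdr(c(0.1, 1.3)), "\\[0, 1\\]")

  set.seed(65)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05), bh_oracle(p, 0.05))
  }
})

test_that("edge selection uses magnitude with lower-id tie-break and a null-safe empty result", {
  assoc <- data.frame(edge_id = 1:4, rs = c(0.15, -0.16, 0.02, 0.10),
                      p = rep(0.001, 4),
                      fdr_significant = c(TRUE, TRUE, FALSE, TRUE))
  strongest <- select_edge(assoc, "strongest")
  expect_equal(strongest$edge_id, 2L)   # |−0.16| beats +0.15
  expect_equal(strongest$rs, -0.16)
  weakest <- select_edge(assoc, "weakest")
  expect_equal(weakest$edge_id, 4L)     # weakest among *significant* edges

  one <- assoc[2, ]
  expect_equal(select_edge(one, "strongest")$edge_id,
               select_edge(one, "weakest")$edge_id)

  tie <- data.frame(edge_id = c(5L, 9L), rs = c(0.2, -0.2), p = 0.001,
                    fdr_significant = TRUE)
  expect_equal(select_edge(tie, "strongest")$edge_id, 5L)

  none <- assoc; none$fdr_significant <- FALSE
  out <- select_edge(none, "strongest")
  expect_length(out$edge_id, 0)
})

test_that("Kruskal-Wallis wrapper matches the rank-formula oracle and degrades gracefully", {
  expect_equal(kruskal_wallis(rep(7, 9), rep(1:3, 3)),
               list(H = 0, df = 2L, p = 1))
  set.seed(66)
  vals <- round(rnorm(15), 1)  # rounding introduces ties
  grp <- rep(c("a", "b", "c"), each = 5)
  got <- kruskal_wallis(vals, grp)
  expect_equal(got$df, 2L)
  # brute-force H with tie correction
  N <- length(vals)
  r <- rank(vals)
  Rj <- tapply(r, grp, sum)
  nj <- tapply(r, grp, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(got$H, unname(H), tolerance = 1e-12)
  expect_equal(got$p, pchisq(H, 2, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("categorical covariates are expanded to indicator columns", {
  set.seed(67)
  df <- data.frame(site = rep(c("A", "B", "C"), each = 10),
                   age = rnorm(30))
  Z <- encode_covariates(df, c("sex", "age")[2])
  expect_equal(ncol(Z), 1L)
  Z2 <- encode_covariates(df, c("site", "age"))
  expect_equal(ncol(Z2), 3L)  # two site indicators + age
  expect_true(all(Z2[, 1:2] %in% c(0, 1)))
  expect_error(encode_covariates(df, "nope"), "missing covariate")
})
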