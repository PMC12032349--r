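rand_ztbl <- function(p, n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, dimnames = list(paste0("f", 1:p),
                                               paste0("s", 1:n)))
  m <- t(scale(t(m)))
  as_coverage_table(m, system = "z")
}

test_that("PCA eigenvalues match a direct covariance eigensolve", {
  set.seed(51)
  m <- matrix(rnorm(9), 3, dimnames = list(paste0("f", 1:3),
                                           paste0("s", 1:3)))
  pc <- pca_table(as_coverage_table(m, "x"), mode = "samples")
  # oracle: eigen of the 1/n covariance of samples-as-rows
  X <- t(m); Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE)$values
  expect_equal(pc$eigenvalues, ev[seq_along(pc$eigenvalues)],
               tolerance = 1e-10)
  expect_equal(pc$variance_fraction,
               (ev / sum(ev))[seq_along(pc$eigenvalues)],
               tolerance = 1e-10)
})

test_that("rank-1 data put all variance on PC1; duplication leaves fractions", {
  u <- rnorm(6); v <- rnorm(4)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("f", 1:6), paste0("s", 1:4))
  # feature mode: rows are observations, rank-1 after centering too
  pc <- pca_table(as_coverage_table(m, "x"), mode = "features")
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-10)

  z <- rand_ztbl(5, 8, seed = 52)
  mz <- coverage_matrix(z)
  dup <- cbind(mz, mz); colnames(dup) <- paste0("s", 1:16)
  p1 <- pca_table(z, mode = "samples")
  p2 <- pca_table(as_coverage_table(dup, "x"), mode = "samples")
  expect_equal(p2$variance_fraction[1:4], p1$variance_fraction[1:4],
               tolerance = 1e-10)
})

test_that("MCOA degenerates to PCA for K = 1 and doubles for twin tables", {
  z <- rand_ztbl(6, 10, seed = 53)
  pc <- pca_table(z, mode = "samples")
  m1 <- mcoa(list(a = z), n_axes = 6, scale_tables = FALSE)
  expect_equal(m1$pseudo_eig, pc$eigenvalues[seq_along(m1$pseudo_eig)],
               tolerance = 1e-8)
  expect_equal(as.matrix(m1$scores[, -1]),
               as.matrix(pc$scores[, -1])[, seq_along(m1$pseudo_eig)],
               ignore_attr = TRUE, tolerance = 1e-8)
  m2 <- mcoa(list(a = z, b = z), n_axes = 6, scale_tables = FALSE)
  expect_equal(m2$pseudo_eig, 2 * m1$pseudo_eig, tolerance = 1e-8)
})

test_that("MCOA axis 1 attains the co-inertia criterion maximum", {
  z1 <- rand_ztbl(3, 6, seed = 54)
  z2 <- rand_ztbl(3, 6, seed = 55)
  mc <- mcoa(list(a = z1, b = z2), scale_tables = FALSE)
  X1 <- t(coverage_matrix(z1)); X2 <- t(coverage_matrix(z2))
  n <- 6
  # criterion value at a direction v: sum over tables of the best
  # squared covariance, i.e. ||X_k' D v||^2 with D = I/n
  crit <- function(v) {
    v <- v / sqrt(sum(v^2) / n)              # unit norm in 1/n metric
    sum((crossprod(X1, v) / n)^2) + sum((crossprod(X2, v) / n)^2)
  }
  # Monte-Carlo: random unit directions never beat lambda1
  set.seed(56)
  vals <- replicate(2000, crit(rnorm(n)))
  expect_gte(mc$pseudo_eig[1] + 1e-10, max(vals))
  # per-table squared covariances sum to the pseudo-eigenvalue
  expect_equal(rowSums(mc$table_cov2), mc$pseudo_eig, tolerance = 1e-8)
})

test_that("MCOA checks sample alignment and degenerate tables", {
  z1 <- rand_ztbl(3, 6, seed = 57)
  z2 <- rand_ztbl(3, 6, seed = 58)
  m2 <- coverage_matrix(z2)[, 6:1]
  expect_error(mcoa(list(a = z1, b = as_coverage_table(m2, "x"))),
               "sample ordering")
  zero <- as_coverage_table(matrix(0, 2, 6,
                                   dimnames = list(c("f1", "f2"),
                                                   colnames(coverage_matrix(z1)))),
                            "x")
  expect_error(mcoa(list(a = z1, b = zero)), "zero total variance")
})

test_that("PERMANOVA matches vegan::adonis2 term by term", {
  skip_if_not_installed("vegan")
  set.seed(59)
  n <- 36
  m <- matrix(rnorm(8 * n), 8, dimnames = list(paste0("f", 1:8),
                                               paste0("s", 1:n)))
  dat <- data.frame(month = factor(sample(1:4, n, TRUE)),
                    year = factor(sample(2011:2013, n, TRUE)))
  got <- permanova(m, dat, terms = c("month", "year"), n_perm = 0)
  want <- vegan::adonis2(t(m) ~ month + year, data = dat,
                         method = "euclidean", permutations = 2,
                         by = "terms")
  expect_equal(got$ss[1:2], want$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(got$pseudo_f[1:2], want$F[1:2], tolerance = 1e-8)
  expect_equal(got$r_squared[1:2], want$R2[1:2], tolerance = 1e-8)
})

test_that("separated groups give R2 ~ 1 and the minimal p-value", {
  m <- cbind(matrix(rnorm(3 * 10, 0, 0.01), 3),
             matrix(rnorm(3 * 10, 50, 0.01), 3))
  dimnames(m) <- list(paste0("f", 1:3), paste0("s", 1:20))
  dat <- data.frame(month = rep(c("a", "b"), each = 10))
  res <- permanova(m, dat, terms = "month", n_perm = 199, seed = 60)
  expect_gt(res$r_squared[1], 0.999)
  expect_equal(res$p_value[1], 1 / 200)
})

test_that("exhaustive-permutation p equals the enumerated Monte-Carlo p", {
  set.seed(61)
  m <- matrix(rnorm(4 * 6), 4, dimnames = list(paste0("f", 1:4),
                                               paste0("s", 1:6)))
  dat <- data.frame(g = rep(c("a", "b"), 3))
  P <- all_perms(6)
  res <- permanova(m, dat, terms = "g", perm_matrix = P)
  # oracle: classic within/between distance formula at every permutation
  D <- dist(t(m))
  f_obs <- oracle_permanova_f(D, dat$g)
  f_perm <- apply(P, 1, function(p) {
    oracle_permanova_f(as.matrix(D)[p, p], dat$g)
  })
  p_oracle <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(P))
  expect_equal(res$pseudo_f[1], f_obs, tolerance = 1e-8)
  expect_equal(res$p_value[1], p_oracle)
})

test_that("total SS of Euclidean z-score distances is (n-1) x features", {
  z <- rand_ztbl(7, 15, seed = 62)
  res <- permanova(z, data.frame(g = factor(rep(1:3, 5))), terms = "g",
                   n_perm = 0)
  expect_equal(res$ss[res$term == "Total"], 14 * 7, tolerance = 1e-6)
})

test_that("empty interaction cells drop the interaction with a warning", {
  set.seed(63)
  n <- 8
  m <- matrix(rnorm(3 * n), 3, dimnames = list(paste0("f", 1:3),
                                               paste0("s", 1:n)))
  # observed cells = month df + year df + 1 -> interaction adds no df
  dat <- data.frame(month = factor(c(1, 1, 1, 1, 2, 2, 3, 3)),
                    year = factor(c(1, 1, 2, 2, 1, 1, 2, 2)))
  expect_warning(res <- permanova(m, dat,
                                  terms = c("month", "year", "month:year"),
                                  n_perm = 9),
                 "dropped|no estimable")
  expect_false("month:year" %in% res$term)
})

test_that("consistent sample permutation leaves every statistic unchanged", {
  z <- rand_ztbl(5, 12, seed = 64)
  dat <- data.frame(month = factor(rep(1:3, 4)))
  res1 <- permanova(z, dat, terms = "month", n_perm = 0)
  perm <- sample(12)
  m2 <- coverage_matrix(z)[, perm]
  res2 <- permanova(as_coverage_table(m2, "z"), dat[perm, , drop = FALSE],
                    terms = "month", n_perm = 0)
  expect_equal(res2$ss, res1$ss, tolerance = 1e-9)
  p1 <- pca_table(z, "samples")
  p2 <- pca_table(as_coverage_table(m2, "z"), "samples")
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-9)
})
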