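test_that("column z-scoring is shift-invariant and exact on a toy", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  z <- zscore_columns(x)
  expect_equal(colMeans(z), c(0, 0))
  expect_equal(apply(z, 2, sd), c(1, 1))
  expect_equal(z[, 1], (c(1, 2, 3) - 2) / 1)
  expect_equal(zscore_columns(x + 5), z, ignore_attr = TRUE)
  colnames(x) <- c("t1_1", "t1_2")
  x[, 2] <- 7
  expect_error(zscore_columns(x), "t1_2")
})

test_that("cross-block rows are within-group correlations in stacked order", {
  set.seed(20)
  n <- 30
  y <- matrix(rnorm(3 * n * 3), 3 * n, 3,
              dimnames = list(NULL, c("strength", "degree", "age")))
  x <- matrix(rnorm(3 * n * 5), 3 * n, 5)
  g <- rep(c("g1", "g2", "g3"), each = n)
  # plant a noiseless duplicate of a behavior into a brain column
  x[g == "g2", 3] <- y[g == "g2", 2]
  r <- cross_block(x, y, g)
  expect_equal(dim(r), c(9L, 5L))
  expect_equal(rownames(r)[4:6], c("g2:strength", "g2:degree", "g2:age"))
  expect_equal(unname(r["g2:degree", 3]), 1)
  # manual within-group correlation for one entry
  expect_equal(unname(r["g1:age", 2]),
               cor(y[g == "g1", 3], x[g == "g1", 2]))
  # permuting participants within a group leaves the matrix unchanged
  perm <- c(sample(1:n), (n + 1):(3 * n))
  expect_equal(cross_block(x[perm, ], y[perm, ], g[perm]), r)
})

test_that("cross-block entries of independent noise stay within sampling bounds", {
  set.seed(21)
  n <- 1000
  y <- matrix(rnorm(3 * n * 3), 3 * n, 3)
  x <- matrix(rnorm(3 * n * 20), 3 * n, 20)
  g <- rep(1:3, each = n)
  r <- cross_block(x, y, g)
  expect_true(all(abs(r) < 0.1))
  y2 <- y; y2[g == 2, 1] <- 5
  expect_error(cross_block(x, y2, g), "zero-variance behavior")
})

test_that("SVD decomposition reconstructs R with orthonormal saliences", {
  set.seed(22)
  r <- matrix(rnorm(9 * 152), 9, 152)
  d <- decompose(r)
  expect_equal(d$v %*% diag(d$s) %*% t(d$u), r, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(d$u), diag(9), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(d$v), diag(9), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(d$covariance_pct), 100)
  expect_true(all(diff(d$s) <= 1e-12))
  # sign convention: the dominant element of each v column is positive
  for (l in 1:9) expect_gt(d$v[which.max(abs(d$v[, l])), l], 0)
})

test_that("a rank-1 cross-block puts all covariance on the first LV", {
  u1 <- rnorm(10); v1 <- rnorm(4)
  r <- outer(v1, u1)
  d <- decompose(r)
  expect_equal(d$covariance_pct[1], 100, tolerance = 1e-10)
  expect_equal(d$covariance_pct[-1], rep(0, 3), tolerance = 1e-10)
})

test_that("singular values match an independent eigendecomposition oracle", {
  r <- matrix(c(3, 1, -1, 2, 0.5, 4), 2, 3)
  d <- decompose(r)
  lam <- eigen(r %*% t(r), symmetric = TRUE)$values
  expect_equal(d$s, sqrt(lam), tolerance = 1e-12)
  # permutation of rows/columns permutes saliences but keeps spectrum
  set.seed(23)
  r2 <- matrix(rnorm(9 * 20), 9, 20)
  pr <- sample(9); pc <- sample(20)
  expect_equal(decompose(r2[pr, pc])$s, decompose(r2)$s, tolerance = 1e-10)
})

test_that("brain scores are projections with the expected algebra", {
  set.seed(24)
  x <- matrix(rnorm(40), 8, 5)
  u <- diag(5)[, 2, drop = FALSE]
  expect_equal(brain_scores(x, u)[, 1], x[, 2])
  expect_equal(brain_scores(2 * x, u), 2 * brain_scores(x, u))
  # covariance of scores equals u' Sigma u
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  sc <- brain_scores(x, q)
  expect_equal(cov(sc), t(q) %*% cov(x) %*% q, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("permutation p-values are reproducible and detect planted signal", {
  dat <- planted_pls_data(n_per_group = 40, effect = 1.0, seed = 25)
  x <- zscore_columns(dat$x)
  p1 <- permutation_test(x, dat$y, dat$groups, n_perm = 199, seed = 9)
  p2 <- permutation_test(x, dat$y, dat$groups, n_perm = 199, seed = 9)
  expect_identical(p1$perm_p, p2$perm_p)
  # a strong planted LV is never exceeded: p at the permutation floor
  expect_equal(p1$perm_p[1], 1 / 200)
  expect_warning(permutation_test(x, dat$y, dat$groups, n_perm = 50,
                                  seed = 1), "fewer than 100")
})

test_that("bootstrap ratios flag planted columns and spare null columns", {
  dat <- planted_pls_data(n_per_group = 60, n_cols = 40, planted = 1:8,
                          effect = 1.0, seed = 26)
  fit <- bpls(dat$x, dat$y, dat$groups, n_perm = 100, n_boot = 300,
              seed = 10)
  mask <- fit$stable_mask[, 1]
  expect_gte(mean(mask[dat$planted]), 0.8)
  expect_lte(mean(mask[-dat$planted]), 0.1)
  # bootstrap ratio carries the salience sign (SE is positive)
  nz <- abs(fit$u[, 1]) > 1e-12
  expect_equal(sign(fit$boot_ratio[nz, 1]), sign(fit$u[nz, 1]),
               ignore_attr = TRUE)
  # fixed seed reproduces the mask bitwise
  fit2 <- bpls(dat$x, dat$y, dat$groups, n_perm = 100, n_boot = 300,
               seed = 10)
  expect_identical(fit$stable_mask, fit2$stable_mask)
  expect_identical(fit$perm_p, fit2$perm_p)
})

test_that("group-specific effects appear only in affected groups' CIs", {
  dat <- planted_pls_data(n_per_group = 60, n_cols = 40, planted = 1:8,
                          effect = 1.0, seed = 27)
  fit <- bpls(dat$x, dat$y, dat$groups, n_perm = 100, n_boot = 300,
              seed = 11)
  lo <- fit$corr_lo[, 1]; hi <- fit$corr_hi[, 1]
  aff <- grepl("^g[12]:", names(lo))
  expect_true(all(lo[aff] > 0 | hi[aff] < 0))
  # each null-group 95% interval covers zero with 95% probability, so
  # demand a majority rather than all three
  expect_gte(sum(lo[!aff] < 0 & hi[!aff] > 0), 2L)
})

test_that("permutation p rendering reports the resolution floor", {
  expect_equal(format_perm_p(c(1 / 1001, 0.02), 1000),
               c("<0.0010", "0.0200"))
})

test_that("the stable-ROI report folds the 152-column mask onto ROIs", {
  dat <- planted_pls_data(n_per_group = 20, n_cols = 152,
                          planted = c(3, 79), effect = 0, seed = 28)
  fit <- bpls(dat$x, dat$y, dat$groups, n_perm = 100, n_boot = 100,
              seed = 12)
  # force a known mask rather than relying on the null fit
  fit$stable_mask[] <- FALSE
  fit$stable_mask[c(3, 76 + 3, 76 + 10), 1] <- TRUE
  rep <- pls_report(fit)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$t1[rep$name == roi_lookup()$name[3]][1], "x")
  expect_true(all(rep$md[rep$t1 == "-"] == "x"))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "stable.csv")
  write.csv(rep, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$name, rep$name)
  expect_equal(back$t1_stable, rep$t1_stable)
})

test_that("cross-block energy is conserved by the decomposition", {
  set.seed(29)
  for (i in 1:20) {
    r <- matrix(rnorm(9 * 30, sd = runif(1, 0.5, 2)), 9, 30)
    d <- decompose(r)
    expect_equal(sum(d$s^2), sum(r^2), tolerance = 1e-10)
  }
})
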