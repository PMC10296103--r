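test_that("one-way ANOVA matches hand-computed sums of squares", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_anova(v, g)
  # between SS = 54 on 2 df, within SS = 6 on 6 df -> F = 27
  expect_equal(res$F, 27)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$p, pf(27, 2, 6, lower.tail = FALSE))
  # identical group means give F = 0
  res0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(1)
  v <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  res <- one_way_anova(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("Levene's test is zero for identical groups and mean-centered", {
  v <- c(1, 2, 3, 1, 2, 3); g <- rep(c("a", "b"), each = 3)
  expect_equal(levene_test(v, g)$W, 0)
  # center = mean differs from median centering on a skewed toy
  set.seed(2)
  v2 <- c(rexp(20), rexp(20, 0.3)); g2 <- rep(c("a", "b"), each = 20)
  expect_false(isTRUE(all.equal(levene_test(v2, g2)$W,
                                levene_test(v2, g2, "median")$W)))
})

test_that("Levene's test has near-nominal size and detects 9:1 variance", {
  set.seed(3)
  rej <- mean(replicate(400, {
    v <- rnorm(90); g <- rep(1:3, each = 30)
    levene_test(v, g)$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.10)
  power <- mean(replicate(100, {
    v <- c(rnorm(30, sd = 3), rnorm(30), rnorm(30))
    levene_test(v, rep(1:3, each = 30))$p < 0.05
  }))
  expect_gt(power, 0.8)
})

test_that("LSD post hocs use the pooled MSE and unadjusted p-values", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  tab <- lsd_posthoc(v, g)
  expect_equal(nrow(tab), 3L)
  ab <- tab[tab$group1 == "a" & tab$group2 == "b", ]
  # pooled MSE = 1, SE = sqrt(2/3), t = -3 / SE, df = 6
  expect_equal(ab$se, sqrt(2 / 3))
  expect_equal(ab$t, -3 / sqrt(2 / 3))
  expect_equal(ab$df, 6)
  # cross-check p against base pairwise.t.test with pooled SD
  ref <- pairwise.t.test(v, g, pool.sd = TRUE, p.adjust.method = "none")
  expect_equal(ab$p, ref$p.value["b", "a"], tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  t0 <- lsd_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(t0$t, 0); expect_equal(t0$p, 1)
})

test_that("Games-Howell reduces to the Welch t-test for two groups", {
  set.seed(4)
  v <- c(rnorm(10, sd = 3), rnorm(20)); g <- rep(c("a", "b"), c(10, 20))
  gh <- games_howell_posthoc(v, g)
  wt <- t.test(v[g == "a"], v[g == "b"])  # Welch by default
  expect_equal(gh$t, unname(wt$statistic), tolerance = 1e-10)
  expect_equal(gh$df, unname(wt$parameter), tolerance = 1e-10)
  # for k = 2 the studentized-range p equals the two-sided t p
  expect_equal(gh$p, wt$p.value, tolerance = 1e-8)
})

test_that("Games-Howell df respects the Welch-Satterthwaite bounds", {
  set.seed(5)
  v <- c(rnorm(8, sd = 4), rnorm(12, sd = 1), rnorm(15, sd = 2))
  g <- rep(c("a", "b", "c"), c(8, 12, 15))
  gh <- games_howell_posthoc(v, g)
  n <- c(a = 8, b = 12, c = 15)
  for (i in seq_len(nrow(gh))) {
    ni <- n[[gh$group1[i]]]; nj <- n[[gh$group2[i]]]
    expect_gte(gh$df[i], min(ni, nj) - 1)
    expect_lte(gh$df[i], ni + nj - 2)
  }
  # equal groups are never significant
  gh0 <- games_howell_posthoc(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))
  expect_gt(gh0$p, 0.99)
})

test_that("Brown-Forsythe matches its textbook formula on a toy", {
  v <- c(1, 3, 5, 2, 4, 9, 1, 7, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  bf <- brown_forsythe(v, g)
  n <- tapply(v, g, length); m <- tapply(v, g, mean)
  s2 <- tapply(v, g, var); N <- sum(n)
  num <- sum(n * (m - sum(n * m) / N)^2)
  ci <- (1 - n / N) * s2
  expect_equal(bf$F, num / sum(ci))
  expect_equal(bf$df2, sum(ci)^2 / sum(ci^2 / (n - 1)))
  expect_equal(bf$df1, 2)
  # equal groups give F = 0
  expect_equal(brown_forsythe(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))$F, 0)
})

test_that("Welch statistic matches its textbook formula on a toy", {
  v <- c(1, 3, 5, 2, 4, 9, 1, 7, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  w <- welch_anova(v, g)
  n <- tapply(v, g, length); m <- tapply(v, g, mean)
  s2 <- tapply(v, g, var); k <- 3
  wt <- n / s2
  mw <- sum(wt * m) / sum(wt)
  A <- sum(wt * (m - mw)^2) / (k - 1)
  lam <- sum((1 - wt / sum(wt))^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  expect_equal(w$F, A / B, tolerance = 1e-12)
  expect_equal(w$df2, (k^2 - 1) / (3 * lam), tolerance = 1e-12)
})

test_that("robust tests approach the classical F under homoscedasticity", {
  set.seed(6)
  v <- rnorm(600) + rep(c(0, 0.4, 0.8), each = 200)
  g <- rep(1:3, each = 200)
  a <- one_way_anova(v, g); w <- welch_anova(v, g); b <- brown_forsythe(v, g)
  expect_lt(abs(w$F - a$F) / max(a$F, 0.1), 0.05)
  expect_lt(abs(b$F - a$F) / max(a$F, 0.1), 0.05)
})

test_that("omnibus tests keep nominal type-I error under the null", {
  set.seed(7)
  n_sim <- 2000
  rej <- matrix(FALSE, n_sim, 3)
  for (i in seq_len(n_sim)) {
    v <- rnorm(45); g <- rep(1:3, each = 15)
    rej[i, ] <- c(one_way_anova(v, g)$p, welch_anova(v, g)$p,
                  brown_forsythe(v, g)$p) < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("tests are location-invariant and F is scale-invariant", {
  set.seed(8)
  v <- rnorm(30); g <- rep(1:3, each = 10)
  expect_equal(one_way_anova(v, g)$F, one_way_anova(v + 100, g)$F)
  expect_equal(one_way_anova(v, g)$F, one_way_anova(v * 3.7, g)$F,
               tolerance = 1e-12)
  expect_equal(welch_anova(v, g)$F, welch_anova(v + 100, g)$F,
               tolerance = 1e-12)
  expect_equal(levene_test(v, g)$W, levene_test(v + 100, g)$W,
               tolerance = 1e-12)
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  # 3-point toy by the product-moment formula
  x <- c(1, 2, 4); y <- c(1, 3, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_hand)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "3 complete pairs")
})

test_that("p-value rendering matches journal table conventions", {
  expect_equal(format_p(c(0.0004, 0.043, 0.5101)),
               c("<0.001", "0.043", "0.510"))
})
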