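# Group comparisons for the demographic and psychosexual variables: classic
# one-way ANOVA with LSD post hocs, Levene's test for variance homogeneity,
# and the heteroscedasticity-robust alternatives (Welch and Brown-Forsythe
# omnibus tests, Games-Howell post hocs) used when Levene's test rejects.

split_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  g <- split(values[keep], factor(groups[keep]))
  if (length(g) < 2L || any(lengths(g) < 2L))
    stop("need at least 2 groups with at least 2 observations each")
  g
}

#' Classical one-way ANOVA
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels aligned with `values`.
#' @return A list with `F`, `df1`, `df2`, `p`, and the group means.
#' @export
one_way_anova <- function(values, groups) {
  g <- split_groups(values, groups)
  fit <- stats::aov(v ~ grp,
                    data = data.frame(v = unlist(g),
                                      grp = rep(names(g), lengths(g))))
  tab <- summary(fit)[[1L]]
  if (tab["Residuals", "Mean Sq"] == 0 &&
      stats::var(vapply(g, mean, 0)) > 0)
    warning("zero within-group variance with unequal means; p collapses to 0")
  list(F = tab[1L, "F value"], df1 = tab[1L, "Df"],
       df2 = tab["Residuals", "Df"], p = tab[1L, "Pr(>F)"],
       group_means = vapply(g, mean, 0), mse = tab["Residuals", "Mean Sq"])
}

#' Levene's test for homogeneity of variance
#'
#' ANOVA on absolute deviations from the group centers; the center is the
#' group mean (the convention of mainstream commercial packages), not the
#' median.
#'
#' @inheritParams one_way_anova
#' @param center `"mean"` (default) or `"median"`.
#' @return A list with `W` (the F statistic on deviations), `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- split_groups(values, groups)
  if (any(vapply(g, function(x) stats::var(x) == 0, TRUE)))
    warning("a group has zero variance; Levene's test is degenerate")
  tab <- car::leveneTest(unlist(g), factor(rep(names(g), lengths(g))),
                         center = get(center))
  list(W = tab[1L, "F value"], df1 = tab[1L, "Df"], df2 = tab[2L, "Df"],
       p = tab[1L, "Pr(>F)"])
}

#' LSD (least significant difference) post hoc comparisons
#'
#' Pairwise t tests sharing the ANOVA's pooled error mean square, with
#' unadjusted two-sided p-values on `N - k` degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return A data.frame with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean difference), `se`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(values, groups) {
  g <- split_groups(values, groups)
  k <- length(g); n <- lengths(g); m <- vapply(g, mean, 0)
  N <- sum(n)
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / (N - k)
  pairs <- utils::combn(names(g), 2L)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(mse * (1 / n[[i]] + 1 / n[[j]]))
    tt <- (m[[i]] - m[[j]]) / se
    data.frame(group1 = i, group2 = j, diff = m[[i]] - m[[j]], se = se,
               t = tt, df = N - k, p = 2 * stats::pt(-abs(tt), N - k))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Games-Howell post hoc comparisons
#'
#' Pairwise comparisons robust to heterogeneity of variance: each pair uses
#' its own Welch-type standard error and Welch-Satterthwaite degrees of
#' freedom, with p-values from the studentized range distribution on k
#' groups (the q statistic is `|diff| / se * sqrt(2)`).
#'
#' @inheritParams one_way_anova
#' @return A data.frame as in [lsd_posthoc()], with Welch df.
#' @export
games_howell_posthoc <- function(values, groups) {
  g <- split_groups(values, groups)
  k <- length(g); n <- lengths(g)
  m <- vapply(g, mean, 0); v <- vapply(g, stats::var, 0)
  pairs <- utils::combn(names(g), 2L)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    wi <- v[[i]] / n[[i]]; wj <- v[[j]] / n[[j]]
    se <- sqrt(wi + wj)
    df <- (wi + wj)^2 / (wi^2 / (n[[i]] - 1) + wj^2 / (n[[j]] - 1))
    tt <- (m[[i]] - m[[j]]) / se
    p <- stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, diff = m[[i]] - m[[j]], se = se,
               t = tt, df = df, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Welch's heteroscedasticity-robust one-way test
#'
#' @inheritParams one_way_anova
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  g <- split_groups(values, groups)
  ft <- stats::oneway.test(v ~ grp,
                           data = data.frame(v = unlist(g),
                                             grp = rep(names(g), lengths(g))),
                           var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1L]),
       df2 = unname(ft$parameter[2L]), p = ft$p.value)
}

#' Brown-Forsythe robust one-way test
#'
#' The between-group sum of squares divided by a variance-weighted error
#' term `sum((1 - n_i/N) s_i^2)`, with Satterthwaite denominator degrees of
#' freedom.
#'
#' @inheritParams one_way_anova
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(values, groups) {
  g <- split_groups(values, groups)
  n <- lengths(g); N <- sum(n); k <- length(g)
  m <- vapply(g, mean, 0); v <- vapply(g, stats::var, 0)
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  ci <- (1 - n / N) * v
  Fstat <- num / sum(ci)
  df2 <- sum(ci)^2 / sum(ci^2 / (n - 1))
  list(F = Fstat, df1 = k - 1, df2 = df2,
       p = stats::pf(Fstat, k - 1, df2, lower.tail = FALSE))
}

#' Pearson correlation with t-reference p-value
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return A list with `r`, `n`, `df`, `t`, `p`.
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), n = length(x),
       df = unname(ct$parameter), t = unname(ct$statistic), p = ct$p.value)
}

#' Full group-comparison report for one variable
#'
#' Runs the omnibus ANOVA, Levene's test, the robust Welch and
#' Brown-Forsythe tests, and both post hoc families, mirroring the layout
#' of a cohort descriptives table with robust-test footnotes.
#'
#' @inheritParams one_way_anova
#' @return A list with components `anova`, `levene`, `welch`,
#'   `brown_forsythe`, `lsd`, `games_howell`.
#' @export
compare_groups <- function(values, groups) {
  list(anova = one_way_anova(values, groups),
       levene = levene_test(values, groups),
       welch = welch_anova(values, groups),
       brown_forsythe = brown_forsythe(values, groups),
       lsd = lsd_posthoc(values, groups),
       games_howell = games_howell_posthoc(values, groups))
}

#' Render a p-value as in journal tables
#'
#' Three decimals, with values below 0.001 rendered as `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
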