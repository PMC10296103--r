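# Behavior partial least squares. The brain block is the participants x 152
# matrix of z-scored ROI metrics (76 T1 columns then 76 MD columns); the
# behavior block holds strength of attractions, degree of
# androphilia-gynephilia and age in months. Within each group, each behavior
# is correlated with every brain column; the stacked (groups x behaviors) x
# columns correlation matrix is decomposed by SVD into latent variables
# whose significance is assessed by permutation and whose salience
# stability by bootstrap resampling with Procrustes alignment.

#' z-score the columns of a brain matrix
#'
#' Converts each ROI-metric column to z-scores across all participants so
#' that metric-specific ranges (T1 in ms vs MD in mm^2/s) cannot dominate
#' the decomposition.
#'
#' @param x Numeric matrix (participants x columns).
#' @return Matrix of the same shape with column means 0 and SDs 1.
#' @export
zscore_columns <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, stats::sd)
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero)) {
    nm <- if (!is.null(colnames(x))) colnames(x)[zero[1L]] else zero[1L]
    stop("zero-variance column: ", nm)
  }
  scale(x)[, , drop = FALSE]
}

group_index_list <- function(groups) {
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups, levels = unique(groups))
  idx <- split(seq_along(groups), groups)
  if (any(lengths(idx) < 3L)) stop("each group needs at least 3 rows")
  idx
}

#' Group-stacked brain-behavior correlation matrix
#'
#' For each group and each behavior, the Pearson correlation of that
#' behavior with every brain column, computed within the group only. Rows
#' are stacked group-major: group 1's behaviors, then group 2's, then
#' group 3's.
#'
#' @param x Brain matrix (participants x columns), typically from
#'   [zscore_columns()].
#' @param y Behavior matrix (participants x behaviors), columns ordered
#'   (strength, degree, age). Correlation is scale-invariant, so behaviors
#'   need not be standardized.
#' @param groups Group labels aligned with the rows; stacking follows
#'   factor level order (or first appearance for character input).
#' @return A (groups x behaviors) x columns matrix with informative row
#'   names.
#' @export
cross_block <- function(x, y, groups) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) == length(groups))
  idx <- group_index_list(groups)
  blocks <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    sds <- apply(y[i, , drop = FALSE], 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance behavior within group ", g)
    r <- stats::cor(y[i, , drop = FALSE], x[i, , drop = FALSE])
    rownames(r) <- paste(g,
                         colnames(y) %||% paste0("b", seq_len(ncol(y))),
                         sep = ":")
    r
  })
  do.call(rbind, blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Singular value decomposition of the cross-block matrix
#'
#' Decomposes `R = V S t(U)` into latent variables: behavior/group
#' saliences `v` (rows of R), brain saliences `u` (columns of R) and
#' singular values `s`. Each latent variable's share of cross-block
#' covariance is `100 * s_i^2 / sum(s^2)`. The sign of each component is
#' fixed by requiring the largest-magnitude element of its `v` column to be
#' positive (ties broken by lowest row index).
#'
#' @param r Cross-block matrix from [cross_block()].
#' @return A list with `u` (columns x L), `s` (length L), `v` (rows x L),
#'   `covariance_pct` (length L, sums to 100).
#' @export
decompose <- function(r) {
  r <- as.matrix(r)
  if (any(!is.finite(r))) stop("cross-block matrix must be finite")
  sv <- svd(r)                      # r = sv$u diag(d) t(sv$v)
  v <- sv$u; u <- sv$v; s <- sv$d
  for (l in seq_along(s)) {
    top <- which.max(abs(v[, l]))   # which.max takes the first on ties
    if (v[top, l] < 0) { v[, l] <- -v[, l]; u[, l] <- -u[, l] }
  }
  rownames(v) <- rownames(r); rownames(u) <- colnames(r)
  list(u = u, s = s, v = v,
       covariance_pct = 100 * s^2 / sum(s^2))
}

#' Project participants onto the brain saliences
#'
#' Brain scores are the dot products of each participant's brain row with
#' the saliences of each latent variable.
#'
#' @param x Brain matrix (participants x columns).
#' @param u Brain saliences (columns x L).
#' @return participants x L score matrix.
#' @export
brain_scores <- function(x, u) {
  as.matrix(x) %*% as.matrix(u)
}

score_behavior_correlations <- function(scores, y, idx, lv) {
  # 9-vector (group-major, behaviors within group) of correlations between
  # LV brain scores and each behavior, within group
  out <- unlist(lapply(names(idx), function(g) {
    i <- idx[[g]]
    stats::cor(y[i, , drop = FALSE], scores[i, lv])
  }))
  names(out) <- unlist(lapply(names(idx), function(g)
    paste(g, colnames(y) %||% paste0("b", seq_len(ncol(y))), sep = ":")))
  out
}

#' Permutation test for latent-variable significance
#'
#' Rows of the brain block are permuted across the whole sample while the
#' behavior block and group assignment stay fixed; the cross-block matrix
#' and its SVD are recomputed for every permutation and each latent
#' variable's singular value is compared with the observed one. The
#' p-value is `(number of permuted s >= observed s + 1) / (n_perm + 1)`.
#'
#' @inheritParams cross_block
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param within_group Permute within groups only instead of across the
#'   whole sample (non-default exchangeability scheme).
#' @param observed_s Optional precomputed observed singular values.
#' @return A list with `perm_p` (per LV), `observed_s`, `n_perm`.
#' @export
permutation_test <- function(x, y, groups, n_perm = 1000, seed = NULL,
                             within_group = FALSE, observed_s = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; p is coarse")
  x <- as.matrix(x); y <- as.matrix(y)
  idx <- group_index_list(groups)
  if (is.null(observed_s)) observed_s <- decompose(cross_block(x, y, groups))$s
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  exceed <- numeric(length(observed_s))
  for (b in seq_len(n_perm)) {
    perm <- if (within_group) {
      p <- integer(n)
      for (i in idx) p[i] <- i[sample.int(length(i))]
      p
    } else sample.int(n)
    s_b <- svd(cross_block(x[perm, , drop = FALSE], y, groups),
               nu = 0, nv = 0)$d
    exceed <- exceed + (s_b >= observed_s)
  }
  list(perm_p = (exceed + 1) / (n_perm + 1), observed_s = observed_s,
       n_perm = n_perm)
}

procrustes_rotation <- function(v_boot, v_ref) {
  m <- crossprod(v_boot, v_ref)
  sv <- svd(m)
  sv$u %*% t(sv$v)
}

#' Bootstrap stability of brain saliences and behavior correlations
#'
#' Participants are resampled with replacement within each group (group
#' sizes preserved); the cross-block matrix and SVD are recomputed, and
#' each bootstrap solution is aligned to the original by the orthogonal
#' Procrustes rotation of its behavior-salience block (without alignment,
#' axis reflections inflate the standard errors). Outputs the bootstrap SE
#' of every brain salience, the bootstrap ratio (original salience / SE)
#' whose magnitude >= `stability_threshold` marks a stable contribution,
#' and percentile confidence intervals for the within-group brain-score x
#' behavior correlations.
#'
#' @inheritParams permutation_test
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param stability_threshold Bootstrap-ratio magnitude for stability
#'   (default 3).
#' @param decomposition Optional precomputed [decompose()] result.
#' @param conf_level Confidence level for the percentile intervals.
#' @return A list with `boot_se` (columns x L), `boot_ratio`,
#'   `stable_mask`, `corr_obs` (9 x L observed correlations), `corr_lo`,
#'   `corr_hi` (percentile bounds), `n_boot`, `n_redrawn`.
#' @export
bootstrap_pls <- function(x, y, groups, n_boot = 1000, seed = NULL,
                          stability_threshold = 3, decomposition = NULL,
                          conf_level = 0.95) {
  x <- as.matrix(x); y <- as.matrix(y)
  idx <- group_index_list(groups)
  if (is.null(decomposition))
    decomposition <- decompose(cross_block(x, y, groups))
  u0 <- decomposition$u; v0 <- decomposition$v
  L <- length(decomposition$s)
  scores0 <- brain_scores(x, u0)
  nb <- length(idx) * ncol(y)
  corr_obs <- vapply(seq_len(L), function(l)
    score_behavior_correlations(scores0, y, idx, l), numeric(nb))
  if (!is.null(seed)) set.seed(seed)
  glab <- factor(rep(names(idx), lengths(idx)), levels = names(idx))
  # the resample keeps group-contiguous ordering, so group index positions
  # within the resampled rows are fixed
  pos <- split(seq_along(glab), glab)
  u_sum <- matrix(0, nrow(u0), L); u_sq <- matrix(0, nrow(u0), L)
  corr_boot <- array(NA_real_, c(nb, L, n_boot))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      take <- unlist(lapply(idx, function(i) i[sample.int(length(i),
                                                          replace = TRUE)]))
      yb <- y[take, , drop = FALSE]
      sds <- unlist(lapply(pos, function(j)
        apply(yb[j, , drop = FALSE], 2L, stats::sd)))
      if (all(sds > 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    xb <- x[take, , drop = FALSE]
    dec_b <- decompose(cross_block(xb, yb, glab))
    q <- procrustes_rotation(dec_b$v, v0)
    ub <- dec_b$u %*% q
    u_sum <- u_sum + ub; u_sq <- u_sq + ub^2
    sb <- brain_scores(xb, ub)
    for (l in seq_len(L))
      corr_boot[, l, b] <- score_behavior_correlations(sb, yb, pos, l)
  }
  boot_se <- sqrt(pmax(u_sq / n_boot - (u_sum / n_boot)^2, 0)) *
    sqrt(n_boot / (n_boot - 1))
  boot_ratio <- u0 / boot_se
  alpha <- (1 - conf_level) / 2
  corr_lo <- apply(corr_boot, c(1L, 2L), stats::quantile, probs = alpha)
  corr_hi <- apply(corr_boot, c(1L, 2L), stats::quantile, probs = 1 - alpha)
  dimnames(corr_lo) <- dimnames(corr_hi) <- dimnames(corr_obs) <-
    list(rownames(v0), paste0("LV", seq_len(L)))
  dimnames(boot_ratio) <- list(rownames(u0), paste0("LV", seq_len(L)))
  list(boot_se = boot_se, boot_ratio = boot_ratio,
       stable_mask = abs(boot_ratio) >= stability_threshold,
       corr_obs = corr_obs, corr_lo = corr_lo, corr_hi = corr_hi,
       n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Behavior PLS with permutation and bootstrap inference
#'
#' End-to-end behavior PLS: column z-scoring of the brain block, the
#' group-stacked cross-block correlation matrix, its SVD, latent-variable
#' permutation p-values, and bootstrap salience stability with
#' brain-score-behavior correlation confidence intervals.
#'
#' @param brain Raw brain matrix (participants x 152; 76 T1 columns then 76
#'   MD columns). z-scored internally unless `zscore = FALSE`.
#' @param behavior Behavior matrix (participants x 3: strength, degree,
#'   age).
#' @param groups Group labels aligned with rows.
#' @param n_perm,n_boot Resampling sizes (defaults 1000).
#' @param seed Integer seed; the permutation and bootstrap streams are
#'   derived from it deterministically.
#' @param stability_threshold Bootstrap-ratio threshold (default 3).
#' @param within_group_perm Permutation exchangeability within groups only.
#' @param zscore z-score brain columns first (default `TRUE`).
#' @return A list of class `pls_result` combining [decompose()],
#'   [permutation_test()] and [bootstrap_pls()] outputs plus the brain
#'   scores of the original sample.
#' @export
bpls <- function(brain, behavior, groups, n_perm = 1000, n_boot = 1000,
                 seed = NULL, stability_threshold = 3,
                 within_group_perm = FALSE, zscore = TRUE) {
  x <- if (zscore) zscore_columns(brain) else as.matrix(brain)
  y <- as.matrix(behavior)
  dec <- decompose(cross_block(x, y, groups))
  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, 2L)
  perm <- permutation_test(x, y, groups, n_perm = n_perm,
                           seed = if (is.null(seed)) NULL else seeds[1L],
                           within_group = within_group_perm,
                           observed_s = dec$s)
  boot <- bootstrap_pls(x, y, groups, n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else seeds[2L],
                        stability_threshold = stability_threshold,
                        decomposition = dec)
  structure(c(dec,
              list(perm_p = perm$perm_p, n_perm = n_perm,
                   scores = brain_scores(x, dec$u)),
              boot,
              list(groups = groups, seed = seed,
                   stability_threshold = stability_threshold)),
            class = "pls_result")
}

#' Render a permutation p-value
#'
#' A p-value with zero exceedances is reported as below the resolution of
#' the permutation scheme rather than as 0.000.
#'
#' @param p Permutation p-value(s) of the form `(k + 1) / (n_perm + 1)`.
#' @param n_perm Number of permutations used.
#' @return Character vector.
#' @export
format_perm_p <- function(p, n_perm) {
  limit <- 1 / (n_perm + 1)
  ifelse(p <= limit, sprintf("<%.4f", limit), sprintf("%.4f", p))
}

#' Stable-ROI table for one latent variable
#'
#' Folds the 152-column stability mask back onto the 76 ROIs: one row per
#' ROI with hemisphere and region name and an x/- flag for each metric,
#' keeping only ROIs stable on at least one metric (the layout of a
#' stable-ROI summary table).
#'
#' @param result A `pls_result` from [bpls()].
#' @param lv Latent variable index (default 1).
#' @param lookup ROI lookup table, see [roi_lookup()]; must have columns
#'   `label`, `name`, `hemisphere`, `lobe`.
#' @return A data.frame with `hemisphere`, `name`, `lobe`, `t1`, `md`
#'   (`"x"` or `"-"`), plus logical `t1_stable`, `md_stable`.
#' @export
pls_report <- function(result, lv = 1L, lookup = roi_lookup()) {
  stopifnot(inherits(result, "pls_result"))
  mask <- result$stable_mask[, lv]
  n_roi <- length(mask) / 2L
  t1 <- mask[seq_len(n_roi)]
  md <- mask[n_roi + seq_len(n_roi)]
  out <- data.frame(
    hemisphere = lookup$hemisphere[seq_len(n_roi)],
    name = lookup$name[seq_len(n_roi)],
    lobe = lookup$lobe[seq_len(n_roi)],
    t1 = ifelse(t1, "x", "-"), md = ifelse(md, "x", "-"),
    t1_stable = unname(t1), md_stable = unname(md),
    stringsAsFactors = FALSE
  )
  out[out$t1_stable | out$md_stable, , drop = FALSE]
}
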