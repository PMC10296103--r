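# Two-level random-intercept regression of mean diffusivity on T1
# relaxation time: ROI observations nested in participants, fixed slope,
# random participant intercept, full maximum likelihood. Both variables are
# grand-standardized (across all observations) first, so the fixed slope is
# reported on the standardized scale.

#' Grand-standardize the predictor and outcome of a long ROI table
#'
#' z-scores each variable across ALL observations (not within participant),
#' because the model tests the overall T1-MD association across cortical
#' regions and participants.
#'
#' @param observations A data.frame with columns `participant`, `roi_id`,
#'   `predictor`, `outcome`.
#' @return The same data.frame with `predictor` and `outcome` z-scored.
#' @export
standardize_observations <- function(observations) {
  stopifnot(all(c("participant", "predictor", "outcome") %in%
                  names(observations)))
  for (v in c("predictor", "outcome")) {
    s <- stats::sd(observations[[v]])
    if (!is.finite(s) || s == 0) stop("zero variance in '", v, "'")
    observations[[v]] <- (observations[[v]] - mean(observations[[v]])) / s
  }
  observations
}

#' Fit the fixed-slope, random-intercept model
#'
#' Fits `outcome ~ predictor + (1 | participant)` by full maximum
#' likelihood (not REML) and reports the fixed slope with its Wald standard
#' error and two-sided normal-reference p-value, plus the variance
#' components. With `standardize = TRUE` (default) inputs are
#' grand-standardized first so the slope is the standardized estimate.
#'
#' @param observations Long data.frame with `participant`, `predictor`,
#'   `outcome`; each (participant, ROI) pair contributes one row.
#' @param standardize Grand-standardize before fitting.
#' @param reml Use REML instead of ML (default `FALSE`, matching the
#'   default of mainstream SEM software for this model family).
#' @return A list of class `mlm_fit`: `slope`, `se`, `z`, `p`, `intercept`,
#'   `var_intercept`, `var_residual`, `loglik`, `n_clusters`, `n_obs`,
#'   `converged`.
#' @export
fit_random_intercept <- function(observations, standardize = TRUE,
                                 reml = FALSE) {
  if (standardize) observations <- standardize_observations(observations)
  cl <- factor(observations$participant)
  if (nlevels(cl) < 2L) stop("need at least 2 clusters")
  if (min(table(cl)) < 2L) stop("need at least 2 observations per cluster")
  dat <- data.frame(y = observations$outcome, x = observations$predictor,
                    id = cl)
  fit <- lme4::lmer(y ~ x + (1 | id), data = dat, REML = reml,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "id"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    slope = co["x", "Estimate"], se = co["x", "Std. Error"],
    z = co["x", "t value"],
    p = 2 * stats::pnorm(-abs(co["x", "t value"])),
    intercept = co["(Intercept)", "Estimate"],
    var_intercept = var_int, var_residual = var_res,
    loglik = as.numeric(stats::logLik(fit)),
    n_clusters = nlevels(cl), n_obs = nrow(dat),
    converged = length(fit@optinfo$conv$lme4$messages) == 0L
  ), class = "mlm_fit")
}

#' Intraclass correlation of a random-intercept fit
#'
#' Share of total variance attributable to the between-participant
#' intercept: `var_intercept / (var_intercept + var_residual)`.
#'
#' @param fit An `mlm_fit` from [fit_random_intercept()].
#' @return The ICC in `[0, 1]`, or `NA` when both components are zero.
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  tot <- fit$var_intercept + fit$var_residual
  if (tot == 0) return(NA_real_)
  fit$var_intercept / tot
}

#' Profile log-likelihood of the random-intercept model
#'
#' Direct evaluation of the marginal Gaussian log-likelihood at given
#' variance components, with the fixed effects set to their GLS solution.
#' Used as an independent check that the fitted components sit at the
#' likelihood optimum; not the estimation route.
#'
#' @param observations As in [fit_random_intercept()] (already on the scale
#'   to be fitted).
#' @param var_intercept,var_residual Variance components to evaluate at.
#' @return The log-likelihood (fixed effects profiled out by GLS).
#' @export
mlm_loglik <- function(observations, var_intercept, var_residual) {
  cl <- factor(observations$participant)
  X <- cbind(1, observations$predictor)
  y <- observations$outcome
  # block-diagonal covariance: sigma2 I + tau2 J per cluster; use the
  # Sherman-Morrison form within clusters
  s2 <- var_residual; t2 <- var_intercept
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (g in levels(cl)) {
    i <- cl == g; ni <- sum(i)
    Xi <- X[i, , drop = FALSE]; yi <- y[i]
    a <- t2 / (s2 * (s2 + ni * t2))
    ViX <- Xi / s2 - a * matrix(colSums(Xi), ni, 2, byrow = TRUE)
    XtVX <- XtVX + crossprod(Xi, ViX)
    XtVy <- XtVy + crossprod(ViX, yi)
  }
  beta <- solve(XtVX, XtVy)
  r <- y - X %*% beta
  ll <- 0
  for (g in levels(cl)) {
    i <- cl == g; ni <- sum(i); ri <- r[i]
    a <- t2 / (s2 * (s2 + ni * t2))
    quad <- sum(ri^2) / s2 - a * sum(ri)^2
    logdet <- (ni - 1) * log(s2) + log(s2 + ni * t2)
    ll <- ll - 0.5 * (ni * log(2 * pi) + logdet + quad)
  }
  as.numeric(ll)
}

#' Assemble the long T1/MD table from two wide ROI matrices
#'
#' @param t1,md Numeric matrices (participants x ROIs) with aligned rows
#'   and columns.
#' @param participants Participant identifiers (row names used if missing).
#' @return A long data.frame with `participant`, `roi_id`, `predictor`
#'   (T1), `outcome` (MD).
#' @export
long_observations <- function(t1, md, participants = rownames(t1)) {
  stopifnot(identical(dim(t1), dim(md)))
  if (is.null(participants)) participants <- seq_len(nrow(t1))
  data.frame(
    participant = rep(participants, times = ncol(t1)),
    roi_id = rep(seq_len(ncol(t1)), each = nrow(t1)),
    predictor = as.vector(t1), outcome = as.vector(md)
  )
}
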