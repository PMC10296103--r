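# Seeded generators emulating the study conditions: a three-group
# adolescent cohort with the reported psychosexual score structure, ROI
# matrices with a planted latent brain-behavior effect shared by two of the
# three groups plus a participant-level T1-MD coupling, and small volumetric
# phantoms with analytically known T1 modes for exercising ROI extraction.

#' Derive independent sub-seeds from a master seed
#'
#' Fixed affine-modular scheme so that enabling or disabling one stage does
#' not perturb another stage's random stream. All derived seeds stay below
#' 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) %% 65536 * 32749 + seq_len(n) * 7919) %%
               2147483647L + 1)
}

# truncated normal whose *post-truncation* mean equals target_mean: the
# underlying location is solved by uniroot so that targets stated for a
# bounded scale are hit in expectation, not merely approached
trunc_normal_mean <- function(sd, lo, hi, target_mean) {
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean outside the attainable open interval")
  if (sd <= 0) stop("sd must be positive")
  tn_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    # far outside the interval the mass collapses onto the nearer bound
    if (!is.finite(z) || z < 1e-14)
      return(if (mu < (lo + hi) / 2) lo else hi)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  f <- function(mu) tn_mean(mu) - target_mean
  lo_mu <- target_mean - 8 * sd; hi_mu <- target_mean + 8 * sd
  while (f(lo_mu) > 0) lo_mu <- lo_mu - 8 * sd
  while (f(hi_mu) < 0) hi_mu <- hi_mu + 8 * sd
  stats::uniroot(f, c(lo_mu, hi_mu), tol = 1e-10)$root
}

rtrunc_normal <- function(n, mu, sd, lo, hi) {
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

# draw from a truncated normal with exact target mean after truncation
rtn_target <- function(n, target_mean, sd, lo, hi) {
  mu <- trunc_normal_mean(sd, lo, hi, target_mean)
  rtrunc_normal(n, mu, sd, lo, hi)
}

# draws with per-element truncation bounds sharing one underlying location,
# solved so the average post-truncation mean equals the target
rtn_target_varying <- function(target_mean, sd, lo, hi) {
  tn_mean1 <- function(mu, l, h) {
    a <- (l - mu) / sd; b <- (h - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (!is.finite(z) || z < 1e-14)
      return(if (mu < (l + h) / 2) l else h)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  f <- function(mu)
    mean(mapply(tn_mean1, mu, lo, hi)) - target_mean
  lo_mu <- target_mean - 8 * sd; hi_mu <- target_mean + 8 * sd
  tries <- 0L
  while (f(lo_mu) > 0 && tries < 20L) { lo_mu <- lo_mu - 8 * sd; tries <- tries + 1L }
  while (f(hi_mu) < 0 && tries < 40L) { hi_mu <- hi_mu + 8 * sd; tries <- tries + 1L }
  if (f(lo_mu) > 0 || f(hi_mu) < 0)
    stop("magnitude target unattainable given the phase draws")
  mu <- stats::uniroot(f, c(lo_mu, hi_mu), tol = 1e-9)$root
  rtrunc_normal(length(lo), mu, sd, lo, hi)
}

# 1-5 integer items around a latent scale mean, mean-preserving: each item
# latent is the scale mean plus a symmetric +/- perturbation clipped to the
# distance to the nearer scale bound (so no asymmetric truncation bias),
# then randomized-rounded to an integer (E[item | latent] = latent)
generate_items <- function(latent, n_items, item_sd) {
  n <- length(latent)
  out <- matrix(0L, n, n_items)
  for (i in seq_len(n)) {
    delta <- pmin(abs(stats::rnorm(n_items, 0, item_sd)),
                  max(latent[i] - 1, 0), max(5 - latent[i], 0))
    x <- pmin(pmax(latent[i] + sample(c(-1, 1), n_items, replace = TRUE) *
                     delta, 1), 5)
    f <- floor(x)
    out[i, ] <- as.integer(f + stats::rbinom(n_items, 1L,
                                             pmin(pmax(x - f, 0), 1)))
  }
  out
}

#' Cohort generator specification
#'
#' Defaults reproduce the study's three groups and their reported
#' psychosexual score moments: group sizes 14/15/17 (cisgender boys, GD
#' AFAB, cisgender girls), per-group age ranges in months, strength of
#' attractions (vector magnitude) means/SDs 3.25/1.28, 2.98/1.34,
#' 2.83/0.76, degree of androphilia-gynephilia (phase, degrees) 64.60/9.29,
#' 46.99/15.56, 30.94/13.18 and GIDYQ-AA regimes 4.91/0.12, 2.17/0.33,
#' 4.90/0.15.
#'
#' @param group_sizes Named integer vector of group sizes.
#' @param age_ranges List of per-group month ranges.
#' @param strength,degree,gidyq Lists of per-group `c(mean, sd)` targets.
#' @param item_sd_eros,item_sd_gidyq Item-level perturbation SDs.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    group_sizes = c(cis_boy = 14L, gd_afab = 15L, cis_girl = 17L),
    age_ranges = list(cis_boy = c(147L, 216L), gd_afab = c(162L, 216L),
                      cis_girl = c(152L, 214L)),
    strength = list(cis_boy = c(3.25, 1.28), gd_afab = c(2.98, 1.34),
                    cis_girl = c(2.83, 0.76)),
    degree = list(cis_boy = c(64.60, 9.29), gd_afab = c(46.99, 15.56),
                  cis_girl = c(30.94, 13.18)),
    gidyq = list(cis_boy = c(4.91, 0.12), gd_afab = c(2.17, 0.33),
                 cis_girl = c(4.90, 0.15)),
    item_sd_eros = 0.5, item_sd_gidyq = 0.3) {
  stopifnot(all(group_sizes >= 3L),
            identical(names(group_sizes), names(age_ranges)))
  structure(list(group_sizes = group_sizes, age_ranges = age_ranges,
                 strength = strength, degree = degree, gidyq = gidyq,
                 item_sd_eros = item_sd_eros,
                 item_sd_gidyq = item_sd_gidyq),
            class = "cohort_spec")
}

phase_limits <- function() {
  c(acos(5 / sqrt(26)), acos(1 / sqrt(26))) * 180 / pi  # ~11.31, 78.69
}

#' Generate a synthetic participant cohort with item-level responses
#'
#' Draws, per participant, a degree of androphilia-gynephilia (phase) and a
#' conditional strength (magnitude) from mean-corrected truncated normals
#' restricted to the attainable region of the 1-5 score plane, converts
#' them to latent androphilia/gynephilia means, and emits mean-preserving
#' integer item responses (8 + 8 EROS items, 27 GIDYQ-AA items) plus an age
#' in months uniform over the group's range. Deterministic under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list: `items` (item-level table suitable for
#'   [build_participants()]), `participants` (scored records), `truth`
#'   (latent per-participant values).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  lim <- phase_limits()
  rows <- lapply(names(spec$group_sizes), function(g) {
    n <- spec$group_sizes[[g]]
    th <- rtn_target(n, spec$degree[[g]][1L], spec$degree[[g]][2L],
                     lim[1L], lim[2L])
    thr <- th * pi / 180
    # attainable magnitude given the phase: both components must fall in
    # [1, 5]; a single underlying location is solved so the *marginal*
    # magnitude mean over the realized phases hits the group target
    m_lo <- pmax(1 / cos(thr), 1 / sin(thr))
    m_hi <- pmin(5 / cos(thr), 5 / sin(thr))
    m <- rtn_target_varying(spec$strength[[g]][1L],
                            spec$strength[[g]][2L], m_lo, m_hi)
    a <- m * cos(thr); g_lat <- m * sin(thr)
    q <- rtn_target(n, spec$gidyq[[g]][1L], spec$gidyq[[g]][2L], 1, 5)
    age <- spec$age_ranges[[g]][1L] +
      sample.int(diff(spec$age_ranges[[g]]) + 1L, n, replace = TRUE) - 1L
    list(group = g, a = a, g = g_lat, q = q, age = age)
  })
  truth <- do.call(rbind, lapply(rows, function(r)
    data.frame(group = r$group, androphilia = r$a, gynephilia = r$g,
               gidyq = r$q, age_months = r$age)))
  truth$id <- sprintf("P%03d", seq_len(nrow(truth)))
  items <- data.frame(id = truth$id, group = truth$group,
                      age_months = truth$age_months,
                      stringsAsFactors = FALSE)
  andro <- generate_items(truth$androphilia, 8L, spec$item_sd_eros)
  gyne <- generate_items(truth$gynephilia, 8L, spec$item_sd_eros)
  gid <- generate_items(truth$gidyq, 27L, spec$item_sd_gidyq)
  colnames(andro) <- eros_item_cols("andro")
  colnames(gyne) <- eros_item_cols("gyne")
  colnames(gid) <- gidyq_item_cols()
  items <- cbind(items, andro, gyne, gid)
  list(items = items, participants = build_participants(items),
       truth = truth)
}

#' Stable-ROI support pattern of the planted effect
#'
#' The default set of ROI-metric columns carrying the planted
#' brain-behavior effect: 29 T1 regions and 9 MD regions matching the
#' spatial pattern of the study's stable-ROI table.
#'
#' @return A list with integer label vectors `t1` and `md`.
#' @export
default_effect_support <- function() {
  lk <- roi_lookup()
  pick <- function(spec) {
    vapply(spec, function(s)
      lk$label[lk$name == s[[1L]] & lk$hemisphere == s[[2L]]], 0L)
  }
  t1 <- pick(list(
    list("Inferior Frontal Gyrus: Opercular Part", "L"),
    list("Inferior Frontal Gyrus: Triangular Part", "L"),
    list("Middle Frontal Gyrus", "L"),
    list("Precentral Gyrus", "L"),
    list("Rolandic Operculum", "L"),
    list("Superior Frontal Gyrus: Dorsolateral", "L"),
    list("Supplementary Motor Area", "L"),
    list("Angular Gyrus", "L"), list("Angular Gyrus", "R"),
    list("Postcentral Gyrus", "L"),
    list("Precuneus", "L"), list("Precuneus", "R"),
    list("Heschl Gyrus", "L"), list("Heschl Gyrus", "R"),
    list("Inferior Temporal Gyrus", "R"),
    list("Middle Temporal Gyrus", "L"), list("Middle Temporal Gyrus", "R"),
    list("Superior Temporal Gyrus", "L"),
    list("Superior Temporal Gyrus", "R"),
    list("Cuneus", "L"), list("Cuneus", "R"),
    list("Inferior Occipital Gyrus", "L"),
    list("Inferior Occipital Gyrus", "R"),
    list("Lingual Gyrus", "L"),
    list("Middle Occipital Gyrus", "L"),
    list("Middle Occipital Gyrus", "R"),
    list("Superior Occipital Gyrus", "L"),
    list("Superior Occipital Gyrus", "R"),
    list("Median Cingulate and Paracingulate Gyri", "R")))
  md <- pick(list(
    list("Middle Frontal Gyrus: Orbital Part", "L"),
    list("Rolandic Operculum", "L"),
    list("Angular Gyrus", "L"),
    list("Postcentral Gyrus", "L"),
    list("Supramarginal Gyrus", "L"), list("Supramarginal Gyrus", "R"),
    list("Heschl Gyrus", "L"),
    list("Middle Temporal Gyrus", "L"),
    list("Superior Temporal Gyrus", "L")))
  list(t1 = t1, md = md)
}

#' Planted-effect specification for the brain generator
#'
#' @param affected_groups Groups carrying the brain-behavior effect
#'   (default cisgender boys and GD AFAB).
#' @param support ROI-metric columns loading on the effect, see
#'   [default_effect_support()].
#' @param effect_size Standardized loading of affected columns on the
#'   behavior composite.
#' @param behavior_weights Weights of (strength, degree, age) in the
#'   behavior composite; normalized internally.
#' @param noise_sd Multiplier on all observation-level noise terms
#'   (default 1; 0 gives a deterministic affine map of the behavior
#'   composite, useful for exactness checks).
#' @param coupling_slope Standardized fixed slope of MD on T1 induced at
#'   the observation level (default 0.089).
#' @param md_icc Intraclass correlation of the MD residual intercept
#'   (default 0.5).
#' @param t1_icc Participant-intercept share of T1 variance (default 0.3).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(affected_groups = c("cis_boy", "gd_afab"),
                        support = default_effect_support(),
                        effect_size = 0.5,
                        behavior_weights = c(strength = 1, degree = 1,
                                             age = 1),
                        noise_sd = 1,
                        coupling_slope = 0.089, md_icc = 0.5,
                        t1_icc = 0.3) {
  stopifnot(abs(coupling_slope) < 1, md_icc >= 0, md_icc <= 1,
            effect_size >= 0, noise_sd >= 0)
  w <- behavior_weights / sqrt(sum(behavior_weights^2))
  structure(list(affected_groups = affected_groups, support = support,
                 effect_size = effect_size, behavior_weights = w,
                 noise_sd = noise_sd, coupling_slope = coupling_slope,
                 md_icc = md_icc, t1_icc = t1_icc),
            class = "effect_spec")
}

#' Generate a 152-column ROI table with a planted brain-behavior effect
#'
#' Each T1 column is a participant intercept plus noise on the z scale; in
#' affected groups, columns in the effect support additionally load on a
#' behavior composite (z-scored strength, degree and age combined with the
#' configured weights) with a negative sign for T1 (shorter T1 with older
#' age and stronger gynephilia) and positive for MD. MD columns are
#' generated from the model `MD = beta * T1 + intercept + residual` with
#' the configured standardized slope and intercept ICC, so the two metrics
#' share participant-level structure. Values are mapped to plausible
#' physical scales (T1 in ms, MD in mm^2/s) per ROI.
#'
#' @param participants Scored participant table from [generate_cohort()]
#'   or [build_participants()] (needs `group`, `strength`, `degree`,
#'   `age_months`).
#' @param effect An [effect_spec()]; set `effect_size = 0` for a null
#'   brain.
#' @param seed Integer seed.
#' @return A list: `brain` (participants x 152 matrix, columns
#'   `t1_1..t1_76` then `md_1..md_76`), `behavior` (participants x 3
#'   matrix: strength, degree, age), `truth` (planted column indices,
#'   composite scores and intercepts).
#' @export
generate_brain <- function(participants, effect = effect_spec(),
                           seed = 1L) {
  stopifnot(inherits(effect, "effect_spec"))
  set.seed(seed)
  n <- nrow(participants)
  behavior <- cbind(strength = participants$strength,
                    degree = participants$degree,
                    age = as.numeric(participants$age_months))
  if (anyNA(behavior))
    warning("participants with missing behavior values present; ",
            "exclude them before PLS")
  eta <- as.vector(scale(behavior) %*% effect$behavior_weights)
  affected <- as.numeric(participants$group %in% effect$affected_groups)
  b_i <- stats::rnorm(n)   # shared participant factor (T1 intercept)
  u_i <- stats::rnorm(n)   # MD-specific participant intercept
  beta <- effect$coupling_slope
  v_int <- (1 - beta^2) * effect$md_icc
  v_res <- (1 - beta^2) * (1 - effect$md_icc)
  c_eff <- effect$effect_size
  ns <- effect$noise_sd
  n_roi <- 76L
  t1_z <- matrix(stats::rnorm(n * n_roi), n, n_roi) *
    (ns * sqrt(1 - effect$t1_icc)) + sqrt(effect$t1_icc) * b_i
  t1_z[, effect$support$t1] <- t1_z[, effect$support$t1] -
    c_eff * (eta * affected)
  md_z <- beta * t1_z +
    matrix(stats::rnorm(n * n_roi), n, n_roi) * (ns * sqrt(v_res)) +
    (ns * sqrt(v_int)) * u_i
  md_z[, effect$support$md] <- md_z[, effect$support$md] +
    c_eff * (eta * affected)
  # flat per-metric baselines: between-ROI mean differences would enter the
  # grand-standardized T1-MD model as spurious covariance, so the coupling
  # is planted purely at the observation level
  brain <- cbind(1700 + 150 * t1_z, 9.5e-4 + 1e-4 * md_z)
  colnames(brain) <- c(paste0("t1_", seq_len(n_roi)),
                       paste0("md_", seq_len(n_roi)))
  rownames(brain) <- participants$id
  planted_cols <- c(effect$support$t1, n_roi + effect$support$md)
  list(brain = brain, behavior = behavior,
       truth = list(planted_cols = sort(planted_cols), eta = eta,
                    affected = affected, b = b_i, u = u_i))
}

#' Simulate long T1/MD observations from the random-intercept model
#'
#' Direct simulation of `MD = slope * T1 + intercept_i + residual` with
#' standardized variables: T1 is standard normal, the intercept and
#' residual variances are `(1 - slope^2) * icc` and
#' `(1 - slope^2) * (1 - icc)`, so MD has unit variance and the
#' standardized fixed slope equals `slope` by construction. Used for
#' parameter-recovery checks of the multilevel fit.
#'
#' @param n_clusters Number of participants (default 46).
#' @param n_per Cluster size (default 76 ROIs).
#' @param slope True standardized slope (default 0.089).
#' @param icc Intercept ICC (default 0.5).
#' @param seed Integer seed.
#' @return A long data.frame: `participant`, `roi_id`, `predictor`,
#'   `outcome`.
#' @export
simulate_t1md <- function(n_clusters = 46L, n_per = 76L, slope = 0.089,
                          icc = 0.5, seed = 1L) {
  stopifnot(abs(slope) < 1, icc >= 0, icc < 1)
  set.seed(seed)
  v_int <- (1 - slope^2) * icc
  v_res <- (1 - slope^2) * (1 - icc)
  id <- rep(seq_len(n_clusters), each = n_per)
  x <- stats::rnorm(n_clusters * n_per)
  y <- slope * x + rep(stats::rnorm(n_clusters, sd = sqrt(v_int)),
                       each = n_per) +
    stats::rnorm(n_clusters * n_per, sd = sqrt(v_res))
  data.frame(participant = id, roi_id = rep(seq_len(n_per), n_clusters),
             predictor = x, outcome = y)
}

#' Generate volumetric phantoms with known ROI summaries
#'
#' Lays out one cube per ROI on a regular lattice inside the grid. Each
#' cube has a gray-matter core (probability 0.95) surrounded by a
#' sub-threshold rind (probability 0.30, same label) whose metric values
#' are deliberately extreme, so any leak of the gray-matter gate corrupts
#' the summaries detectably. Core T1 values are drawn from a shifted gamma
#' distribution with analytically known density mode via stratified
#' (quantile-spaced) sampling, so the planted mode is recovered sharply;
#' core MD is constant per ROI.
#'
#' @param n_rois Number of ROIs (default 76).
#' @param grid Grid dimensions (default `c(48, 48, 48)`).
#' @param seed Integer seed (controls the within-core ordering of the
#'   stratified draws).
#' @return A list: `t1`, `md` (each a [volume_set()]), `truth`
#'   (data.frame with `roi_id`, `t1_mode`, `t1_shape`, `md_value`,
#'   `n_core`).
#' @export
generate_phantom <- function(n_rois = 76L, grid = c(48L, 48L, 48L),
                             seed = 1L) {
  slot <- c(12L, 12L, 9L)
  slots_per_dim <- grid %/% slot
  if (prod(slots_per_dim) < n_rois)
    stop("grid too small for ", n_rois, " ROIs")
  set.seed(seed)
  lab <- array(0L, grid); gm <- array(0, grid)
  t1m <- array(0, grid); mdm <- array(0, grid)
  truth <- vector("list", n_rois)
  roi <- 0L
  for (k in seq_len(slots_per_dim[3L])) for (j in seq_len(slots_per_dim[2L]))
    for (i in seq_len(slots_per_dim[1L])) {
      if (roi >= n_rois) break
      roi <- roi + 1L
      o <- (c(i, j, k) - 1L) * slot
      cube <- list(o[1L] + 2:11, o[2L] + 2:11, o[3L] + 2:8)   # 10 x 10 x 7
      core <- list(o[1L] + 3:10, o[2L] + 3:10, o[3L] + 3:7)   # 8 x 8 x 5
      lab[cube[[1L]], cube[[2L]], cube[[3L]]] <- roi
      gm[cube[[1L]], cube[[2L]], cube[[3L]]] <- 0.30          # rind
      gm[core[[1L]], core[[2L]], core[[3L]]] <- 0.95
      shape <- 4L + (roi %% 5L)
      shift <- 1200 + 8 * roi
      mode_true <- shift + (shape - 1) * 40
      n_core <- 8L * 8L * 5L
      u <- (sample.int(n_core) - 0.5) / n_core
      vals <- shift + stats::qgamma(u, shape = shape, scale = 40)
      t1_core <- array(vals, dim = c(8L, 8L, 5L))
      # extreme rind values: counting them would visibly shift summaries
      t1m[cube[[1L]], cube[[2L]], cube[[3L]]] <- 4900
      t1m[core[[1L]], core[[2L]], core[[3L]]] <- t1_core
      md_val <- 6e-4 + 4e-5 * roi
      mdm[cube[[1L]], cube[[2L]], cube[[3L]]] <- 3.9e-3
      mdm[core[[1L]], core[[2L]], core[[3L]]] <- md_val
      truth[[roi]] <- data.frame(roi_id = roi, t1_mode = mode_true,
                                 t1_shape = shape, md_value = md_val,
                                 n_core = n_core)
    }
  list(t1 = volume_set(t1m, gm, lab), md = volume_set(mdm, gm, lab),
       truth = do.call(rbind, truth))
}

#' Write a phantom volume set to NIfTI files
#'
#' @param vols A [volume_set()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths (metric, gm, labels).
#' @export
write_volume_set <- function(vols, dir, prefix = "phantom") {
  stopifnot(inherits(vols, "volume_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("metric", "gm", "labels"), ".nii"))
  RNifti::writeNifti(RNifti::asNifti(vols$metric), paths[1L])
  RNifti::writeNifti(RNifti::asNifti(vols$gm), paths[2L])
  RNifti::writeNifti(RNifti::asNifti(vols$labels), paths[3L])
  invisible(paths)
}
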