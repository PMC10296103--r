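test_that("sub-seed derivation is deterministic and bounded", {
  expect_identical(derive_seeds(42L, 3L), derive_seeds(42L, 3L))
  s <- derive_seeds(123456L, 10L)
  expect_true(all(s > 0 & s < 2^31))
  expect_equal(length(unique(s)), 10L)
  expect_false(any(derive_seeds(1L, 3L) == derive_seeds(2L, 3L)))
})

test_that("cohort generation is a pure function of spec and seed", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  expect_identical(a$items, b$items)
  expect_identical(a$participants, b$participants)
  c <- generate_cohort(seed = 6)
  expect_false(identical(a$items, c$items))
})

test_that("generated cohorts respect the scale, age and flag structure", {
  cc <- generate_cohort(seed = 8)
  p <- cc$participants
  expect_equal(nrow(p), 46L)
  expect_equal(unname(table(p$group)[c("cis_boy", "gd_afab", "cis_girl")]),
               c(14L, 15L, 17L), ignore_attr = TRUE)
  items <- as.matrix(cc$items[, grep("^(eros|gidyq)", names(cc$items))])
  expect_true(all(items %in% 1:5))
  sp <- cohort_spec()
  for (g in names(sp$group_sizes)) {
    ages <- p$age_months[p$group == g]
    expect_true(all(ages >= sp$age_ranges[[g]][1] &
                      ages <= sp$age_ranges[[g]][2]))
  }
  # screening flag separates the GD group from cisgender groups
  expect_gte(mean(p$gd_flag[p$group == "gd_afab"]), 0.9)
  expect_equal(mean(p$gd_flag[p$group != "gd_afab"]), 0)
})

test_that("large cohorts hit the configured group moments", {
  sp <- cohort_spec(group_sizes = c(cis_boy = 500L, gd_afab = 500L,
                                    cis_girl = 500L))
  cc <- generate_cohort(sp, seed = 9)
  p <- cc$participants
  for (g in names(sp$group_sizes)) {
    sub <- p[p$group == g, ]
    tol_deg <- 2 * sp$degree[[g]][2] / sqrt(500)
    tol_str <- 2 * sp$strength[[g]][2] / sqrt(500)
    tol_gid <- 2 * sp$gidyq[[g]][2] / sqrt(500) + 0.02
    expect_lt(abs(mean(sub$degree) - sp$degree[[g]][1]), tol_deg)
    expect_lt(abs(mean(sub$strength) - sp$strength[[g]][1]), tol_str)
    expect_lt(abs(mean(sub$gidyq_mean) - sp$gidyq[[g]][1]), tol_gid)
  }
  # derived scores stay inside the attainable polar region
  expect_true(all(p$strength >= sqrt(2) & p$strength <= sqrt(50)))
  expect_true(all(p$degree > 11.3 & p$degree < 78.7))
})

test_that("unattainable cohort targets are rejected", {
  expect_error(generate_cohort(cohort_spec(
    gidyq = list(cis_boy = c(5.5, 0.1), gd_afab = c(2.17, 0.33),
                 cis_girl = c(4.9, 0.15))), seed = 1),
    "outside the attainable")
})

test_that("the default effect support matches the 29 + 9 stable pattern", {
  sup <- default_effect_support()
  expect_length(sup$t1, 29L)
  expect_length(sup$md, 9L)
  expect_true(all(sup$t1 %in% 1:76) && all(sup$md %in% 1:76))
  expect_false(anyDuplicated(sup$t1) > 0)
  lk <- roi_lookup()
  expect_true("Rolandic Operculum" %in% lk$name[lk$label %in% sup$t1])
})

test_that("zero-noise planted columns are affine images of the composite", {
  cc <- generate_cohort(seed = 10)
  ef <- effect_spec(noise_sd = 0, t1_icc = 0, effect_size = 0.7)
  gb <- generate_brain(cc$participants, ef, seed = 11)
  j <- ef$support$t1[1]
  aff <- gb$truth$affected == 1
  x <- gb$brain[aff, j]
  z <- gb$truth$eta[aff]
  fit <- lm(x ~ z)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(unname(coef(fit)[2]), -0.7 * 150, tolerance = 1e-8)
  # unaffected group: flat column
  expect_lt(sd(gb$brain[!aff, j]), 1e-10)
})

test_that("brain generation is seed-deterministic and z-scorable", {
  cc <- generate_cohort(seed = 12)
  a <- generate_brain(cc$participants, seed = 13)
  b <- generate_brain(cc$participants, seed = 13)
  expect_identical(a$brain, b$brain)
  expect_equal(dim(a$brain), c(46L, 152L))
  expect_silent(zscore_columns(a$brain))
  expect_equal(length(a$truth$planted_cols), 38L)
})

test_that("with the effect off the T1-MD coupling is recovered", {
  sp <- cohort_spec(group_sizes = c(cis_boy = 20L, gd_afab = 20L,
                                    cis_girl = 20L))
  cc <- generate_cohort(sp, seed = 14)
  gb <- generate_brain(cc$participants, effect_spec(effect_size = 0),
                       seed = 15)
  obs <- long_observations(gb$brain[, 1:76], gb$brain[, 77:152],
                           cc$participants$id)
  fit <- fit_random_intercept(obs)
  expect_lt(abs(fit$slope - 0.089), 2 * fit$se)
  expect_lt(abs(icc(fit) - 0.5), 0.15)
})

test_that("simulate_t1md matches its nominal moments", {
  obs <- simulate_t1md(n_clusters = 200, n_per = 40, slope = 0.3,
                       icc = 0.4, seed = 16)
  expect_equal(sd(obs$outcome), 1, tolerance = 0.03)
  expect_lt(abs(cor(obs$predictor, obs$outcome) - 0.3), 0.05)
  expect_identical(obs, simulate_t1md(n_clusters = 200, n_per = 40,
                                      slope = 0.3, icc = 0.4, seed = 16))
})

test_that("phantom ROI modes and MD constants are planted as documented", {
  ph <- generate_phantom(n_rois = 12L, grid = c(48L, 36L, 9L), seed = 17)
  expect_equal(nrow(ph$truth), 12L)
  # analytic mode of the shifted gamma: shift + (shape - 1) * scale
  expect_equal(ph$truth$t1_mode,
               1200 + 8 * (1:12) + (ph$truth$t1_shape - 1) * 40)
  # rind voxels exist, carry the label, and sit below the gate
  lab1 <- ph$t1$labels == 1L
  expect_true(any(ph$t1$gm[lab1] <= 0.40))
  expect_true(any(ph$t1$gm[lab1] > 0.40))
  expect_error(generate_phantom(n_rois = 80L, grid = c(24L, 24L, 9L)),
               "too small")
})

test_that("phantom NIfTI output is byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  p1 <- write_volume_set(generate_phantom(4L, c(24L, 24L, 9L), seed = 18)$t1,
                         file.path(dir, "a"))
  p2 <- write_volume_set(generate_phantom(4L, c(24L, 24L, 9L), seed = 18)$t1,
                         file.path(dir, "b"))
  for (k in 1:3)
    expect_identical(unname(tools::md5sum(p1[k])),
                     unname(tools::md5sum(p2[k])))
})
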