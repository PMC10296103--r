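#!/usr/bin/env Rscript
# Stage 5: behavior PLS of the 152 ROI-metric columns against strength,
# degree and age within the three groups: permutation significance (1000),
# bootstrap salience stability (1000, |ratio| >= 3) and 95% CIs for the
# brain-score correlations.

suppressPackageStartupMessages(library(cortexmicro))
seed <- 1L
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(seed = seed, stages = "pls",
                    n_perm = 1000L, n_boot = 1000L)
pls <- res$pls
lv <- data.frame(lv = 1:9, s = round(pls$s, 3),
                 covariance_pct = round(pls$covariance_pct, 2),
                 perm_p = format_perm_p(pls$perm_p, pls$n_perm))
write.csv(lv, "results/pls_latent_variables.csv", row.names = FALSE)
ci <- data.frame(row = rownames(pls$corr_obs),
                 r = round(pls$corr_obs[, 1], 3),
                 lo = round(pls$corr_lo[, 1], 3),
                 hi = round(pls$corr_hi[, 1], 3))
write.csv(ci, "results/lv1_behavior_correlations.csv", row.names = FALSE)
write.csv(pls_report(pls), "results/lv1_stable_rois.csv", row.names = FALSE)

cat("Latent variables:\n"); print(lv[1:3, ], row.names = FALSE)
cat("\nLV1 brain-score correlations (95% bootstrap CIs):\n")
print(ci, row.names = FALSE)
n_stable <- colSums(matrix(pls$stable_mask[, 1], ncol = 2))
cat(sprintf("\nStable columns on LV1: %d T1, %d MD\n",
            n_stable[1], n_stable[2]))
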