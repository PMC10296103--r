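#!/usr/bin/env Rscript
# Stage 2: exercise ROI extraction on a volumetric phantom with known
# ground truth: spline-fit histogram modes for T1 and gated means for MD,
# for all 76 cortical ROIs.

suppressPackageStartupMessages(library(cortexmicro))
seed <- 1L
dir.create("results", showWarnings = FALSE)

ph <- generate_phantom(n_rois = 76L, seed = derive_seeds(seed, 4L)[4L])
t1 <- extract_all(ph$t1, "t1")
md <- extract_all(ph$md, "md")
summary_tab <- merge(
  data.frame(roi_id = t1$roi_id, t1_mode = t1$value,
             n_voxels = t1$n_voxels),
  data.frame(roi_id = md$roi_id, md_mean = md$value))
summary_tab <- merge(summary_tab, ph$truth[c("roi_id", "t1_mode", "md_value")],
                     by = "roi_id", suffixes = c("_est", "_true"))
write.csv(summary_tab, "results/phantom_roi_summaries.csv",
          row.names = FALSE)

err <- abs(summary_tab$t1_mode_est - summary_tab$t1_mode_true)
cat("T1 mode recovery over 76 ROIs: max |error| =", max(err),
    "ms (bin width 30 ms)\n")
cat("MD means recovered exactly:",
    all(summary_tab$md_mean == summary_tab$md_value), "\n")
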