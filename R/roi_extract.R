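# ROI-level reduction of volumetric metric maps. Cortical gray-matter voxels
# are selected per atlas region (gray-matter probability strictly > 0.40);
# T1 relaxation time is summarized by the peak of a cubic spline fitted to
# the ROI histogram (500-5000 ms, 30 ms bins) because partial-volume effects
# skew T1 distributions positively, and mean diffusivity by the arithmetic
# mean of values inside the plotted range (0.0005-0.004 mm^2/s).

#' Default histogram/gating settings for ROI extraction
#'
#' @return A list with elements `gm_threshold` (0.40), `t1_range`
#'   (500-5000 ms), `t1_bin` (30 ms), `md_range` (0.0005-0.004 mm^2/s),
#'   `md_bin` (5e-5 mm^2/s, i.e. a width of 50 in the map's native
#'   1e-6 mm^2/s unit), `md_gate` (apply the histogram range as an outlier
#'   gate before averaging MD) and `min_voxels` (minimum voxel count for a
#'   usable ROI summary).
#' @export
roi_settings <- function() {
  list(gm_threshold = 0.40,
       t1_range = c(500, 5000), t1_bin = 30,
       md_range = c(5e-4, 4e-3), md_bin = 5e-5,
       md_gate = TRUE, min_voxels = 10L)
}

#' Bundle co-registered volumes for ROI extraction
#'
#' @param metric_map 3-D array of metric values (T1 in ms or MD in mm^2/s).
#' @param gm_prob_map 3-D array of gray-matter probabilities in `[0, 1]`.
#' @param label_map 3-D integer array of atlas labels (0 = background,
#'   1..n_rois).
#' @return A `volume_set` list; all grids must share dimensions.
#' @export
volume_set <- function(metric_map, gm_prob_map, label_map) {
  if (!identical(dim(metric_map), dim(gm_prob_map)) ||
      !identical(dim(metric_map), dim(label_map)))
    stop("metric, gray-matter and label grids must share dimensions")
  if (any(gm_prob_map < 0 | gm_prob_map > 1, na.rm = TRUE))
    stop("gray-matter probabilities must lie in [0, 1]")
  structure(list(metric = metric_map, gm = gm_prob_map,
                 labels = label_map), class = "volume_set")
}

#' Read a volume set from NIfTI files
#'
#' @param metric_path,gm_path,label_path Paths to NIfTI-1 volumes on a
#'   common grid.
#' @return A [volume_set()].
#' @export
read_volume_set <- function(metric_path, gm_path, label_path) {
  rd <- function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  }
  volume_set(rd(metric_path), rd(gm_path), rd(label_path))
}

#' Select gray-matter voxel values for one ROI
#'
#' Returns the metric values at voxels carrying the ROI label whose
#' gray-matter probability is strictly greater than the threshold; voxels at
#' exactly the threshold are excluded.
#'
#' @param vols A [volume_set()].
#' @param roi_id Integer atlas label.
#' @param gm_threshold Gray-matter probability gate (default 0.40).
#' @return Numeric vector of metric values (length 0 if no voxel qualifies).
#' @export
select_gm_voxels <- function(vols, roi_id, gm_threshold = 0.40) {
  stopifnot(inherits(vols, "volume_set"))
  vols$metric[vols$labels == roi_id & vols$gm > gm_threshold]
}

#' Histogram of metric values over an open interval
#'
#' Bins values strictly inside `(lo, hi)` into consecutive bins of width
#' `bin_width` starting at `lo`; a final partial bin is retained when the
#' range is not an exact multiple of the width. Values at or outside the
#' interval endpoints are excluded.
#'
#' @param values Numeric vector.
#' @param lo,hi Open-interval bounds, `hi > lo`.
#' @param bin_width Positive bin width in the metric's units.
#' @param roi_id,metric Optional identifiers carried through for reporting.
#' @return A `roi_histogram` list with `breaks` (bin edges), `counts`,
#'   `mids` (bin centers), `n` (retained values), `roi_id`, `metric`.
#' @export
build_histogram <- function(values, lo, hi, bin_width,
                            roi_id = NA_integer_, metric = NA_character_) {
  stopifnot(hi > lo, bin_width > 0)
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  x <- values[!is.na(values) & values > lo & values < hi]
  # bins are (lo, lo+w], (lo+w, lo+2w], ...; the open lower end excludes lo
  idx <- findInterval(x, breaks, left.open = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 n = length(x), roi_id = roi_id, metric = metric),
            class = "roi_histogram")
}

#' T1 mode of an ROI via a spline fitted to its histogram
#'
#' Fits a cubic interpolating spline through the (bin center, count) pairs
#' and returns the abscissa of its maximum on a 1 ms evaluation grid over
#' the occupied histogram support. With fewer than four bins of nonzero
#' count the spline is unreliable and the center of the max-count bin is
#' returned with a warning.
#'
#' @param hist A `roi_histogram` from [build_histogram()].
#' @param grid_step Evaluation grid step in metric units (default 1, i.e.
#'   1 ms for T1).
#' @return The metric value at the histogram peak, or `NA_real_` for an
#'   empty histogram.
#' @export
t1_mode <- function(hist, grid_step = 1) {
  stopifnot(inherits(hist, "roi_histogram"))
  if (hist$n == 0L) return(NA_real_)
  nz <- which(hist$counts > 0L)
  if (length(nz) < 4L) {
    warning("fewer than 4 occupied bins; falling back to max-count bin center")
    return(hist$mids[which.max(hist$counts)])
  }
  # restrict to the occupied support so empty flanking bins cannot pull the
  # spline into extrapolated oscillations
  keep <- seq(min(nz), max(nz))
  f <- stats::splinefun(hist$mids[keep], hist$counts[keep], method = "fmm")
  grid <- seq(hist$mids[keep[1L]], hist$mids[keep[length(keep)]],
              by = grid_step)
  grid[which.max(f(grid))]
}

#' Mean diffusivity of an ROI
#'
#' Arithmetic mean of the selected MD values; values outside the open range
#' `(lo, hi)` are treated as outliers and dropped first (disable with
#' `gate = FALSE`).
#'
#' @param values MD values from [select_gm_voxels()], in mm^2/s.
#' @param lo,hi Outlier gate bounds (defaults 0.0005 and 0.004 mm^2/s).
#' @param gate Apply the range gate before averaging.
#' @return Mean MD, or `NA_real_` when no value survives.
#' @export
md_mean <- function(values, lo = 5e-4, hi = 4e-3, gate = TRUE) {
  x <- values[!is.na(values)]
  if (gate) x <- x[x > lo & x < hi]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Extract one scalar per atlas ROI from a volume set
#'
#' Applies the gray-matter gate per ROI and summarizes the metric: T1 by the
#' spline-fit histogram mode, MD by the (gated) mean. ROIs absent from the
#' label map, or with fewer than `settings$min_voxels` qualifying voxels,
#' are reported with `NA` value and flagged.
#'
#' @param vols A [volume_set()].
#' @param metric `"t1"` or `"md"`.
#' @param participant Identifier carried into the output.
#' @param n_rois Number of atlas labels expected (default 76).
#' @param settings Extraction settings, see [roi_settings()].
#' @return A data.frame with one row per ROI: `participant`, `roi_id`,
#'   `metric`, `value`, `n_voxels`, `flagged`.
#' @export
extract_all <- function(vols, metric = c("t1", "md"), participant = NA,
                        n_rois = 76L, settings = roi_settings()) {
  metric <- match.arg(metric)
  stopifnot(inherits(vols, "volume_set"))
  present <- sort(unique(as.integer(vols$labels)))
  present <- present[present > 0L]
  missing_labels <- setdiff(seq_len(n_rois), present)
  if (length(missing_labels))
    warning("labels absent from label map: ",
            paste(missing_labels, collapse = ", "))
  rows <- lapply(seq_len(n_rois), function(roi) {
    vals <- select_gm_voxels(vols, roi, settings$gm_threshold)
    n <- length(vals)
    if (n < settings$min_voxels)
      return(data.frame(participant = participant, roi_id = roi,
                        metric = metric, value = NA_real_, n_voxels = n,
                        flagged = TRUE))
    value <- if (metric == "t1") {
      h <- build_histogram(vals, settings$t1_range[1], settings$t1_range[2],
                           settings$t1_bin, roi_id = roi, metric = "t1")
      t1_mode(h)
    } else {
      md_mean(vals, settings$md_range[1], settings$md_range[2],
              gate = settings$md_gate)
    }
    data.frame(participant = participant, roi_id = roi, metric = metric,
               value = value, n_voxels = n, flagged = is.na(value))
  })
  do.call(rbind, rows)
}

#' Atlas lookup table for the 76 cortical ROIs
#'
#' Reads the bundled label table mapping integer labels 1..76 to cortical
#' region name, hemisphere and lobe (38 bilateral regions of the AAL
#' cortical parcellation, subcortical structures excluded).
#'
#' @return A data.frame with columns `label`, `name`, `hemisphere`, `lobe`.
#' @export
roi_lookup <- function() {
  path <- system.file("extdata", "aal_cortical_rois.tsv",
                      package = "cortexmicro", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
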