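# Orchestration and shared I/O: canonical column layout for the assembled
# analysis table, validation on ingest, and a single driver that runs the
# synthetic (or ingested) cohort through scoring, group statistics, the
# T1-MD multilevel model and behavior PLS with one master seed.

brain_col_names <- function(n_roi = 76L)
  c(paste0("t1_", seq_len(n_roi)), paste0("md_", seq_len(n_roi)))

#' Validate and canonicalize an assembled ROI/behavior table
#'
#' Accepts a data.frame or CSV path holding one row per participant with
#' identifier, group, the three behavior variables and the 152 ROI-metric
#' columns (`t1_1` ... `t1_76`, `md_1` ... `md_76`, any column order).
#' Rows are reordered so groups are contiguous (order of first appearance);
#' columns are put in canonical order. Participants with missing behavior
#' values are dropped with a warning (they cannot enter PLS).
#'
#' @param x Data frame or path to a CSV file.
#' @param col_map Named character vector mapping canonical names
#'   (`participant`, `group`, `strength`, `degree`, `age`) to the table's
#'   column names, for deposits using different headers.
#' @return A list: `brain` (n x 152 matrix), `behavior` (n x 3 matrix),
#'   `groups` (factor), `participant` (ids), `group_sizes`.
#' @export
ingest_roi_table <- function(x, col_map = c(participant = "participant",
                                            group = "group",
                                            strength = "strength",
                                            degree = "degree",
                                            age = "age")) {
  if (is.character(x)) x <- utils::read.csv(x, check.names = FALSE)
  stopifnot(is.data.frame(x))
  need <- c(unname(col_map), brain_col_names())
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- names(x)[duplicated(names(x))]
  if (length(dup))
    stop("duplicated columns: ", paste(unique(dup), collapse = ", "))
  behavior <- cbind(strength = as.numeric(x[[col_map[["strength"]]]]),
                    degree = as.numeric(x[[col_map[["degree"]]]]),
                    age = as.numeric(x[[col_map[["age"]]]]))
  drop <- !stats::complete.cases(behavior)
  if (any(drop)) {
    warning(sum(drop), " participant(s) with missing behavior excluded")
    x <- x[!drop, , drop = FALSE]
    behavior <- behavior[!drop, , drop = FALSE]
  }
  grp <- factor(x[[col_map[["group"]]]],
                levels = unique(x[[col_map[["group"]]]]))
  ord <- order(as.integer(grp))
  x <- x[ord, , drop = FALSE]
  behavior <- behavior[ord, , drop = FALSE]
  grp <- grp[ord]
  brain <- as.matrix(x[brain_col_names()])
  rownames(brain) <- x[[col_map[["participant"]]]]
  list(brain = brain, behavior = behavior, groups = grp,
       participant = x[[col_map[["participant"]]]],
       group_sizes = as.integer(table(grp)))
}

#' Write the assembled analysis table
#'
#' Inverse of [ingest_roi_table()]: one CSV row per participant with
#' behavior and the 152 canonical brain columns.
#'
#' @param brain,behavior,groups,participant As returned by
#'   [ingest_roi_table()] or built from the generators.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_roi_table <- function(brain, behavior, groups, participant, path) {
  df <- data.frame(participant = participant, group = as.character(groups),
                   strength = behavior[, 1L], degree = behavior[, 2L],
                   age = behavior[, 3L], check.names = FALSE)
  df <- cbind(df, as.data.frame(brain, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis
#'
#' Generates (or ingests) the cohort and brain data, then runs the group
#' comparisons for each psychosexual variable, the random-intercept T1-MD
#' model and behavior PLS. All randomness derives from the single master
#' seed via fixed sub-streams, so disabling a stage does not perturb the
#' others.
#'
#' @param seed Master seed.
#' @param cohort A [cohort_spec()] (ignored when `roi_table` is given).
#' @param effect An [effect_spec()] (ignored when `roi_table` is given).
#' @param roi_table Optional pre-assembled table (path or data.frame) to
#'   ingest instead of simulating.
#' @param n_perm,n_boot Resampling sizes for PLS.
#' @param stages Character subset of `c("stats", "mlm", "pls")` to run.
#' @param out_dir Optional directory for CSV/JSON outputs and the run
#'   manifest.
#' @return A list with `data` (brain/behavior/groups), `participants`
#'   (when simulated), `stats`, `mlm`, `pls` and `manifest`.
#' @export
run_pipeline <- function(seed = 1L, cohort = cohort_spec(),
                         effect = effect_spec(), roi_table = NULL,
                         n_perm = 1000L, n_boot = 1000L,
                         stages = c("stats", "mlm", "pls"),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  seeds <- derive_seeds(seed, 3L)
  participants <- NULL
  if (is.null(roi_table)) {
    sim <- generate_cohort(cohort, seed = seeds[1L])
    participants <- sim$participants
    gen <- generate_brain(participants, effect, seed = seeds[2L])
    dat <- list(brain = gen$brain, behavior = gen$behavior,
                groups = factor(participants$group,
                                levels = names(cohort$group_sizes)),
                participant = participants$id,
                group_sizes = unname(cohort$group_sizes))
  } else {
    dat <- ingest_roi_table(roi_table)
  }
  res <- list(data = dat, participants = participants)
  if ("stats" %in% stages && !is.null(participants)) {
    res$stats <- lapply(
      c(age_months = "age_months", gidyq = "gidyq_mean",
        strength = "strength", degree = "degree"),
      function(v) compare_groups(participants[[v]], participants$group))
  }
  if ("mlm" %in% stages) {
    obs <- long_observations(dat$brain[, 1:76, drop = FALSE],
                             dat$brain[, 77:152, drop = FALSE],
                             participants = dat$participant)
    res$mlm <- fit_random_intercept(obs)
  }
  if ("pls" %in% stages) {
    res$pls <- bpls(dat$brain, dat$behavior, dat$groups,
                    n_perm = n_perm, n_boot = n_boot, seed = seeds[3L])
  }
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("cortexmicro")),
    seed = seed, sub_seeds = seeds, stages = stages,
    n_perm = n_perm, n_boot = n_boot,
    simulated = is.null(roi_table),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_roi_table(dat$brain, dat$behavior, dat$groups, dat$participant,
                    file.path(out_dir, "roi_behavior_table.csv"))
    jsonlite::write_json(res$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(res$mlm))
      jsonlite::write_json(unclass(res$mlm)[c("slope", "se", "p",
                                              "var_intercept",
                                              "var_residual",
                                              "n_clusters", "n_obs")],
                           file.path(out_dir, "mlm_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$pls)) {
      jsonlite::write_json(
        list(singular_values = res$pls$s,
             covariance_pct = res$pls$covariance_pct,
             perm_p = res$pls$perm_p, seed = seed),
        file.path(out_dir, "pls_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(pls_report(res$pls),
                       file.path(out_dir, "stable_rois.csv"),
                       row.names = FALSE)
    }
  }
  res
}

#' Reproduce the deposited-data analyses
#'
#' Runs the deterministic core analyses on a local copy of the study's
#' deposited ROI/behavior tables (arranged in the canonical layout of
#' [ingest_roi_table()], with a `gidyq` column added): the Welch robust
#' omnibus statistic for the GIDYQ-AA, the standardized random-intercept
#' T1-MD slope, and the first latent variable's cross-block covariance
#' percentage. Requires the deposit to have been downloaded; this package
#' ships no participant data.
#'
#' @param path Path to the deposit CSV.
#' @return A list with `welch_gidyq`, `mlm_slope`, `lv1_covariance_pct`.
#' @export
reproduce_study <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"gidyq" %in% names(tab)) stop("deposit table needs a 'gidyq' column")
  dat <- ingest_roi_table(tab)
  welch <- welch_anova(tab$gidyq, tab$group)
  obs <- long_observations(dat$brain[, 1:76], dat$brain[, 77:152],
                           participants = dat$participant)
  fit <- fit_random_intercept(obs)
  dec <- decompose(cross_block(zscore_columns(dat$brain), dat$behavior,
                               dat$groups))
  list(welch_gidyq = welch$F, mlm_slope = fit$slope,
       lv1_covariance_pct = dec$covariance_pct[1L])
}
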