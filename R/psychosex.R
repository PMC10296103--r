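# Questionnaire scoring and the magnitude/phase representation of sexual
# attraction. The EROS instrument yields a mean androphilia and a mean
# gynephilia score (each on a 1-5 Likert scale); these are treated as the
# two components of an attraction vector whose length encodes the strength
# of attractions and whose angle (in degrees from the androphilia axis)
# encodes the androphilia-gynephilia dimension.

#' Score a Likert questionnaire scale
#'
#' Computes the mean of the answered items, provided that the fraction of
#' answered items reaches `min_fraction` (default 75\%); otherwise the score
#' is missing. Items must be integers on the 1-5 scale; `NA` marks an
#' unanswered item.
#'
#' @param items Numeric vector of item responses (1-5 or `NA`). The vector
#'   length defines the number of slots in the scale (8 for each EROS
#'   subscale, 27 for the GIDYQ-AA).
#' @param min_fraction Minimum fraction of answered items required for a
#'   score, in `[0, 1]`.
#' @return The mean of the present items, or `NA_real_` when fewer than
#'   `min_fraction` of the slots are answered.
#' @examples
#' score_scale(c(1, 2, 3, 4, 5, 1, 2, 3))   # 2.625
#' score_scale(c(5, 5, 5, NA, NA, NA, NA, NA))  # NA: only 3/8 answered
#' @export
score_scale <- function(items, min_fraction = 0.75) {
  if (!is.numeric(items) || length(items) == 0L)
    stop("'items' must be a non-empty numeric vector")
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must be a single proportion in [0, 1]")
  present <- !is.na(items)
  bad <- which(present & (items %% 1 != 0 | items < 1 | items > 5))
  if (length(bad))
    stop(sprintf("item %s outside the 1-5 integer scale (value %s)",
                 bad[1L], format(items[bad[1L]])))
  if (sum(present) / length(items) < min_fraction) return(NA_real_)
  mean(items[present])
}

check_scale_mean <- function(x, what) {
  ok <- is.na(x) | (x >= 1 & x <= 5)
  if (!all(ok))
    stop(sprintf("%s outside [1, 5]: %s", what,
                 paste(format(x[!ok][seq_len(min(3L, sum(!ok)))]),
                       collapse = ", ")))
  invisible(x)
}

#' Strength of attractions: magnitude of the attraction vector
#'
#' The mean androphilia score `a` and mean gynephilia score `g` define a
#' vector in the plane; its Euclidean length `sqrt(a^2 + g^2)` summarizes
#' the overall strength of sexual attractions irrespective of their target.
#' Over the attainable score range (1-5 on each axis) the magnitude spans
#' `sqrt(2)` (about 1.41) to `sqrt(50)` (about 7.07). Vectorized.
#'
#' @param a Mean androphilia score(s) in `[1, 5]` (`NA` allowed).
#' @param g Mean gynephilia score(s) in `[1, 5]` (`NA` allowed).
#' @return Numeric vector of magnitudes.
#' @seealso [attraction_phase()]
#' @examples
#' attraction_magnitude(3, 4)  # 5
#' @export
attraction_magnitude <- function(a, g) {
  check_scale_mean(a, "androphilia mean")
  check_scale_mean(g, "gynephilia mean")
  sqrt(a^2 + g^2)
}

#' Degree of androphilia-gynephilia: phase of the attraction vector
#'
#' The angle of the attraction vector from the androphilia axis, in degrees:
#' `acos(a / sqrt(a^2 + g^2)) * 180 / pi`. About 11 degrees represents
#' exclusive androphilia (a = 5, g = 1), about 79 degrees exclusive
#' gynephilia (a = 1, g = 5), and 45 degrees exactly equal scores; the
#' attainable range is symmetric about 45 degrees (plus or minus about 34).
#' Larger values are more gynephilic. Vectorized.
#'
#' @inheritParams attraction_magnitude
#' @return Numeric vector of phases in degrees.
#' @seealso [attraction_magnitude()]
#' @examples
#' attraction_phase(5, 1)  # 11.31
#' attraction_phase(2, 2)  # 45 exactly
#' @export
attraction_phase <- function(a, g) {
  check_scale_mean(a, "androphilia mean")
  check_scale_mean(g, "gynephilia mean")
  out <- acos(a / sqrt(a^2 + g^2)) * 180 / pi
  # equal scores are exactly equidistant between the axes; do not let
  # floating-point rounding blur the 45-degree landmark
  out[which(a == g)] <- 45
  out
}

#' Gender-dysphoria screening flag from the GIDYQ-AA mean
#'
#' `TRUE` when the GIDYQ-AA mean score is strictly below the 3.00 screening
#' threshold (lower scores indicate greater gender dysphoria); a score of
#' exactly 3.00 is below-threshold evidence and returns `FALSE`. Missing
#' scores give a missing flag. Vectorized.
#'
#' @param gidyq_mean GIDYQ-AA mean score(s) in `[1, 5]` (`NA` allowed).
#' @param threshold Screening threshold; default 3.00.
#' @return Logical vector.
#' @export
gd_flag <- function(gidyq_mean, threshold = 3.00) {
  check_scale_mean(gidyq_mean, "GIDYQ-AA mean")
  gidyq_mean < threshold
}

#' Round half-up for display
#'
#' Base R's `round()` rounds half to even; questionnaire conventions round
#' half away from zero. Used only for printed output, never internally.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Recover mean scores from magnitude and phase
#'
#' Inverse of the polar representation: `a = m * cos(theta)`,
#' `g = m * sin(theta)` with `theta` in degrees.
#'
#' @param magnitude Vector magnitude(s).
#' @param phase_deg Phase(s) in degrees.
#' @return A data.frame with columns `androphilia` and `gynephilia`.
#' @export
attraction_components <- function(magnitude, phase_deg) {
  th <- phase_deg * pi / 180
  data.frame(androphilia = magnitude * cos(th),
             gynephilia  = magnitude * sin(th))
}

eros_item_cols  <- function(which = c("andro", "gyne"))
  paste0("eros_", match.arg(which), "_", 1:8)
gidyq_item_cols <- function() paste0("gidyq_", 1:27)

#' Build participant records from an item-level questionnaire table
#'
#' Scores the 8-item EROS androphilia and gynephilia subscales and the
#' 27-item GIDYQ-AA (mean of answered items, requiring at least
#' `min_fraction` answered), then derives the attraction magnitude and
#' phase and the gender-dysphoria screening flag.
#'
#' @param items A data.frame with columns `id`, `group`, `age_months`,
#'   `eros_andro_1` ... `eros_andro_8`, `eros_gyne_1` ... `eros_gyne_8`,
#'   and `gidyq_1` ... `gidyq_27`. Alternatively two ISO date columns
#'   `birth_date` and `consent_date` may replace `age_months`; the age in
#'   months is then computed and rounded to the nearest month.
#' @param min_fraction Minimum answered fraction per scale (default 0.75).
#' @return A data.frame with one row per participant: `id`, `group`,
#'   `age_months`, `androphilia_mean`, `gynephilia_mean`, `gidyq_mean`,
#'   `gd_flag`, `strength` (magnitude) and `degree` (phase in degrees).
#' @export
build_participants <- function(items, min_fraction = 0.75) {
  stopifnot(is.data.frame(items))
  need <- c("id", "group", eros_item_cols("andro"), eros_item_cols("gyne"),
            gidyq_item_cols())
  miss <- setdiff(need, names(items))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"age_months" %in% names(items)) {
    if (!all(c("birth_date", "consent_date") %in% names(items)))
      stop("need either 'age_months' or 'birth_date'+'consent_date'")
    d0 <- as.Date(items$birth_date)
    d1 <- as.Date(items$consent_date)
    age_months <- as.integer(round(as.numeric(d1 - d0) / 365.25 * 12))
  } else {
    age_months <- as.integer(items$age_months)
  }
  score_block <- function(cols)
    apply(as.matrix(items[cols]), 1L, score_scale, min_fraction = min_fraction)
  a <- score_block(eros_item_cols("andro"))
  g <- score_block(eros_item_cols("gyne"))
  q <- score_block(gidyq_item_cols())
  data.frame(
    id = items$id, group = items$group, age_months = age_months,
    androphilia_mean = a, gynephilia_mean = g, gidyq_mean = q,
    gd_flag = gd_flag(q),
    strength = attraction_magnitude(a, g),
    degree = attraction_phase(a, g),
    stringsAsFactors = FALSE
  )
}

#' Group-wise descriptives for the demographic/psychosexual variables
#'
#' Mean, SD and range by group for age, the GIDYQ-AA mean, the strength of
#' attractions and the degree of androphilia-gynephilia, in the layout of a
#' standard cohort descriptives table.
#'
#' @param participants Output of [build_participants()] (or a table with the
#'   same columns).
#' @param variables Character vector of columns to summarize.
#' @return A data.frame with columns `variable`, `group`, `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
group_descriptives <- function(participants,
                               variables = c("age_months", "gidyq_mean",
                                             "strength", "degree")) {
  stopifnot(all(variables %in% names(participants)))
  out <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(split(participants[[v]], participants$group),
      function(x) {
        x <- x[!is.na(x)]
        data.frame(variable = v, n = length(x), mean = mean(x), sd = sd(x),
                   min = min(x), max = max(x))
      }))
  }))
  out$group <- rep(names(split(participants[[variables[1]]],
                               participants$group)), length(variables))
  rownames(out) <- NULL
  out[c("variable", "group", "n", "mean", "sd", "min", "max")]
}
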