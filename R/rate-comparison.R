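# Comparing per-subject growth rates of cube-root volume and maximum
# diameter, on percent-per-year scale, and categorising the ratio.

RATE_CATEGORIES <- c("considerably_faster_diameter", "moderately_faster_diameter",
                     "equivalent", "moderately_faster_volume",
                     "considerably_faster_volume")

#' Categorise a volume/diameter growth-rate ratio
#'
#' Five ordered classes of the ratio between a subject's cube-root-volume
#' and maximum-diameter growth rates: ratios in \[0.8, 1.25\] indicate
#' equivalent growth (the band is closed at both ends and log-symmetric,
#' `log 1.25 = -log 0.8`); \[0.5, 0.8) and (1.25, 2\] moderately faster
#' growth of diameter resp. volume; below 0.5 or above 2 considerably faster
#' growth (at least twice as fast) of one parameter.
#'
#' @param ratio positive finite ratio(s) of cube-root-volume rate over
#'   diameter rate.
#' @return ordered factor with levels from considerably faster diameter to
#'   considerably faster volume.
#' @examples
#' categorize_ratio(c(1, 1.5, 2.5, 0.8))
#' @export
categorize_ratio <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  cls <- ifelse(ratio < 0.5, RATE_CATEGORIES[1L],
         ifelse(ratio < 0.8, RATE_CATEGORIES[2L],
         ifelse(ratio <= 1.25, RATE_CATEGORIES[3L],
         ifelse(ratio <= 2, RATE_CATEGORIES[4L], RATE_CATEGORIES[5L]))))
  factor(cls, levels = RATE_CATEGORIES, ordered = TRUE)
}

#' Compare subject-level growth rates of volume and diameter
#'
#' Estimates each subject's growth rate (percent per year) separately on the
#' maximum-diameter and cube-root-volume scales, forms the ratio of the two
#' percent rates, and categorises it with [categorize_ratio()]. The volume
#' rate in percent is derived from the cube-root rate via the cube law,
#' `100 ((1 + r/100)^3 - 1)`. Subjects lacking two usable visits on either
#' series are excluded with a recorded count.
#'
#' @param cohort an `aaa_cohort` with both diameter and volume.
#' @param params_diameter growth parameters (or `aaa_growth_fit`) for the
#'   diameter scale.
#' @param params_cuberoot growth parameters (or fit) for the
#'   cube-root-volume scale.
#' @param mode rate-estimation mode, see [individual_rates()].
#' @param ratio_on `"percent"` (default, the reported convention) or
#'   `"lambda"` to form the ratio on raw rates; the two differ only at
#'   second order.
#' @return list with `records` (per-subject data frame: rates, ratio,
#'   category, plus morphology/sex/smoking columns when present),
#'   `proportions` (the five class proportions, summing to 1) and
#'   `n_excluded`.
#' @export
compare_rates <- function(cohort, params_diameter, params_cuberoot,
                          mode = c("map", "conditional_ml"),
                          ratio_on = c("percent", "lambda")) {
  mode <- match.arg(mode)
  ratio_on <- match.arg(ratio_on)
  if (inherits(params_diameter, "aaa_growth_fit")) {
    params_diameter <- params_diameter$params
  }
  if (inherits(params_cuberoot, "aaa_growth_fit")) {
    params_cuberoot <- params_cuberoot$params
  }
  stopifnot(params_diameter$scale == "diameter",
            params_cuberoot$scale == "cuberoot_volume")
  rd <- individual_rates(cohort, params_diameter, mode)
  rv <- individual_rates(cohort, params_cuberoot, mode)
  common <- intersect(rd$subject_id, rv$subject_id)
  if (length(common) == 0L) {
    stop("no subject has >= 2 usable visits on both series", call. = FALSE)
  }
  rd <- rd[match(common, rd$subject_id), ]
  rv <- rv[match(common, rv$subject_id), ]
  ratio <- if (ratio_on == "percent") {
    rv$percent_per_year / rd$percent_per_year
  } else {
    rv$lambda_hat / rd$lambda_hat
  }
  records <- data.frame(
    subject_id = common,
    rate_diameter_pct = rd$percent_per_year,
    rate_cuberoot_volume_pct = rv$percent_per_year,
    rate_volume_pct = 100 * ((1 + rv$percent_per_year / 100)^3 - 1),
    ratio = ratio,
    category = categorize_ratio(ratio)
  )
  for (col in c("morphology", "sex", "smoking")) {
    if (col %in% names(cohort)) {
      records[[col]] <- cohort[[col]][match(common, cohort$subject_id)]
    }
  }
  props <- table(records$category) / nrow(records)
  n_total <- length(unique(cohort$subject_id))
  list(records = records,
       proportions = setNames(as.numeric(props), names(props)),
       n_excluded = n_total - length(common))
}

#' Absolute and relative changes from baseline
#'
#' For each visit, the change from the subject's first visit on the chosen
#' size scale: `absolute = y_ij - y_i1`, `relative = y_ij / y_i1`. The first
#' visit yields (0, 1).
#'
#' @param cohort an `aaa_cohort`.
#' @param scale size scale, see [apply_scale()].
#' @return data frame: `subject_id`, `time_years`, `value`,
#'   `absolute_change`, `relative_change`.
#' @export
changes_from_baseline <- function(cohort, scale = c("volume", "diameter",
                                                    "cuberoot_volume")) {
  scale <- match.arg(scale)
  x <- apply_scale(cohort, scale)
  x <- x[!is.na(x$size), , drop = FALSE]
  base <- ave(x$size, x$subject_id, FUN = function(v) v[1L])
  data.frame(subject_id = x$subject_id, time_years = x$time_years,
             value = x$size,
             absolute_change = x$size - base,
             relative_change = x$size / base)
}

#' Summarise growth rates by group
#'
#' Median (minimum-maximum) of each rate column and of the rate ratio per
#' group (e.g. aneurysm morphology), in the style of a descriptive cohort
#' table. Groups of size 1 report min = median = max.
#'
#' @param records per-subject records from [compare_rates()].
#' @param by name of the grouping column in `records` (e.g. `"morphology"`).
#' @return data frame with one row per group: `n` and, for each of the rate
#'   columns and the ratio, `<col>_median`, `<col>_min`, `<col>_max` and a
#'   formatted `<col>_label` "median (min-max)".
#' @export
summarize_rates_by_group <- function(records, by = "morphology") {
  if (!by %in% names(records)) {
    stop("unknown grouping column: ", by, call. = FALSE)
  }
  cols <- c("rate_diameter_pct", "rate_cuberoot_volume_pct",
            "rate_volume_pct", "ratio")
  cols <- intersect(cols, names(records))
  g <- records[[by]]
  g[is.na(g)] <- "unknown"
  groups <- unique(g)
  rows <- lapply(groups, function(grp) {
    sub <- records[g == grp, , drop = FALSE]
    row <- data.frame(group = grp, n = nrow(sub))
    for (col in cols) {
      v <- sub[[col]]
      row[[paste0(col, "_median")]] <- median(v)
      row[[paste0(col, "_min")]] <- min(v)
      row[[paste0(col, "_max")]] <- max(v)
      row[[paste0(col, "_label")]] <-
        sprintf("%.1f (%.1f-%.1f)", median(v), min(v), max(v))
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- by
  out
}
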