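# Longitudinal cohort data model: one row per CT visit.

COHORT_COLUMNS <- c("subject_id", "time_years", "diameter_mm", "volume_ml")
MORPHOLOGY_LEVELS <- c("fusiform", "saccular", "eccentric", "other", "unknown")
SIZE_SCALES <- c("diameter", "volume", "cuberoot_volume")

#' Construct and validate a longitudinal AAA cohort
#'
#' A cohort is a data frame with one row per visit and columns
#' `subject_id`, `time_years` (years since the subject's first visit),
#' `diameter_mm` (maximum aortic diameter, mm), `volume_ml` (aneurysm
#' volume, ml), and optionally `morphology` (one of fusiform, saccular,
#' eccentric, other, unknown), `sex` and `smoking`.
#'
#' Validation enforces: each subject's first visit at time 0; strictly
#' increasing visit times within subject (duplicates rejected); size values,
#' when present, strictly positive and finite. Rows are reordered by subject
#' and time. Subjects with a single visit are retained but flagged (they
#' cannot contribute to growth-rate estimation).
#'
#' @param x data frame with at least the four mandatory columns.
#' @param rebase_time if `TRUE`, per-subject times are shifted so the first
#'   visit is at 0 (useful when times are given on a common study clock).
#' @return the validated cohort, class `aaa_cohort`, with attribute
#'   `single_visit` listing flagged subjects.
#' @export
as_cohort <- function(x, rebase_time = FALSE) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$subject_id <- as.character(x$subject_id)
  for (col in c("time_years", "diameter_mm", "volume_ml")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if ("morphology" %in% names(x)) {
    m <- as.character(x$morphology)
    bad <- !is.na(m) & !(m %in% MORPHOLOGY_LEVELS)
    if (any(bad)) {
      stop("validation error: unknown morphology value(s): ",
           paste(unique(m[bad]), collapse = ", "), call. = FALSE)
    }
    x$morphology <- m
  }
  if (anyNA(x$subject_id) || anyNA(x$time_years)) {
    stop("validation error: subject_id and time_years must be non-missing",
         call. = FALSE)
  }
  x <- x[order(x$subject_id, x$time_years), , drop = FALSE]
  rownames(x) <- NULL
  if (rebase_time) {
    first <- tapply(x$time_years, x$subject_id, min)
    x$time_years <- x$time_years - as.numeric(first[x$subject_id])
  }

  for (col in c("diameter_mm", "volume_ml")) {
    v <- x[[col]]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad) > 0L) {
      stop(sprintf("validation error: non-positive or non-finite %s at row %d (subject %s)",
                   col, bad[1L], x$subject_id[bad[1L]]), call. = FALSE)
    }
  }
  if (any(x$time_years < 0)) {
    stop("validation error: negative time_years", call. = FALSE)
  }
  sp <- split(seq_len(nrow(x)), x$subject_id)
  for (idx in sp) {
    tt <- x$time_years[idx]
    if (tt[1L] != 0) {
      stop(sprintf("validation error: first visit of subject %s is at time %g, not 0 (use rebase_time = TRUE for study-clock times)",
                   x$subject_id[idx[1L]], tt[1L]), call. = FALSE)
    }
    if (anyDuplicated(tt)) {
      stop(sprintf("validation error: duplicate visit time for subject %s",
                   x$subject_id[idx[1L]]), call. = FALSE)
    }
  }
  n_visits <- vapply(sp, length, integer(1))
  attr(x, "single_visit") <- names(n_visits)[n_visits == 1L]
  class(x) <- c("aaa_cohort", "data.frame")
  x
}

#' Read a longitudinal cohort from CSV
#'
#' Expects a header row with columns
#' `subject_id,time_years,diameter_mm,volume_ml[,morphology,sex,smoking]`,
#' decimal point `.`, UTF-8. Missing values may be written as `NA` or left
#' empty. Lines starting with `#` (metadata written by [write_cohort()] or
#' the command-line interface) are skipped. Alternatively a `visit_date`
#' column (ISO dates) may replace `time_years`; dates are converted to years
#' since first visit using 365.25 days/year.
#'
#' @param path CSV file path.
#' @param date_col optional name of a visit-date column used instead of
#'   `time_years`.
#' @param rebase_time passed to [as_cohort()].
#' @return validated `aaa_cohort`.
#' @export
read_cohort <- function(path, date_col = NULL, rebase_time = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, na.strings = c("NA", ""), comment.char = "#",
                stringsAsFactors = FALSE)
  if (!is.null(date_col)) {
    if (!date_col %in% names(x)) {
      stop("cohort schema error: missing mandatory column(s): ", date_col,
           call. = FALSE)
    }
    d <- as.Date(x[[date_col]])
    x$time_years <- as.numeric(d) / 365.25
    rebase_time <- TRUE
  }
  as_cohort(x, rebase_time = rebase_time)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` recovers the
#' cohort (up to floating-point printing precision).
#'
#' @param cohort an `aaa_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach a size scale to a cohort
#'
#' Adds a `size` column holding the analysed series: `diameter_mm`,
#' `volume_ml`, or the cube root of volume (`volume_ml^(1/3)`, in
#' ml^(1/3)). The cube-root transform puts volume on the geometric scale of
#' a length so that growth rates of volume and diameter are directly
#' comparable. Visits missing the source value keep `NA` in `size` and are
#' dropped from analyses with a reported count.
#'
#' @param cohort an `aaa_cohort`.
#' @param scale one of `"diameter"`, `"volume"`, `"cuberoot_volume"`.
#' @return the cohort with a `size` column and attribute `size_scale`.
#' @export
apply_scale <- function(cohort, scale = c("volume", "diameter", "cuberoot_volume")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort, "aaa_cohort"))
  src <- if (scale == "diameter") cohort$diameter_mm else cohort$volume_ml
  if (all(is.na(src))) {
    stop(sprintf("scale '%s' requires %s, which is entirely missing", scale,
                 if (scale == "diameter") "diameter_mm" else "volume_ml"),
         call. = FALSE)
  }
  cohort$size <- switch(scale,
    diameter = src,
    volume = src,
    cuberoot_volume = src^(1 / 3)
  )
  attr(cohort, "size_scale") <- scale
  attr(cohort, "n_missing_size") <- sum(is.na(cohort$size))
  cohort
}

#' First visit of each subject
#'
#' @param cohort an `aaa_cohort`.
#' @return one-row-per-subject data frame of baseline visits.
#' @export
first_visits <- function(cohort) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  idx <- !duplicated(cohort$subject_id)
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.aaa_cohort <- function(x, ...) {
  ns <- length(unique(x$subject_id))
  cat(sprintf("AAA cohort: %d visits, %d subjects", nrow(x), ns))
  sv <- attr(x, "single_visit")
  if (length(sv) > 0L) cat(sprintf(" (%d single-visit)", length(sv)))
  sc <- attr(x, "size_scale")
  if (!is.null(sc)) cat(sprintf("; size scale: %s", sc))
  cat("\n")
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Internal: per-subject increment series on the chosen scale.
# Each element: list(subject_id, dt, dz, t0_value) where dt are times since
# the subject's first usable visit (first visit dropped) and dz the
# corresponding log-size increments. Subjects with < 2 usable visits are
# excluded and reported.
cohort_series <- function(cohort, scale = NULL) {
  if (is.null(attr(cohort, "size_scale"))) {
    cohort <- apply_scale(cohort, scale %||% "volume")
  } else if (!is.null(scale) && scale != attr(cohort, "size_scale")) {
    cohort <- apply_scale(cohort, scale)
  }
  keep <- !is.na(cohort$size)
  x <- cohort[keep, , drop = FALSE]
  sp <- split(seq_len(nrow(x)), x$subject_id)
  series <- list()
  excluded <- character(0)
  for (id in names(sp)) {
    idx <- sp[[id]]
    if (length(idx) < 2L) {
      excluded <- c(excluded, id)
      next
    }
    tt <- x$time_years[idx]
    y <- log(x$size[idx])
    series[[id]] <- list(subject_id = id,
                         dt = tt[-1L] - tt[1L],
                         dz = y[-1L] - y[1L],
                         t0_value = x$size[idx[1L]])
  }
  structure(series,
            excluded = excluded,
            scale = attr(cohort, "size_scale"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
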