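#' Quartile-based sinus class limits
#'
#' Derives the class boundaries of the three-class sinus classification
#' from the first and third quartiles of signed sinus depth, optionally
#' stratified (e.g. by dentition group). Quartiles use the linear
#' interpolation of order statistics (quantile type 7, the R default).
#' Each stratum's raw quartiles are rounded to the nearest integer
#' millimetre (half away from zero); the classification is `consistent`
#' when all strata round to the same pair, which becomes the pooled
#' (lower, upper) limits. When strata disagree, the pooled limits fall
#' back to the rounded quartiles of all depths combined and `consistent`
#' is `FALSE`; the per-stratum candidates remain available for inspection.
#'
#' @param depths Numeric vector of signed sinus depths (mm; positive =
#'   below the palatal line).
#' @param strata Optional parallel vector of stratum labels; `NULL` treats
#'   the sample as one stratum.
#' @return Object of class `class_limits`: list with `per_stratum` (tibble
#'   `stratum`, `q1_raw`, `q3_raw`, `lower`, `upper`), `lower`, `upper`
#'   (pooled integer mm), `consistent`.
#' @export
class_limits <- function(depths, strata = NULL) {
  depths <- as.numeric(depths)
  if (anyNA(depths)) stop("depths contain NA", call. = FALSE)
  if (is.null(strata)) strata <- rep("all", length(depths))
  if (length(strata) != length(depths)) {
    stop("`strata` must parallel `depths`", call. = FALSE)
  }
  per <- lapply(split(depths, strata), function(d) {
    if (length(d) < 4) {
      stop("each stratum needs at least 4 depths for quartiles",
           call. = FALSE)
    }
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
    tibble::tibble(q1_raw = q[1], q3_raw = q[2],
                   lower = round_half_away(q[1]),
                   upper = round_half_away(q[2]))
  })
  per_stratum <- dplyr::bind_rows(per, .id = "stratum")
  consistent <- nrow(unique(per_stratum[c("lower", "upper")])) == 1
  if (consistent) {
    lower <- per_stratum$lower[1]
    upper <- per_stratum$upper[1]
  } else {
    q <- stats::quantile(depths, c(0.25, 0.75), names = FALSE, type = 7)
    lower <- round_half_away(q[1])
    upper <- round_half_away(q[2])
  }
  if (lower > upper) stop("degenerate limits: lower > upper", call. = FALSE)
  structure(list(per_stratum = per_stratum, lower = lower, upper = upper,
                 consistent = consistent),
            class = "class_limits")
}

#' @export
print.class_limits <- function(x, ...) {
  cat(sprintf("<class_limits> lower = %g mm, upper = %g mm (%s)\n",
              x$lower, x$upper,
              if (x$consistent) "consistent across strata"
              else "strata disagree; pooled"))
  print(x$per_stratum)
  invisible(x)
}

# round to nearest integer, halves away from zero (0.3 -> 0, 5.9 -> 6,
# 6.2 -> 6, -0.5 -> -1); base round() would go to even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign a sinus class from signed depth
#'
#' Class I: sinus floor above the hard palate (depth < lower limit);
#' class II: floor between the limits; class III: floor more than the
#' upper limit below the palate. With the default `closed_upper`
#' convention class II is the closed interval \[lower, upper\] — a depth
#' exactly at either limit is class II; `open_upper` instead assigns the
#' upper boundary to class III.
#'
#' @param depth Numeric vector of signed depths (mm).
#' @param lower,upper Class limits (mm), or a [class_limits()] object as
#'   `lower`.
#' @param boundary `"closed_upper"` (default) or `"open_upper"`.
#' @return Ordered factor with levels `I < II < III`.
#' @examples
#' assign_class(c(-2, 0, 6.01), 0, 6)
#' @export
assign_class <- function(depth, lower = 0, upper = 6,
                         boundary = c("closed_upper", "open_upper")) {
  boundary <- match.arg(boundary)
  if (inherits(lower, "class_limits")) {
    lim <- lower
    lower <- lim$lower
    upper <- lim$upper
  }
  stopifnot(length(lower) == 1, length(upper) == 1, lower <= upper)
  cls <- ifelse(depth < lower, "I",
                if (boundary == "closed_upper") {
                  ifelse(depth <= upper, "II", "III")
                } else {
                  ifelse(depth < upper, "II", "III")
                })
  factor(cls, levels = c("I", "II", "III"), ordered = TRUE)
}

#' Classify every sinus in a cohort
#'
#' Fills the `sinus_class` column of a cohort table. In `"quartile"` mode
#' the limits are derived from this cohort's own depths via
#' [class_limits()]; `use_rounded = FALSE` uses the raw (unrounded)
#' quartiles, which by construction puts one quarter of a continuous
#' sample in each outer class and half in the middle class. In `"fixed"`
#' mode the supplied integer limits (default 0 and 6 mm, the rounded
#' quartiles of the reference cohort) are applied as-is.
#'
#' @param cohort Cohort tibble with a `sinus_depth_mm` column.
#' @param mode `"quartile"` or `"fixed"`.
#' @param lower,upper Fixed limits (mm) for `mode = "fixed"`.
#' @param strata Optional column name to stratify quartile estimation.
#' @param use_rounded Use rounded integer limits in quartile mode
#'   (default `TRUE`).
#' @param boundary Boundary convention, see [assign_class()].
#' @return The cohort with `sinus_class` filled; the limits used are
#'   attached as attribute `"limits"`.
#' @export
classify_cohort <- function(cohort, mode = c("quartile", "fixed"),
                            lower = 0, upper = 6, strata = NULL,
                            use_rounded = TRUE,
                            boundary = c("closed_upper", "open_upper")) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (!"sinus_depth_mm" %in% names(cohort)) {
    stop("cohort lacks a sinus_depth_mm column", call. = FALSE)
  }
  if (anyNA(cohort$sinus_depth_mm)) {
    stop("cohort has missing sinus depths; exclude those records first",
         call. = FALSE)
  }
  if (mode == "quartile") {
    strat <- if (!is.null(strata)) cohort[[strata]] else NULL
    lim <- class_limits(cohort$sinus_depth_mm, strat)
    if (use_rounded) {
      lo <- lim$lower
      up <- lim$upper
    } else {
      q <- stats::quantile(cohort$sinus_depth_mm, c(0.25, 0.75),
                           names = FALSE, type = 7)
      lo <- q[1]
      up <- q[2]
    }
  } else {
    lim <- list(lower = lower, upper = upper, consistent = TRUE)
    lo <- lower
    up <- upper
  }
  cohort$sinus_class <- as.character(
    assign_class(cohort$sinus_depth_mm, lo, up, boundary = boundary))
  attr(cohort, "limits") <- list(lower = lo, upper = up, mode = mode,
                                 boundary = boundary, detail = lim)
  cohort
}
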