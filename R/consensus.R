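#' Consensus of replicate landmark placements
#'
#' Each landmark is placed up to four times (two observers, two sessions
#' six weeks apart). The consensus location is the coordinate-wise median
#' of the replicates; for an even count each coordinate's median is the
#' midpoint of the two central order statistics. The deviation of a
#' replicate is its Euclidean distance from that median; when any replicate
#' deviates by more than `threshold_mm` (default 2 mm) the landmark is
#' flagged as containing a gross measurement error. The study resolved such
#' flags by manual re-adjudication; here the flag is resolved mechanically
#' by excluding replicates beyond the threshold and recomputing the median
#' from the survivors. If fewer than two replicates survive, the point is
#' marked unresolved rather than inventing a value.
#'
#' @param replicates Numeric matrix with one row per replicate and two
#'   columns (x, y) in mm, or a list of length-2 points.
#' @param threshold_mm Gross-error threshold in mm (> 0).
#' @return List with `point` (length-2 consensus coordinates), `flagged`
#'   (any replicate beyond threshold from the initial median),
#'   `max_deviation` (mm, from the initial median), `n_used` (replicates in
#'   the final consensus) and `resolved` (`FALSE` when fewer than two
#'   replicates survived exclusion while others were excluded).
#' @examples
#' consensus_point(rbind(c(10, 10), c(10.2, 10), c(10, 10.4), c(9.8, 9.8)))
#' @export
consensus_point <- function(replicates, threshold_mm = 2) {
  if (is.list(replicates) && !is.matrix(replicates)) {
    replicates <- do.call(rbind, replicates)
  }
  replicates <- matrix(as.numeric(replicates), ncol = 2)
  n <- nrow(replicates)
  if (n < 1) stop("consensus requires at least one replicate", call. = FALSE)
  if (!is.numeric(threshold_mm) || threshold_mm <= 0) {
    stop("`threshold_mm` must be positive", call. = FALSE)
  }
  med <- apply(replicates, 2, stats::median)
  dev <- sqrt(rowSums(sweep(replicates, 2, med)^2))
  max_dev <- max(dev)
  flagged <- max_dev > threshold_mm
  if (!flagged) {
    return(list(point = med, flagged = FALSE, max_deviation = max_dev,
                n_used = n, resolved = TRUE))
  }
  keep <- dev <= threshold_mm
  n_used <- sum(keep)
  if (n_used < 2 && n > 1) {
    # exclusion would leave no agreeing pair: unresolvable, keep the
    # initial median as the best available estimate but say so
    return(list(point = med, flagged = TRUE, max_deviation = max_dev,
                n_used = n_used, resolved = FALSE))
  }
  point <- apply(replicates[keep, , drop = FALSE], 2, stats::median)
  list(point = point, flagged = TRUE, max_deviation = max_dev,
       n_used = n_used, resolved = TRUE)
}

#' Consensus landmark sheet for one patient
#'
#' Aggregates all replicate sheets of one patient (already calibrated to
#' mm) into a single consensus sheet, one consensus point per landmark
#' label, plus a flag report that serves as the audit trail replacing the
#' study's manual adjudication of gross errors.
#'
#' @param points_mm Tibble with columns `patient_id`, `observer_id`,
#'   `session_id`, `label`, `x_mm`, `y_mm` for a single patient.
#' @param threshold_mm Gross-error threshold in mm.
#' @return List with `points` (named list label -> length-2 mm point) and
#'   `report` (tibble: `patient_id`, `label`, `n_replicates`,
#'   `max_deviation_mm`, `flagged`, `n_used`, `resolved`).
#' @export
consensus_sheet <- function(points_mm, threshold_mm = 2) {
  pid <- unique(points_mm$patient_id)
  if (length(pid) != 1) {
    stop("consensus_sheet expects points for exactly one patient",
         call. = FALSE)
  }
  labs <- intersect(LANDMARK_LABELS, unique(points_mm$label))
  pts <- list()
  rows <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lb <- labs[i]
    sub <- points_mm[points_mm$label == lb, ]
    cp <- consensus_point(cbind(sub$x_mm, sub$y_mm), threshold_mm)
    pts[[lb]] <- cp$point
    rows[[i]] <- tibble::tibble(
      patient_id = pid, label = lb, n_replicates = nrow(sub),
      max_deviation_mm = cp$max_deviation, flagged = cp$flagged,
      n_used = cp$n_used, resolved = cp$resolved
    )
  }
  list(points = pts, report = dplyr::bind_rows(rows))
}
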