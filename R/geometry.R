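#' Pixel-to-millimetre calibration from a digital ruler
#'
#' Two calibration landmarks are placed on both ends of a digital ruler of
#' known physical length; the scale factor is that length divided by the
#' pixel distance between the two points.
#'
#' @param p1,p2 Numeric length-2 vectors, pixel coordinates of the two ruler
#'   endpoints.
#' @param ruler_length_mm Physical ruler length in millimetres (> 0).
#' @return Scale in mm per pixel (positive scalar).
#' @examples
#' calibrate(c(0, 0), c(0, 200), 20) # 0.1 mm/px
#' @export
calibrate <- function(p1, p2, ruler_length_mm) {
  p1 <- as_point(p1, "p1")
  p2 <- as_point(p2, "p2")
  if (!is.numeric(ruler_length_mm) || length(ruler_length_mm) != 1 ||
      !is.finite(ruler_length_mm) || ruler_length_mm <= 0) {
    stop("`ruler_length_mm` must be a single positive number", call. = FALSE)
  }
  d <- sqrt(sum((p2 - p1)^2))
  if (d == 0) {
    stop("calibration points coincide: pixel distance is zero", call. = FALSE)
  }
  ruler_length_mm / d
}

#' Hard-palate reference axis
#'
#' Builds the palatal reference line through the two hard-palate landmarks
#' (one per side) together with an inferior-pointing unit normal. The normal
#' is oriented so that the alveolar ridge (supplied as a hint point, usually
#' the mean of the two alveolar-tip landmarks) lies on its non-negative side.
#' In raster image coordinates (y increasing inferiorly) a horizontal palate
#' yields the normal (0, 1).
#'
#' @param p7,p12 Numeric length-2 vectors (mm): the right and left palatal
#'   landmarks.
#' @param alveolar_hint Numeric length-2 vector (mm): any point on the
#'   alveolar (inferior) side of the palate.
#' @return An object of class `palatal_axis`: a list with `anchor`,
#'   `direction` (unit vector along the palate) and `inferior_normal`
#'   (unit vector perpendicular to it, pointing toward the ridge).
#' @export
palatal_axis <- function(p7, p12, alveolar_hint) {
  p7 <- as_point(p7, "p7")
  p12 <- as_point(p12, "p12")
  hint <- as_point(alveolar_hint, "alveolar_hint")
  v <- p12 - p7
  len <- sqrt(sum(v^2))
  if (len == 0) {
    stop("palatal landmarks coincide: axis is degenerate", call. = FALSE)
  }
  direction <- v / len
  normal <- c(-direction[2], direction[1])
  if (sum((hint - p7) * normal) < 0) normal <- -normal
  structure(
    list(anchor = p7, direction = direction, inferior_normal = normal),
    class = "palatal_axis"
  )
}

#' @export
print.palatal_axis <- function(x, ...) {
  cat("<palatal_axis>\n")
  cat(sprintf("  anchor:          (%.3f, %.3f) mm\n", x$anchor[1], x$anchor[2]))
  cat(sprintf("  direction:       (%.4f, %.4f)\n", x$direction[1], x$direction[2]))
  cat(sprintf("  inferior normal: (%.4f, %.4f)\n",
              x$inferior_normal[1], x$inferior_normal[2]))
  invisible(x)
}

#' Signed sinus depth relative to the palatal line
#'
#' Signed perpendicular distance of the deepest sinus-floor point from the
#' hard-palate line. Positive values mean the sinus floor lies inferior to
#' (below) the palate, i.e. the sinus extends into the alveolar process;
#' negative values mean it stays above the palatal level.
#'
#' @param p4 Numeric length-2 vector (mm): deepest point of the sinus floor.
#' @param axis A [palatal_axis()] object.
#' @return Signed depth in mm.
#' @export
sinus_depth <- function(p4, axis) {
  p4 <- as_point(p4, "p4")
  stopifnot(inherits(axis, "palatal_axis"))
  sum((p4 - axis$anchor) * axis$inferior_normal)
}

#' Residual alveolar ridge height
#'
#' Distance between the alveolar tip and the deepest point of the sinus
#' floor: the bone height available for implant placement. The default is
#' the Euclidean distance between the two landmarks; `"projected"` instead
#' measures the separation of the two points along the palatal normal,
#' provided for sensitivity analysis.
#'
#' @param tip Numeric length-2 vector (mm): alveolar tip landmark.
#' @param floor Numeric length-2 vector (mm): deepest sinus-floor landmark.
#' @param method `"euclidean"` (default) or `"projected"`.
#' @param axis A [palatal_axis()] object; required for `method = "projected"`.
#' @return Height in mm (non-negative).
#' @export
alveolar_height <- function(tip, floor, method = c("euclidean", "projected"),
                            axis = NULL) {
  tip <- as_point(tip, "tip")
  floor <- as_point(floor, "floor")
  method <- match.arg(method)
  if (method == "euclidean") {
    sqrt(sum((tip - floor)^2))
  } else {
    if (is.null(axis)) {
      stop("`axis` is required for projected alveolar height", call. = FALSE)
    }
    stopifnot(inherits(axis, "palatal_axis"))
    abs(sum((tip - floor) * axis$inferior_normal))
  }
}

#' Sinus opening angle
#'
#' Angle at the deepest sinus-floor point subtended by the highest points of
#' the lateral (buccal) and medial (palatal) sinus walls. Computed with the
#' two-argument arctangent of the cross and dot products of the two rays,
#' which is numerically stable near 0 and 180 degrees (unlike acos of the
#' normalized dot product). Symmetric in the two wall points.
#'
#' @param p3 Numeric length-2 vector (mm): highest lateral wall point.
#' @param p4 Numeric length-2 vector (mm): vertex, deepest sinus-floor point.
#' @param p5 Numeric length-2 vector (mm): highest medial wall point.
#' @return Angle in degrees, strictly inside (0, 180).
#' @export
opening_angle <- function(p3, p4, p5) {
  p3 <- as_point(p3, "p3")
  p4 <- as_point(p4, "p4")
  p5 <- as_point(p5, "p5")
  u <- p3 - p4
  v <- p5 - p4
  if (all(u == 0) || all(v == 0)) {
    stop("opening angle undefined: wall point coincides with the vertex",
         call. = FALSE)
  }
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  ang <- atan2(abs(cross), dot) * 180 / pi
  if (ang <= 0 || ang >= 180) {
    stop(sprintf(
      "opening angle %.6f deg is outside the open interval (0, 180): rays are collinear",
      ang), call. = FALSE)
  }
  ang
}

#' Measure one sinus from consensus landmarks
#'
#' Computes the three morphometric statistics for one side of one patient
#' from calibrated (mm) consensus landmarks: signed sinus depth of the floor
#' point below the palatal line, alveolar ridge height between floor and
#' alveolar tip, and the sinus opening angle at the floor point. The right
#' sinus uses landmarks P3 (lateral wall), P4 (floor), P5 (medial wall) and
#' P6 (alveolar tip); the left sinus uses P8, P9, P10 and P11. Both share
#' the palatal axis through P7 and P12.
#'
#' @param points Named list of length-2 mm coordinates; names are landmark
#'   labels `P1`..`P12` (only the labels needed for `side` plus P7/P12 are
#'   required).
#' @param side `"right"` or `"left"`.
#' @param axis Optional precomputed [palatal_axis()]; built from P7/P12 and
#'   the available alveolar tips when omitted.
#' @param ah_method Alveolar-height convention, see [alveolar_height()].
#' @return One-row tibble with columns `side`, `sinus_depth`,
#'   `alveolar_height`, `opening_angle` (mm, mm, degrees), or, if required
#'   landmarks are missing, a zero-row tibble with attribute `"skip_reason"`.
#' @export
measure_sinus <- function(points, side = c("right", "left"), axis = NULL,
                          ah_method = c("euclidean", "projected")) {
  side <- match.arg(side)
  ah_method <- match.arg(ah_method)
  lab <- side_labels(side)
  need <- c(unlist(lab, use.names = FALSE), "P7", "P12")
  missing_lab <- setdiff(need, names(points))
  empty <- tibble::tibble(
    side = character(), sinus_depth = double(),
    alveolar_height = double(), opening_angle = double()
  )
  if (length(missing_lab) > 0) {
    attr(empty, "skip_reason") <-
      paste0("missing landmarks: ", paste(missing_lab, collapse = ", "))
    return(empty)
  }
  if (is.null(axis)) {
    hints <- points[intersect(c("P6", "P11"), names(points))]
    hint <- colMeans(do.call(rbind, hints))
    axis <- palatal_axis(points$P7, points$P12, hint)
  }
  tibble::tibble(
    side = side,
    sinus_depth = sinus_depth(points[[lab$floor]], axis),
    alveolar_height = alveolar_height(points[[lab$tip]], points[[lab$floor]],
                                      method = ah_method, axis = axis),
    opening_angle = opening_angle(points[[lab$lateral]], points[[lab$floor]],
                                  points[[lab$medial]])
  )
}

# landmark labels for the five side-specific roles (Fig.-1 numbering:
# lateral wall top, floor, medial wall top, alveolar tip, palatal point)
side_labels <- function(side) {
  if (side == "right") {
    list(lateral = "P3", floor = "P4", medial = "P5", tip = "P6")
  } else {
    list(lateral = "P8", floor = "P9", medial = "P10", tip = "P11")
  }
}

as_point <- function(p, name) {
  p <- as.numeric(p)
  if (length(p) != 2 || anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("`%s` must be a finite numeric length-2 point", name),
         call. = FALSE)
  }
  p
}
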