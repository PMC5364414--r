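#' @importFrom rlang .data
NULL

LANDMARK_LABELS <- paste0("P", 1:12)

LANDMARK_COLS <- c("patient_id", "observer_id", "session_id", "label",
                   "x_px", "y_px", "ruler_length_mm")

COHORT_COLS <- c("patient_id", "side", "gender", "dentition", "age",
                 "sinus_depth_mm", "alveolar_height_mm", "opening_angle_deg",
                 "sinus_class")

#' Read a landmark CSV file
#'
#' Reads the flat landmark table: one row per patient x observer x session x
#' landmark label, with pixel coordinates (raster convention: origin top
#' left, y increasing inferiorly) and the physical length of the digital
#' ruler whose endpoints are landmarks P1 and P2. One observer-session set
#' of 12 labelled points for one patient image is a "sheet"; sheets with
#' missing labels are retained but flagged (see [sheet_summary()]) so that
#' exclusion is an explicit, logged pipeline step rather than a silent drop.
#'
#' @param path Path to a CSV file with header
#'   `patient_id,observer_id,session_id,label,x_px,y_px,ruler_length_mm`.
#' @return A tibble with those columns, `label` checked against `P1`..`P12`,
#'   coordinates numeric.
#' @seealso [sheet_summary()], [write_landmark_csv()]
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(LANDMARK_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("landmark schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[LANDMARK_COLS]
  bad_label <- which(!raw$label %in% LANDMARK_LABELS)
  if (length(bad_label) > 0) {
    stop(sprintf("invalid landmark label(s) at data row(s) %s (expected P1..P12)",
                 paste(utils::head(bad_label, 5), collapse = ", ")),
         call. = FALSE)
  }
  num <- lapply(raw[c("x_px", "y_px", "ruler_length_mm")], function(col) {
    suppressWarnings(as.numeric(col))
  })
  for (nm in names(num)) {
    bad <- which(is.na(num[[nm]]) & !is.na(raw[[nm]]) & nzchar(raw[[nm]]))
    bad <- union(bad, which(is.na(num[[nm]])))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column %s at data row(s) %s",
                   nm, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    observer_id = raw$observer_id,
    session_id = raw$session_id,
    label = raw$label,
    x_px = num$x_px,
    y_px = num$y_px,
    ruler_length_mm = num$ruler_length_mm
  )
  dup <- duplicated(out[c("patient_id", "observer_id", "session_id", "label")])
  if (any(dup)) {
    stop(sprintf("duplicate (patient, observer, session, label) at data row(s) %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")),
         call. = FALSE)
  }
  if (any(out$ruler_length_mm <= 0)) {
    stop("ruler_length_mm must be positive", call. = FALSE)
  }
  out
}

#' Write a landmark table to CSV
#'
#' @param landmarks Landmark tibble as returned by [read_landmark_csv()] or
#'   [render_landmarks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(landmarks, path) {
  stopifnot(all(LANDMARK_COLS %in% names(landmarks)))
  utils::write.csv(landmarks[LANDMARK_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-sheet validation summary
#'
#' Summarises each (patient, observer, session) sheet: number of points,
#' completeness (all 12 labels present exactly once), and whether the two
#' ruler calibration points are distinct.
#'
#' @param landmarks Landmark tibble.
#' @return Tibble with one row per sheet: `patient_id`, `observer_id`,
#'   `session_id`, `n_points`, `complete`, `calibration_ok`.
#' @export
sheet_summary <- function(landmarks) {
  landmarks |>
    dplyr::group_by(.data$patient_id, .data$observer_id, .data$session_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      complete = all(LANDMARK_LABELS %in% .data$label) && dplyr::n() == 12L,
      calibration_ok = {
        p1 <- which(.data$label == "P1")
        p2 <- which(.data$label == "P2")
        length(p1) == 1 && length(p2) == 1 &&
          (.data$x_px[p1] != .data$x_px[p2] || .data$y_px[p1] != .data$y_px[p2])
      },
      .groups = "drop"
    )
}

#' Convert landmark sheets from pixels to millimetres
#'
#' Calibrates every sheet with its own ruler points (P1, P2 and
#' `ruler_length_mm`) and rescales all coordinates to mm. Sheets whose
#' calibration points coincide are dropped with a warning naming them.
#'
#' @param landmarks Landmark tibble (pixel coordinates).
#' @return Tibble `patient_id`, `observer_id`, `session_id`, `label`,
#'   `x_mm`, `y_mm`, `scale_mm_per_px`.
#' @export
calibrate_landmarks <- function(landmarks) {
  landmarks |>
    dplyr::group_by(.data$patient_id, .data$observer_id, .data$session_id) |>
    dplyr::group_modify(function(df, key) {
      i1 <- which(df$label == "P1")
      i2 <- which(df$label == "P2")
      if (length(i1) != 1 || length(i2) != 1) {
        warning(sprintf("sheet %s/%s/%s lacks calibration points; dropped",
                        key$patient_id, key$observer_id, key$session_id),
                call. = FALSE)
        return(df[0, c("label", "x_px", "y_px")] |>
                 dplyr::mutate(x_mm = double(), y_mm = double(),
                               scale_mm_per_px = double()) |>
                 dplyr::select(-"x_px", -"y_px"))
      }
      sc <- tryCatch(
        calibrate(c(df$x_px[i1], df$y_px[i1]), c(df$x_px[i2], df$y_px[i2]),
                  df$ruler_length_mm[[1]]),
        error = function(e) NA_real_
      )
      if (is.na(sc)) {
        warning(sprintf("sheet %s/%s/%s has degenerate calibration; dropped",
                        key$patient_id, key$observer_id, key$session_id),
                call. = FALSE)
        return(tibble::tibble(label = character(), x_mm = double(),
                              y_mm = double(), scale_mm_per_px = double()))
      }
      tibble::tibble(label = df$label, x_mm = df$x_px * sc,
                     y_mm = df$y_px * sc, scale_mm_per_px = sc)
    }) |>
    dplyr::ungroup()
}

#' Write / read the per-sinus cohort table
#'
#' The cohort table holds one row per measured sinus with its covariates
#' and derived measurements; it is the unit of all downstream statistics.
#' Numeric measurement columns are written with six decimals, so a
#' write-then-read round trip reproduces the table to that precision.
#'
#' @param cohort Cohort tibble with columns `patient_id`, `side`, `gender`,
#'   `dentition`, `age`, `sinus_depth_mm`, `alveolar_height_mm`,
#'   `opening_angle_deg` and optionally `sinus_class`.
#' @param path File path.
#' @return `path` invisibly (write); the cohort tibble (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  if (nrow(cohort) == 0) {
    stop("cohort is empty: nothing to write", call. = FALSE)
  }
  out <- cohort
  if (!"sinus_class" %in% names(out)) out$sinus_class <- NA_character_
  missing_cols <- setdiff(setdiff(COHORT_COLS, "sinus_class"), names(out))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- out[COHORT_COLS]
  for (nm in c("sinus_depth_mm", "alveolar_height_mm", "opening_angle_deg")) {
    out[[nm]] <- sprintf("%.6f", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[COHORT_COLS])
  out$patient_id <- as.character(out$patient_id)
  out$sinus_class <- as.character(out$sinus_class)
  out$sinus_class[out$sinus_class %in% c("", "NA")] <- NA_character_
  out
}

#' Read patient metadata
#'
#' @param path CSV with header `patient_id,gender,dentition,age`.
#' @return Validated tibble; `gender` in {female, male}, `dentition` in
#'   {dentate, edentulous}, `age >= 18` (the study inclusion criterion).
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(tibble::as_tibble(raw))
}

validate_metadata <- function(meta) {
  need <- c("patient_id", "gender", "dentition", "age")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    stop(sprintf("metadata schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  meta$patient_id <- as.character(meta$patient_id)
  if (!all(meta$gender %in% c("female", "male"))) {
    stop("metadata: gender must be 'female' or 'male'", call. = FALSE)
  }
  if (!all(meta$dentition %in% c("dentate", "edentulous"))) {
    stop("metadata: dentition must be 'dentate' or 'edentulous'", call. = FALSE)
  }
  if (any(!is.finite(meta$age)) || any(meta$age < 18)) {
    stop("metadata: age must be finite and >= 18", call. = FALSE)
  }
  if (anyDuplicated(meta$patient_id)) {
    stop("metadata: duplicated patient_id", call. = FALSE)
  }
  meta[need]
}
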