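#' Measure a cohort from landmark sheets
#'
#' The core measurement pass: validates sheets, calibrates each sheet with
#' its own ruler, aggregates replicate placements into consensus landmarks
#' with gross-error flagging, builds the palatal axis per patient and
#' measures both sinuses. Patients whose consensus could not be resolved
#' (fewer than two agreeing replicates for a landmark) or whose sides lack
#' required landmarks are excluded with a logged reason — the analogue of
#' the study's per-scan exclusions for indistinguishable bone contours.
#'
#' @param landmarks Landmark tibble (pixel coordinates), e.g. from
#'   [read_landmark_csv()] or [render_landmarks()].
#' @param meta Patient metadata tibble (`patient_id`, `gender`,
#'   `dentition`, `age`).
#' @param consensus_threshold_mm Gross-error threshold (mm).
#' @param ah_method Alveolar-height convention, see [alveolar_height()].
#' @param drop_unresolved Exclude patients with unresolved consensus
#'   landmarks that a measurement depends on (default `TRUE`).
#' @return List with `cohort` (per-sinus measurement tibble), `flags`
#'   (consensus flag report) and `exclusions` (tibble `patient_id`,
#'   `side`, `reason`).
#' @export
measure_cohort <- function(landmarks, meta,
                           consensus_threshold_mm = 2,
                           ah_method = c("euclidean", "projected"),
                           drop_unresolved = TRUE) {
  ah_method <- match.arg(ah_method)
  meta <- validate_metadata(meta)
  mm <- calibrate_landmarks(landmarks)
  records <- list()
  flags <- list()
  excl <- list()
  note_excl <- function(pid, side, reason) {
    excl[[length(excl) + 1]] <<- tibble::tibble(
      patient_id = pid, side = side, reason = reason)
  }
  for (pid in unique(mm$patient_id)) {
    sub <- mm[mm$patient_id == pid, ]
    cs <- consensus_sheet(sub, consensus_threshold_mm)
    flags[[pid]] <- cs$report
    bad <- cs$report$label[!cs$report$resolved]
    axis_labs <- c("P7", "P12")
    if (!all(axis_labs %in% names(cs$points))) {
      note_excl(pid, "both", paste0("missing palatal landmarks: ",
                paste(setdiff(axis_labs, names(cs$points)), collapse = ", ")))
      next
    }
    if (drop_unresolved && any(axis_labs %in% bad)) {
      note_excl(pid, "both", "unresolved consensus on palatal landmarks")
      next
    }
    # orient the palatal normal toward image-inferior (+y in the raster
    # convention): robust even when an alveolar tip lies above the
    # palatal line, as it can in deep class I recessus
    mid <- (cs$points$P7 + cs$points$P12) / 2
    axis <- palatal_axis(cs$points$P7, cs$points$P12, mid + c(0, 1))
    for (side in c("right", "left")) {
      need <- unlist(side_labels(side), use.names = FALSE)
      if (drop_unresolved && any(need %in% bad)) {
        note_excl(pid, side, paste0(
          "unresolved consensus: ",
          paste(intersect(need, bad), collapse = ", ")))
        next
      }
      m <- measure_sinus(cs$points, side, axis = axis,
                         ah_method = ah_method)
      if (nrow(m) == 0) {
        note_excl(pid, side, attr(m, "skip_reason"))
        next
      }
      records[[length(records) + 1]] <-
        dplyr::mutate(m, patient_id = pid, .before = 1)
    }
  }
  cohort <- dplyr::bind_rows(records)
  if (nrow(cohort) > 0) {
    cohort <- cohort |>
      dplyr::rename(sinus_depth_mm = "sinus_depth",
                    alveolar_height_mm = "alveolar_height",
                    opening_angle_deg = "opening_angle") |>
      dplyr::inner_join(meta, by = "patient_id") |>
      dplyr::select("patient_id", "side", "gender", "dentition", "age",
                    "sinus_depth_mm", "alveolar_height_mm",
                    "opening_angle_deg")
  }
  list(cohort = cohort,
       flags = dplyr::bind_rows(flags),
       exclusions = if (length(excl) > 0) dplyr::bind_rows(excl) else
         tibble::tibble(patient_id = character(), side = character(),
                        reason = character()))
}

#' Run the full measurement-to-statistics pipeline
#'
#' End-to-end orchestration: read (or accept) landmark sheets and patient
#' metadata, calibrate, build consensus landmarks, measure every sinus,
#' classify by sinus depth, fit the standard comparison models and write
#' all outputs (cohort CSV, class-limit report, consensus flag report,
#' model table, run log) to an output directory. Running twice on the
#' same inputs produces byte-identical outputs.
#'
#' @param landmarks Landmark tibble or path to a landmark CSV.
#' @param meta Metadata tibble or path to a metadata CSV.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param consensus_threshold_mm Gross-error threshold (mm).
#' @param class_mode `"quartile"` (limits from this cohort) or `"fixed"`.
#' @param class_lower,class_upper Fixed class limits (mm).
#' @param strata Stratification column for quartile limits (default
#'   `"dentition"`, the study's grouping; `NULL` pools).
#' @param ah_method Alveolar-height convention.
#' @param run_models Fit the comparison models (default `TRUE`; needs at
#'   least two levels per factor).
#' @return List: `cohort` (classified), `limits`, `flags`, `exclusions`,
#'   `models` (or `NULL`), `log` (character vector of log lines).
#' @export
run_pipeline <- function(landmarks, meta, out_dir = NULL,
                         consensus_threshold_mm = 2,
                         class_mode = c("quartile", "fixed"),
                         class_lower = 0, class_upper = 6,
                         strata = "dentition",
                         ah_method = c("euclidean", "projected"),
                         run_models = TRUE) {
  class_mode <- match.arg(class_mode)
  ah_method <- match.arg(ah_method)
  logln <- character()
  say <- function(...) {
    line <- sprintf(...)
    logln <<- c(logln, line)
    message(line)
  }
  if (is.character(landmarks)) landmarks <- read_landmark_csv(landmarks)
  if (is.character(meta)) meta <- read_metadata_csv(meta)
  sheets <- sheet_summary(landmarks)
  say("pipeline: %d landmark rows, %d sheets (%d complete), %d patients",
      nrow(landmarks), nrow(sheets), sum(sheets$complete),
      length(unique(landmarks$patient_id)))
  res <- measure_cohort(landmarks, meta,
                        consensus_threshold_mm = consensus_threshold_mm,
                        ah_method = ah_method)
  for (i in seq_len(nrow(res$exclusions))) {
    say("excluded %s (%s): %s", res$exclusions$patient_id[i],
        res$exclusions$side[i], res$exclusions$reason[i])
  }
  say("measured %d sinuses from %d patients (%d flagged landmarks, %d excluded sides)",
      nrow(res$cohort), length(unique(res$cohort$patient_id)),
      sum(res$flags$flagged),
      sum(ifelse(res$exclusions$side == "both", 2L, 1L)))
  if (nrow(res$cohort) == 0) stop("no sinuses could be measured", call. = FALSE)
  cohort <- classify_cohort(res$cohort, mode = class_mode,
                            lower = class_lower, upper = class_upper,
                            strata = if (class_mode == "quartile") strata)
  limits <- attr(cohort, "limits")
  say("classified %d sinuses: limits (%g, %g) mm [%s]; classes I/II/III = %s",
      nrow(cohort), limits$lower, limits$upper, class_mode,
      paste(table(factor(cohort$sinus_class, c("I", "II", "III"))),
            collapse = "/"))
  models <- NULL
  if (run_models) {
    models <- tryCatch(standard_models(cohort), error = function(e) {
      say("model fitting skipped: %s", conditionMessage(e))
      NULL
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(res$flags, file.path(out_dir, "consensus_flags.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(limits$detail$per_stratum %||%
                       data.frame(lower = limits$lower,
                                  upper = limits$upper),
                     file.path(out_dir, "class_limits.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(models)) {
      utils::write.csv(models, file.path(out_dir, "models.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    writeLines(logln, file.path(out_dir, "run_log.txt"))
    say("outputs written to %s", out_dir)
  }
  list(cohort = cohort, limits = limits, flags = res$flags,
       exclusions = res$exclusions, models = models, log = logln)
}
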