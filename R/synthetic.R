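# Truncated-normal helpers. The location parameter is calibrated so that
# the *truncated* mean equals the requested mean: a model stated as
# "13.0 +/- 4.9 mm, support > 0" really has mean 13.0.

ptnorm <- function(q, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  (stats::pnorm(q, mean, sd) - pa) / (pb - pa)
}

qtnorm <- function(p, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + p * (pb - pa), mean, sd)
}

rtnorm <- function(n, mean, sd, lower, upper) {
  qtnorm(stats::runif(n), mean, sd, lower, upper)
}

tnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) {
    # essentially all mass truncated away: mean collapses onto the
    # nearer support boundary
    return(if (stats::pnorm(a) > 0.5) lower else upper)
  }
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

tnorm_var <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  sd^2 * (1 + (aa - bb) / z - ((da - db) / z)^2)
}

# location such that the truncated distribution has the target mean;
# the truncated mean is monotone increasing in the location, so expand a
# bracket around the target until it straddles the root
tnorm_loc <- function(target_mean, sd, lower, upper) {
  if (target_mean <= lower || target_mean >= upper) {
    stop("target mean must lie strictly inside the truncation support",
         call. = FALSE)
  }
  f <- function(m) tnorm_mean(m, sd, lower, upper) - target_mean
  lo <- target_mean - sd
  hi <- target_mean + sd
  for (i in 1:60) {
    if (f(lo) <= 0) break
    lo <- target_mean - (target_mean - lo) * 2
  }
  for (i in 1:60) {
    if (f(hi) >= 0) break
    hi <- target_mean + (hi - target_mean) * 2
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Class-conditional sinus-depth model
#'
#' Signed sinus depth is modelled as a three-component mixture whose
#' supports partition at the class boundaries 0 and 6 mm: class I depths
#' are negative (floor above the palate), class II depths lie in
#' \[0, 6\] mm, class III depths exceed 6 mm. Component I is a negative
#' half-normal anchored at 0, component II a truncated normal centred in
#' the class interval, component III a positive half-normal anchored at
#' 6 mm. With the default class probabilities (0.25, 0.50, 0.25) the
#' population quartiles are exactly 0 and 6 mm by construction; the two
#' half-normal spreads are then calibrated so the pooled mixture matches
#' the requested overall mean and standard deviation.
#'
#' @param mean,sd Target pooled mean and SD of depth (mm).
#' @param class_probs Class probabilities, summing to 1.
#' @param breaks The two class boundaries (mm), default `c(0, 6)`.
#' @param mid_sd Spread of the middle (class II) component (mm).
#' @return Object of class `depth_model` with component parameters and the
#'   implied pooled moments.
#' @export
depth_model <- function(mean = 3.0, sd = 5.4,
                        class_probs = c(0.25, 0.50, 0.25),
                        breaks = c(0, 6), mid_sd = 2) {
  stopifnot(length(class_probs) == 3, all(class_probs > 0),
            abs(sum(class_probs) - 1) < 1e-9,
            length(breaks) == 2, breaks[1] < breaks[2], mid_sd > 0)
  b1 <- breaks[1]
  b2 <- breaks[2]
  p <- class_probs
  mid <- (b1 + b2) / 2
  cc <- sqrt(2 / pi)
  v2 <- tnorm_var(mid, mid_sd, b1, b2)
  e2_sq <- mid^2 + v2
  m0 <- p[1] * b1 + p[2] * mid + p[3] * b2
  # mean constraint ties the two half-normal spreads together; solve the
  # remaining spread against the pooled SD
  s3_of <- function(s1) (mean - m0 + p[1] * cc * s1) / (p[3] * cc)
  pooled_sd <- function(s1) {
    s3 <- s3_of(s1)
    m2 <- p[1] * (b1^2 - 2 * b1 * cc * s1 + s1^2) + p[2] * e2_sq +
      p[3] * (b2^2 + 2 * b2 * cc * s3 + s3^2)
    sqrt(max(m2 - mean^2, 0))
  }
  lo <- max(1e-6, (m0 - mean) / (p[1] * cc) + 1e-6)  # keep s3 > 0
  f <- function(s1) pooled_sd(s1) - sd
  if (f(lo) > 0) {
    stop(sprintf(
      "depth model infeasible: sd %.3f is below the minimum %.3f implied by mean %.3f",
      sd, pooled_sd(lo), mean), call. = FALSE)
  }
  s1 <- stats::uniroot(f, c(lo, 1000), tol = 1e-12)$root
  s3 <- s3_of(s1)
  structure(
    list(mean = mean, sd = sd, class_probs = p, breaks = breaks,
         mid = mid, mid_sd = mid_sd, s1 = s1, s3 = s3),
    class = "depth_model"
  )
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf(
    "<depth_model> pooled %.2f +/- %.2f mm; class probs (%.2f, %.2f, %.2f)\n",
    x$mean, x$sd, x$class_probs[1], x$class_probs[2], x$class_probs[3]))
  cat(sprintf("  I: half-normal below %g (spread %.3f); II: N(%g, %g) on [%g, %g]; III: half-normal above %g (spread %.3f)\n",
              x$breaks[1], x$s1, x$mid, x$mid_sd, x$breaks[1], x$breaks[2],
              x$breaks[2], x$s3))
  invisible(x)
}

# mixture quantile function of a depth model
qdepth <- function(u, model) {
  p <- model$class_probs
  c1 <- p[1]
  c2 <- p[1] + p[2]
  b1 <- model$breaks[1]
  b2 <- model$breaks[2]
  out <- numeric(length(u))
  i1 <- u < c1
  i2 <- u >= c1 & u <= c2
  i3 <- u > c2
  out[i1] <- qtnorm(u[i1] / c1, b1, model$s1, -Inf, b1)
  out[i2] <- qtnorm((u[i2] - c1) / p[2], model$mid, model$mid_sd, b1, b2)
  out[i3] <- qtnorm((u[i3] - c2) / p[3], b2, model$s3, b2, Inf)
  out
}

#' Synthetic cohort specification
#'
#' Describes a virtual study population: how many patients per
#' gender-by-dentition cell (two sinuses each), the class-structured depth
#' model, class-conditional alveolar-height and opening-angle models, a
#' dentition offset on alveolar height, and the age distribution. Model
#' means are the actual means of the (truncated) sampling distributions.
#'
#' Two sampling modes exist. `"random"` draws every quantity
#' independently from its model — a realistic cohort with sampling noise.
#' `"deterministic"` replaces random draws by midpoint quantiles
#' (u = (i - 1/2)/n) of the same distributions within each cell, so sample
#' moments match the model essentially exactly and distribution-level
#' targets can be checked without Monte-Carlo slack.
#'
#' @param n_patients Patients per cell: a single count (all four
#'   gender-by-dentition cells) or a named vector with names among
#'   `female_dentate`, `female_edentulous`, `male_dentate`,
#'   `male_edentulous` (cells omitted or 0 are skipped).
#' @param class_probs Sinus-class probabilities (I, II, III).
#' @param depth Pooled depth model: `list(mean =, sd =)` in mm.
#' @param depth_by_gender Optional per-gender override: named list
#'   `female`/`male` of `list(mean =, sd =)`.
#' @param ah_class_mean,ah_class_sd Alveolar height mean/SD (mm) per class
#'   I, II, III; support truncated to > 0.
#' @param ah_dentition_offset Additive shift (mm) of the alveolar-height
#'   mean, named `dentate`/`edentulous`. The default `c(1.3, -1.3)`
#'   reproduces the reported ~2.6 mm dentate-edentulous gap while leaving
#'   class means unchanged in dentition-balanced cohorts.
#' @param angle_class_mean,angle_class_sd Opening angle mean/SD (degrees)
#'   per class; support truncated to (0, 180).
#' @param age_mean,age_sd Patient age model (years), truncated at >= 18.
#' @param sampling `"random"` or `"deterministic"`.
#' @param seed Integer seed for `"random"` sampling.
#' @param mid_sd Spread of the class II depth component (mm).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        class_probs = c(0.25, 0.50, 0.25),
                        depth = list(mean = 3.0, sd = 5.4),
                        depth_by_gender = NULL,
                        ah_class_mean = c(13.0, 7.7, 5.44),
                        ah_class_sd = c(4.9, 2.9, 2.52),
                        ah_dentition_offset = c(dentate = 1.3,
                                                edentulous = -1.3),
                        angle_class_mean = c(113.87, 101.19, 90.13),
                        angle_class_sd = c(17.56, 13.32, 10.73),
                        age_mean = 57.5, age_sd = 16.5,
                        sampling = c("random", "deterministic"),
                        seed = 0, mid_sd = 2) {
  sampling <- match.arg(sampling)
  cells <- c("female_dentate", "female_edentulous",
             "male_dentate", "male_edentulous")
  if (is.null(names(n_patients))) {
    stopifnot(length(n_patients) == 1, n_patients >= 1)
    n_patients <- stats::setNames(rep(n_patients, 4), cells)
  } else {
    stopifnot(all(names(n_patients) %in% cells), all(n_patients >= 0),
              sum(n_patients) >= 1)
  }
  stopifnot(length(class_probs) == 3, abs(sum(class_probs) - 1) < 1e-9,
            all(class_probs > 0),
            length(ah_class_mean) == 3, length(ah_class_sd) == 3,
            all(ah_class_sd > 0), all(ah_class_mean > 0),
            length(angle_class_mean) == 3, length(angle_class_sd) == 3,
            all(angle_class_sd > 0),
            all(angle_class_mean > 0), all(angle_class_mean < 180),
            all(c("dentate", "edentulous") %in% names(ah_dentition_offset)),
            age_sd > 0)
  dm <- list(pooled = depth_model(depth$mean, depth$sd, class_probs,
                                  mid_sd = mid_sd))
  if (!is.null(depth_by_gender)) {
    stopifnot(all(names(depth_by_gender) %in% c("female", "male")))
    for (g in names(depth_by_gender)) {
      dg <- depth_by_gender[[g]]
      dm[[g]] <- depth_model(dg$mean, dg$sd, class_probs, mid_sd = mid_sd)
    }
  }
  structure(
    list(n_patients = n_patients, class_probs = class_probs,
         depth_models = dm,
         ah_class_mean = ah_class_mean, ah_class_sd = ah_class_sd,
         ah_dentition_offset = ah_dentition_offset,
         angle_class_mean = angle_class_mean,
         angle_class_sd = angle_class_sd,
         age_mean = age_mean, age_sd = age_sd,
         sampling = sampling, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate ground-truth sinus measurements
#'
#' Draws a cohort from a [cohort_spec()]: per sinus a class, a signed
#' depth from the class-conditional depth component, an alveolar height
#' from the (class x dentition) model and an opening angle from the class
#' model; per patient an age. Each patient contributes a right and a left
#' sinus. Deterministic given the spec (and its seed in random mode).
#'
#' @param spec A [cohort_spec()].
#' @return Truth tibble: `patient_id`, `side`, `gender`, `dentition`,
#'   `age`, `sinus_class`, `sinus_depth_mm`, `alveolar_height_mm`,
#'   `opening_angle_deg`.
#' @export
simulate_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$sampling == "random") set.seed(spec$seed)
  cells <- spec$n_patients[spec$n_patients > 0]
  out <- vector("list", length(cells))
  pid0 <- 0L
  for (ci in seq_along(cells)) {
    parts <- strsplit(names(cells)[ci], "_", fixed = TRUE)[[1]]
    gender <- parts[1]
    dentition <- parts[2]
    npat <- as.integer(cells[ci])
    m <- 2L * npat
    dmod <- spec$depth_models[[gender]] %||% spec$depth_models$pooled
    off <- spec$ah_dentition_offset[[dentition]]
    ah_loc <- vapply(1:3, function(k) {
      tnorm_loc(spec$ah_class_mean[k] + off, spec$ah_class_sd[k], 0, Inf)
    }, numeric(1))
    an_loc <- vapply(1:3, function(k) {
      tnorm_loc(spec$angle_class_mean[k], spec$angle_class_sd[k], 0, 180)
    }, numeric(1))
    age_loc <- tnorm_loc(spec$age_mean, spec$age_sd, 18, Inf)
    if (spec$sampling == "deterministic") {
      u <- (seq_len(m) - 0.5) / m
      depth <- qdepth(u, dmod)
      cls <- as.integer(cut(depth, c(-Inf, dmod$breaks[1], dmod$breaks[2], Inf),
                            right = FALSE))
      cls[depth == dmod$breaks[2]] <- 2L  # boundary belongs to class II
      ah <- angle <- numeric(m)
      for (k in 1:3) {
        idx <- which(cls == k)   # contiguous, depth ascending
        nk <- length(idx)
        if (nk == 0) next
        uk <- (seq_len(nk) - 0.5) / nk
        # deeper sinus extension pairs with smaller ridge height and
        # narrower opening angle, the trend seen across classes
        ah[idx] <- qtnorm(rev(uk), ah_loc[k], spec$ah_class_sd[k], 0, Inf)
        angle[idx] <- qtnorm(rev(uk), an_loc[k], spec$angle_class_sd[k],
                             0, 180)
      }
      age_pat <- qtnorm((seq_len(npat) - 0.5) / npat, age_loc,
                        spec$age_sd, 18, Inf)
    } else {
      cls <- sample.int(3, m, replace = TRUE, prob = spec$class_probs)
      depth <- numeric(m)
      b1 <- dmod$breaks[1]
      b2 <- dmod$breaks[2]
      depth[cls == 1] <- rtnorm(sum(cls == 1), b1, dmod$s1, -Inf, b1)
      depth[cls == 2] <- rtnorm(sum(cls == 2), dmod$mid, dmod$mid_sd, b1, b2)
      depth[cls == 3] <- rtnorm(sum(cls == 3), b2, dmod$s3, b2, Inf)
      ah <- rtnorm(m, ah_loc[cls], spec$ah_class_sd[cls], 0, Inf)
      angle <- rtnorm(m, an_loc[cls], spec$angle_class_sd[cls], 0, 180)
      age_pat <- rtnorm(npat, age_loc, spec$age_sd, 18, Inf)
    }
    out[[ci]] <- tibble::tibble(
      patient_id = sprintf("pt%05d", pid0 + rep(seq_len(npat), each = 2L)),
      side = rep(c("right", "left"), npat),
      gender = gender, dentition = dentition,
      age = rep(round(age_pat, 1), each = 2L),
      sinus_class = c("I", "II", "III")[cls],
      sinus_depth_mm = depth,
      alveolar_height_mm = ah,
      opening_angle_deg = angle
    )
    pid0 <- pid0 + npat
  }
  dplyr::bind_rows(out)
}

#' Patient metadata of a truth table
#'
#' @param truth Output of [simulate_truth()].
#' @return One row per patient: `patient_id`, `gender`, `dentition`, `age`.
#' @export
truth_metadata <- function(truth) {
  dplyr::distinct(truth, .data$patient_id, .data$gender,
                  .data$dentition, .data$age)
}

#' Rendering specification for synthetic landmark sheets
#'
#' Controls how ground-truth measurements are turned back into pixel
#' landmark sheets: image scale, palatal tilt, sinus-wall ray length, the
#' digital ruler, the replicate design (observers x sessions), isotropic
#' observer noise, and an optional gross-error process that displaces one
#' replicate of a landmark by a fixed magnitude in a random direction.
#'
#' @param scale_mm_per_px Image scale (mm per pixel, > 0). Default 0.5,
#'   a typical coronal CT in-plane resolution.
#' @param palatal_tilt_deg Tilt of the palatal line against the image x
#'   axis (degrees).
#' @param wall_length_mm Length of the rays from the sinus floor to the
#'   two wall-top landmarks (mm).
#' @param ruler_length_mm Physical length of the digital ruler (mm).
#' @param noise_sd_mm Isotropic per-coordinate observer noise SD (mm) for
#'   the anatomical landmarks; 0 disables noise.
#' @param ruler_noise_sd_mm Noise SD (mm) for the two ruler endpoints.
#'   Defaults to 0: the digital ruler is a software graphic with
#'   unambiguous endpoints, unlike anatomical contours. Nonzero values
#'   propagate a coherent calibration error to the whole sheet.
#' @param gross_error_rate Probability that a landmark of a patient gets
#'   one grossly displaced replicate.
#' @param gross_error_mm Displacement magnitude of a gross error (mm);
#'   must exceed the 2 mm consensus flag threshold.
#' @param n_observers,n_sessions Replicate design (2 x 2 in the study).
#' @param seed Integer seed for noise and gross errors.
#' @return Object of class `render_spec`.
#' @export
render_spec <- function(scale_mm_per_px = 0.5, palatal_tilt_deg = 0,
                        wall_length_mm = 20, ruler_length_mm = 50,
                        noise_sd_mm = 0.3, ruler_noise_sd_mm = 0,
                        gross_error_rate = 0,
                        gross_error_mm = 5, n_observers = 2,
                        n_sessions = 2, seed = 0) {
  stopifnot(scale_mm_per_px > 0, wall_length_mm > 0, ruler_length_mm > 0,
            noise_sd_mm >= 0, ruler_noise_sd_mm >= 0,
            gross_error_rate >= 0, gross_error_rate <= 1,
            n_observers >= 1, n_sessions >= 1)
  if (gross_error_rate > 0 && gross_error_mm <= 2) {
    stop("gross_error_mm must exceed the 2 mm consensus threshold",
         call. = FALSE)
  }
  structure(
    list(scale_mm_per_px = scale_mm_per_px,
         palatal_tilt_deg = palatal_tilt_deg,
         wall_length_mm = wall_length_mm,
         ruler_length_mm = ruler_length_mm,
         noise_sd_mm = noise_sd_mm,
         ruler_noise_sd_mm = ruler_noise_sd_mm,
         gross_error_rate = gross_error_rate,
         gross_error_mm = gross_error_mm,
         n_observers = as.integer(n_observers),
         n_sessions = as.integer(n_sessions),
         seed = as.integer(seed)),
    class = "render_spec"
  )
}

rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

#' Render ground truth to replicated pixel landmark sheets
#'
#' Inverts the measurement geometry: for each patient a palatal line at
#' the specified tilt carries the two palatal landmarks; each side's
#' sinus-floor landmark sits at the signed perpendicular offset equal to
#' the true depth, the alveolar tip at Euclidean distance equal to the
#' true height further inferior, and the two wall-top landmarks on rays
#' from the floor subtending exactly the true opening angle, opening
#' superiorly. Ruler landmarks consistent with the image scale are added,
#' coordinates are converted to pixels, and the sheet is replicated per
#' observer and session with isotropic noise and optional gross errors.
#' At zero noise, measuring the rendered sheets reproduces the truth to
#' floating-point accuracy for any tilt and scale.
#'
#' @param truth Truth tibble from [simulate_truth()] (or any table with
#'   `patient_id`, `side`, `sinus_depth_mm`, `alveolar_height_mm`,
#'   `opening_angle_deg`).
#' @param rspec A [render_spec()].
#' @return Landmark tibble in the landmark CSV schema.
#' @export
render_landmarks <- function(truth, rspec = render_spec()) {
  stopifnot(inherits(rspec, "render_spec"))
  need <- c("patient_id", "side", "sinus_depth_mm", "alveolar_height_mm",
            "opening_angle_deg")
  stopifnot(all(need %in% names(truth)))
  if (any(truth$opening_angle_deg <= 0 | truth$opening_angle_deg >= 180)) {
    stop("cannot render opening angles outside (0, 180)", call. = FALSE)
  }
  if (any(truth$alveolar_height_mm < 0)) {
    stop("cannot render negative alveolar heights", call. = FALSE)
  }
  set.seed(rspec$seed)
  tilt <- rspec$palatal_tilt_deg
  u <- c(cos(tilt * pi / 180), sin(tilt * pi / 180)) # along palate
  nrm <- c(-u[2], u[1])                              # inferior (y down)
  centre <- c(128, 100)
  half_gap <- 40   # sinus centres sit this far from the midline (mm)
  pal_half <- 25   # palatal landmarks this far from the midline (mm)
  wl <- rspec$wall_length_mm
  patients <- split(truth, truth$patient_id)
  sheets <- vector("list", length(patients))
  for (pi in seq_along(patients)) {
    tr <- patients[[pi]]
    pid <- tr$patient_id[1]
    pts <- list(
      P1 = c(10, 10),
      P2 = c(10, 10) + rspec$ruler_length_mm * c(1, 0),
      P7 = centre - pal_half * u,
      P12 = centre + pal_half * u
    )
    for (si in seq_len(nrow(tr))) {
      side <- tr$side[si]
      sgn <- if (side == "right") -1 else 1
      lab <- side_labels(side)
      floor_pt <- centre + sgn * half_gap * u + tr$sinus_depth_mm[si] * nrm
      tip_pt <- floor_pt + tr$alveolar_height_mm[si] * nrm
      half <- tr$opening_angle_deg[si] / 2
      up <- -nrm
      pts[[lab$lateral]] <- floor_pt + wl * rot2(up, sgn * half)
      pts[[lab$medial]] <- floor_pt + wl * rot2(up, -sgn * half)
      pts[[lab$floor]] <- floor_pt
      pts[[lab$tip]] <- tip_pt
    }
    labs <- names(pts)
    base <- do.call(rbind, pts) / rspec$scale_mm_per_px  # px
    noise_px <- ifelse(labs %in% c("P1", "P2"),
                       rspec$ruler_noise_sd_mm,
                       rspec$noise_sd_mm) / rspec$scale_mm_per_px
    n_rep <- rspec$n_observers * rspec$n_sessions
    rep_grid <- expand.grid(observer = seq_len(rspec$n_observers),
                            session = seq_len(rspec$n_sessions))
    rows <- vector("list", n_rep)
    # gross errors afflict anatomical landmarks, one replicate each
    anat <- setdiff(labs, c("P1", "P2"))
    gross_lab <- anat[stats::runif(length(anat)) < rspec$gross_error_rate]
    gross_rep <- stats::setNames(
      sample.int(n_rep, length(gross_lab), replace = TRUE), gross_lab)
    for (ri in seq_len(n_rep)) {
      xy <- base
      if (any(noise_px > 0)) {
        xy <- xy + matrix(stats::rnorm(length(base), 0, noise_px),
                          ncol = 2)
      }
      hit <- gross_lab[gross_rep == ri]
      for (gl in hit) {
        th <- stats::runif(1, 0, 2 * pi)
        xy[match(gl, labs), ] <- xy[match(gl, labs), ] +
          rspec$gross_error_mm / rspec$scale_mm_per_px * c(cos(th), sin(th))
      }
      rows[[ri]] <- tibble::tibble(
        patient_id = pid,
        observer_id = sprintf("obs%d", rep_grid$observer[ri]),
        session_id = as.character(rep_grid$session[ri]),
        label = labs,
        x_px = xy[, 1],
        y_px = xy[, 2],
        ruler_length_mm = rspec$ruler_length_mm
      )
    }
    sheets[[pi]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(sheets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
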