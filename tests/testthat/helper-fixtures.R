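# build a one-sheet landmark tibble from a named list of px points
make_sheet <- function(points, patient_id = "p1", observer_id = "obs1",
                       session_id = "1", ruler_length_mm = 50) {
  tibble::tibble(
    patient_id = patient_id,
    observer_id = observer_id,
    session_id = session_id,
    label = names(points),
    x_px = vapply(points, `[`, numeric(1), 1),
    y_px = vapply(points, `[`, numeric(1), 2),
    ruler_length_mm = ruler_length_mm
  )
}

# a geometrically valid full 12-point sheet (px, scale 0.5 mm/px)
full_sheet_points <- function() {
  tr <- tibble::tibble(
    patient_id = "p1", side = c("right", "left"),
    sinus_depth_mm = c(3, -2), alveolar_height_mm = c(7, 11),
    opening_angle_deg = c(100, 115)
  )
  lm <- sinusmorph::render_landmarks(
    tr, sinusmorph::render_spec(noise_sd_mm = 0, n_observers = 1,
                                n_sessions = 1))
  stats::setNames(Map(c, lm$x_px, lm$y_px), lm$label)
}

meta_for <- function(truth) sinusmorph::truth_metadata(truth)

# random rigid transform applied to a list/matrix of points
rigid_transform <- function(pts, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lapply(pts, function(p) as.numeric(R %*% p + shift))
}
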