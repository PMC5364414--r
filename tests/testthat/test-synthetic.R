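test_that("depth model calibration reproduces the requested pooled moments", {
  for (tgt in list(c(3.0, 5.4), c(3.1, 5.44), c(2.96, 5.41))) {
    dm <- depth_model(mean = tgt[1], sd = tgt[2])
    u <- (seq_len(2e5) - 0.5) / 2e5
    d <- sinusmorph:::qdepth(u, dm)
    expect_equal(mean(d), tgt[1], tolerance = 2e-3)
    expect_equal(stats::sd(d), tgt[2], tolerance = 2e-3)
    # quartiles sit at the class boundaries by construction
    expect_equal(unname(stats::quantile(d, c(0.25, 0.75))), c(0, 6),
                 tolerance = 1e-2)
  }
  expect_error(depth_model(mean = 3, sd = 0.1), "infeasible")
})

test_that("simulation is deterministic given the spec seed", {
  spec <- cohort_spec(n_patients = 10, seed = 17)
  expect_identical(simulate_truth(spec), simulate_truth(spec))
  lm1 <- render_landmarks(simulate_truth(spec), render_spec(seed = 4))
  lm2 <- render_landmarks(simulate_truth(spec), render_spec(seed = 4))
  expect_identical(lm1, lm2)
})

test_that("random-mode class frequencies match the class probabilities", {
  spec <- cohort_spec(n_patients = c(female_dentate = 2000), seed = 2)
  truth <- simulate_truth(spec)
  expect_equal(nrow(truth), 4000)
  freq <- table(factor(truth$sinus_class, c("I", "II", "III"))) / 4000
  expect_lt(max(abs(freq - c(0.25, 0.50, 0.25))), 0.02)
  # depths respect the class supports
  expect_true(all(truth$sinus_depth_mm[truth$sinus_class == "I"] < 0))
  expect_true(all(truth$sinus_depth_mm[truth$sinus_class == "II"] >= 0 &
                    truth$sinus_depth_mm[truth$sinus_class == "II"] <= 6))
  expect_true(all(truth$sinus_depth_mm[truth$sinus_class == "III"] > 6))
  expect_true(all(truth$alveolar_height_mm > 0))
  expect_true(all(truth$opening_angle_deg > 0 & truth$opening_angle_deg < 180))
  expect_true(all(truth$age >= 18))
})

test_that("deterministic sampling matches the model means without Monte-Carlo slack", {
  spec <- cohort_spec(n_patients = c(female_dentate = 197),
                      depth_by_gender = list(female = list(mean = 3.1,
                                                           sd = 5.44)),
                      ah_dentition_offset = c(dentate = 0, edentulous = 0),
                      sampling = "deterministic")
  truth <- simulate_truth(spec)
  expect_equal(mean(truth$sinus_depth_mm), 3.1, tolerance = 0.05 / 3.1)
  by_class <- cohort_summary(truth, "alveolar_height_mm", "sinus_class")
  expect_lt(max(abs(by_class$mean - c(13.0, 7.7, 5.44))), 0.05)
  by_class_an <- cohort_summary(truth, "opening_angle_deg", "sinus_class")
  expect_lt(max(abs(by_class_an$mean - c(113.87, 101.19, 90.13))), 0.5)
})

test_that("rendered sheets are schema-valid and measure back exactly at zero noise", {
  spec <- cohort_spec(n_patients = c(male_edentulous = 30),
                      sampling = "deterministic")
  truth <- simulate_truth(spec)
  for (rs in list(render_spec(noise_sd_mm = 0),
                  render_spec(noise_sd_mm = 0, palatal_tilt_deg = 12,
                              scale_mm_per_px = 0.3))) {
    lm <- render_landmarks(truth, rs)
    smry <- sheet_summary(lm)
    expect_true(all(smry$complete))
    expect_true(all(smry$calibration_ok))
    res <- measure_cohort(lm, truth_metadata(truth))
    joined <- dplyr::inner_join(truth, res$cohort,
                                by = c("patient_id", "side"),
                                suffix = c(".t", ".m"))
    expect_equal(nrow(joined), nrow(truth))
    expect_lt(max(abs(joined$sinus_depth_mm.t - joined$sinus_depth_mm.m)),
              1e-9)
    expect_lt(max(abs(joined$alveolar_height_mm.t -
                        joined$alveolar_height_mm.m)), 1e-9)
    expect_lt(max(abs(joined$opening_angle_deg.t -
                        joined$opening_angle_deg.m)), 1e-9)
  }
})

test_that("consensus over noisy replicates bounds the depth error as the noise model predicts", {
  # depth = (floor - palatal anchor) . normal, both ends carrying
  # median-of-4 consensus noise: at 0.3 mm landmark noise the depth error
  # SD is ~0.23 mm (0.3 x 0.55 per consensus point, two points plus a
  # small palatal-rotation lever), so ~95% of sinuses land within 0.5 mm
  # and ~99% within 0.75 mm of truth
  spec <- cohort_spec(n_patients = 25, seed = 6)
  truth <- simulate_truth(spec)
  lm <- render_landmarks(truth, render_spec(noise_sd_mm = 0.3, seed = 6))
  res <- measure_cohort(lm, truth_metadata(truth))
  joined <- dplyr::inner_join(truth, res$cohort,
                              by = c("patient_id", "side"),
                              suffix = c(".t", ".m"))
  err <- abs(joined$sinus_depth_mm.t - joined$sinus_depth_mm.m)
  expect_gte(mean(err < 0.5), 0.93)
  expect_gte(mean(err < 0.75), 0.99)
})

test_that("injected gross errors surface as consensus flags at the injected rate", {
  rate <- 0.05
  spec <- cohort_spec(n_patients = 50, seed = 8)
  truth <- simulate_truth(spec)
  lm <- render_landmarks(truth, render_spec(noise_sd_mm = 0.3,
                                            gross_error_rate = rate,
                                            seed = 8))
  res <- measure_cohort(lm, truth_metadata(truth))
  anat <- res$flags[!res$flags$label %in% c("P1", "P2"), ]
  n <- nrow(anat)
  phat <- mean(anat$flagged)
  ci <- rate + c(-1, 1) * 3 * sqrt(rate * (1 - rate) / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("render rejects geometrically impossible truths", {
  tr <- tibble::tibble(patient_id = "p", side = "right",
                       sinus_depth_mm = 3, alveolar_height_mm = 7,
                       opening_angle_deg = 185)
  expect_error(render_landmarks(tr), "0, 180")
  tr$opening_angle_deg <- 90
  tr$alveolar_height_mm <- -1
  expect_error(render_landmarks(tr), "negative")
})
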