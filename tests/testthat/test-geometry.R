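test_that("calibration converts ruler pixel distance to mm per px", {
  expect_equal(calibrate(c(0, 0), c(0, 200), 20), 0.1)
  # 3-4-5 triangle: pixel distance 50
  expect_equal(calibrate(c(0, 0), c(30, 40), 10), 0.2)
  expect_error(calibrate(c(5, 5), c(5, 5), 10), "coincide")
  expect_error(calibrate(c(0, 0), c(1, 1), -3), "positive")
  expect_error(calibrate(c(0, 0), c(1, 1), 0), "positive")
})

test_that("palatal axis orients its normal toward the alveolar hint", {
  ax <- palatal_axis(c(0, 0), c(100, 0), c(50, 30))
  expect_equal(ax$inferior_normal, c(0, 1))
  ax2 <- palatal_axis(c(0, 0), c(100, 0), c(50, -30))
  expect_equal(ax2$inferior_normal, c(0, -1))
  expect_equal(sum(ax$direction * ax$inferior_normal), 0)
  expect_equal(sqrt(sum(ax$direction^2)), 1)
  expect_error(palatal_axis(c(1, 1), c(1, 1), c(0, 0)), "degenerate")
})

test_that("palatal axis rotates with its defining points", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p7 <- c(10, 5); p12 <- c(90, 5); hint <- c(50, 40)
  ax <- palatal_axis(p7, p12, hint)
  axr <- palatal_axis(as.numeric(R %*% p7), as.numeric(R %*% p12),
                      as.numeric(R %*% hint))
  expect_equal(axr$direction, as.numeric(R %*% ax$direction))
  expect_equal(axr$inferior_normal, as.numeric(R %*% ax$inferior_normal))
})

test_that("sinus depth is the signed offset from the palatal line", {
  ax <- palatal_axis(c(0, 0), c(100, 0), c(50, 30))
  expect_equal(sinus_depth(c(40, 3), ax), 3)
  expect_equal(sinus_depth(c(77, 0), ax), 0)
  expect_equal(sinus_depth(c(40, -2.5), ax), -2.5)
})

test_that("sinus depth is linear along the inferior normal", {
  ax <- palatal_axis(c(3, 7), c(80, 22), c(40, 60))
  p <- c(35, 30)
  d0 <- sinus_depth(p, ax)
  for (t in c(-4, 0.5, 2, 11)) {
    expect_equal(sinus_depth(p + t * ax$inferior_normal, ax), d0 + t)
  }
})

test_that("all three statistics are rigid-transform invariant", {
  set.seed(11)
  for (i in 1:20) {
    pts <- list(p3 = stats::runif(2, 0, 50), p4 = stats::runif(2, 0, 50),
                p5 = stats::runif(2, 0, 50), p6 = stats::runif(2, 0, 50),
                p7 = c(0, 0), p12 = c(stats::runif(1, 40, 90), 0),
                hint = c(30, stats::runif(1, 10, 40)))
    ax <- palatal_axis(pts$p7, pts$p12, pts$hint)
    d <- sinus_depth(pts$p4, ax)
    h <- alveolar_height(pts$p6, pts$p4)
    a <- opening_angle(pts$p3, pts$p4, pts$p5)
    tp <- rigid_transform(pts, stats::runif(1, -180, 180),
                          stats::runif(2, -100, 100))
    axt <- palatal_axis(tp$p7, tp$p12, tp$hint)
    expect_lt(abs(sinus_depth(tp$p4, axt) - d), 1e-9)
    expect_lt(abs(alveolar_height(tp$p6, tp$p4) - h), 1e-9)
    expect_lt(abs(opening_angle(tp$p3, tp$p4, tp$p5) - a), 1e-9)
  }
})

test_that("alveolar height is the tip-to-floor distance", {
  expect_equal(alveolar_height(c(40, 10), c(40, 3)), 7)
  expect_equal(alveolar_height(c(43, 7), c(40, 3)), 5) # 3-4-5
  expect_equal(alveolar_height(c(12, 9), c(12, 9)), 0)
})

test_that("projected alveolar height measures along the palatal normal", {
  ax <- palatal_axis(c(0, 0), c(100, 0), c(50, 30))
  expect_equal(alveolar_height(c(43, 7), c(40, 3), method = "projected",
                               axis = ax), 4)
  expect_error(alveolar_height(c(43, 7), c(40, 3), method = "projected"),
               "axis")
})

test_that("opening angle matches hand-computed vertex angles", {
  expect_equal(opening_angle(c(-5, -5), c(0, 0), c(5, -5)), 90)
  # dot product cos = -0.5
  expect_equal(opening_angle(c(-sqrt(3), -1), c(0, 0), c(sqrt(3), -1)), 120)
  expect_equal(opening_angle(c(5, -5), c(0, 0), c(-5, -5)),
               opening_angle(c(-5, -5), c(0, 0), c(5, -5)))
  expect_error(opening_angle(c(0, 0), c(0, 0), c(1, 1)), "coincides")
  expect_error(opening_angle(c(-1, 0), c(0, 0), c(1, 0)), "collinear")
})

test_that("opening angle is symmetric under swapping the wall points", {
  set.seed(12)
  for (i in 1:20) {
    p3 <- stats::runif(2, -10, 10)
    p5 <- stats::runif(2, -10, 10)
    p4 <- stats::runif(2, 20, 30)
    expect_equal(opening_angle(p3, p4, p5), opening_angle(p5, p4, p3))
  }
})

test_that("measure_sinus recovers a rendered configuration and skips incomplete sides", {
  pts_px <- full_sheet_points()
  scale <- calibrate(pts_px$P1, pts_px$P2, 50)
  pts <- lapply(pts_px, function(p) p * scale)
  m <- measure_sinus(pts, "right")
  expect_equal(m$sinus_depth, 3, tolerance = 1e-12)
  expect_equal(m$alveolar_height, 7, tolerance = 1e-12)
  expect_equal(m$opening_angle, 100, tolerance = 1e-12)
  ml <- measure_sinus(pts, "left")
  expect_equal(ml$sinus_depth, -2, tolerance = 1e-12)
  # same configuration at doubled scale: identical mm outputs
  pts2 <- lapply(pts_px, function(p) p * 2) # px at half the mm/px scale
  scale2 <- calibrate(pts2$P1, pts2$P2, 50)
  m2 <- measure_sinus(lapply(pts2, function(p) p * scale2), "right")
  expect_equal(m2$sinus_depth, m$sinus_depth)
  expect_equal(m2$alveolar_height, m$alveolar_height)
  expect_equal(m2$opening_angle, m$opening_angle)
  # missing floor point: skipped with a reason
  skipped <- measure_sinus(pts[setdiff(names(pts), "P4")], "right")
  expect_equal(nrow(skipped), 0)
  expect_match(attr(skipped, "skip_reason"), "P4")
})
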