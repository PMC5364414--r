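test_that("one-way ANOVA matches the hand sum-of-squares computation", {
  # groups {1,2,3} and {4,5,6}: SSB = 13.5 (df 1), SSW = 4 (df 4), F = 13.5
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$terms$statistic, 13.5)
  expect_equal(res$terms$df, 1L)
  expect_equal(res$residual$df, 4L)
  expect_equal(res$terms$sum_sq, 13.5)
  expect_equal(res$residual$sum_sq, 4)
  expect_equal(res$terms$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("identical groups give F = 0 and degenerate designs error", {
  res <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$terms$statistic, 0)
  expect_error(one_way_anova(1:4, rep("a", 4)), "two groups")
  expect_error(one_way_anova(1:3, c("a", "b", "b")), "two observations")
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "residual variance")
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(41)
  for (i in 1:10) {
    x <- stats::rnorm(12)
    g <- rep(c("a", "b"), times = c(5, 7))
    f <- one_way_anova(x, g)$terms$statistic
    t2 <- stats::t.test(x ~ g, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2))
  }
})

test_that("between + within sums of squares add to the total", {
  set.seed(42)
  x <- stats::rnorm(60)
  g <- sample(letters[1:4], 60, replace = TRUE)
  res <- one_way_anova(x, g)
  expect_equal(res$terms$sum_sq + res$residual$sum_sq,
               sum((x - mean(x))^2), tolerance = 1e-9)
})

test_that("additive ANOVA uses sequential SS and rejects aliased factors", {
  set.seed(43)
  df <- data.frame(y = stats::rnorm(40),
                   a = sample(c("x", "y"), 40, replace = TRUE),
                   b = "const")
  expect_error(additive_anova(df, "y", c("a", "b")), "constant")
  expect_error(additive_anova(df, "y", c("a", "missing")), "unknown")
  # balanced two-factor design: sequential SS are order-invariant
  bal <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                     rep = 1:4)
  set.seed(44)
  bal$y <- stats::rnorm(nrow(bal)) + as.integer(factor(bal$a)) +
    0.5 * as.integer(factor(bal$b))
  r1 <- additive_anova(bal, "y", c("a", "b"))
  r2 <- additive_anova(bal, "y", c("b", "a"))
  expect_equal(r1$terms$sum_sq[r1$terms$term == "a"],
               r2$terms$sum_sq[r2$terms$term == "a"], tolerance = 1e-9)
  expect_equal(r1$terms$sum_sq[r1$terms$term == "b"],
               r2$terms$sum_sq[r2$terms$term == "b"], tolerance = 1e-9)
})

test_that("additive ANOVA with one factor reduces to one-way and ignores row order", {
  set.seed(45)
  df <- data.frame(y = stats::rnorm(30),
                   g = sample(c("p", "q", "r"), 30, replace = TRUE))
  r1 <- additive_anova(df, "y", "g")
  r2 <- one_way_anova(df$y, df$g)
  expect_equal(r1$terms$statistic, r2$terms$statistic)
  expect_equal(r1$terms$p_value, r2$terms$p_value)
  shuffled <- df[sample(nrow(df)), ]
  r3 <- additive_anova(shuffled, "y", "g")
  expect_equal(r3$terms$statistic, r1$terms$statistic)
  expect_equal(r3$terms$sum_sq, r1$terms$sum_sq)
})

test_that("group summaries report n, mean, sample SD and range per level", {
  df <- tibble::tibble(v = c(1, 2, 3, 10), g = c("a", "a", "a", "b"))
  s <- cohort_summary(df, "v", "g")
  expect_equal(s$n, c(3L, 1L))
  expect_equal(s$mean, c(2, 10))
  expect_equal(s$sd[1], 1)
  expect_true(is.na(s$sd[2])) # zero degrees of freedom
  expect_equal(s$min, c(1, 10))
  expect_equal(s$max, c(3, 10))
  const <- cohort_summary(tibble::tibble(v = c(4, 4), g = "a"), "v", "g")
  expect_equal(const$sd, 0)
  expect_equal(const$min, const$max)
  expect_error(cohort_summary(df, "nope", "g"), "unknown")
})

test_that("deterministic cohort summaries match the generator targets", {
  spec <- cohort_spec(n_patients = c(female_dentate = 99,
                                     female_edentulous = 98),
                      ah_dentition_offset = c(dentate = 0, edentulous = 0),
                      sampling = "deterministic")
  truth <- simulate_truth(spec)
  s_ah <- cohort_summary(truth, "alveolar_height_mm", "sinus_class")
  expect_equal(s_ah$mean[s_ah$level == "I"], 13.0, tolerance = 0.05 / 13)
  expect_equal(s_ah$mean[s_ah$level == "II"], 7.7, tolerance = 0.05 / 7.7)
  expect_equal(s_ah$mean[s_ah$level == "III"], 5.44, tolerance = 0.05 / 5.44)
  s_an <- cohort_summary(truth, "opening_angle_deg", "sinus_class")
  expect_equal(s_an$mean, c(113.87, 101.19, 90.13), tolerance = 0.5 / 90)
})

test_that("standard models recover the built-in effect structure", {
  spec <- cohort_spec(n_patients = 98, seed = 7)
  truth <- simulate_truth(spec)
  cohort <- classify_cohort(truth[setdiff(names(truth), "sinus_class")],
                            mode = "fixed")
  mods <- standard_models(cohort)
  p_ah_class <- mods$p_value[mods$response == "alveolar_height_mm" &
                               mods$model == "sinus_class"]
  p_ah_dent <- mods$p_value[mods$response == "alveolar_height_mm" &
                              mods$model == "dentition"]
  expect_lt(p_ah_class, 1e-6)
  expect_lt(p_ah_dent, 1e-3)
  p_angle_class <- mods$p_value[mods$response == "opening_angle_deg" &
                                  mods$model == "sinus_class"]
  expect_lt(p_angle_class, 1e-6)
})
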