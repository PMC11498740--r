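# Replicate values for one distance (weevil specimen, front-to-back),
# used for the single-cell checks below.
mv_A <- measurement_series("Eupholus", "F-B", "multiview", "A",
                           c(26.68, 26.80, 26.85))
mv_B <- measurement_series("Eupholus", "F-B", "multiview", "B",
                           c(26.71, 26.75, 26.80))
ct_A <- measurement_series("Eupholus", "F-B", "uCT", "A",
                           c(27.34, 27.37, 27.38))

test_that("percent difference to the reference matches hand values", {
  expect_equal(round_half_up(pct_diff_to_reference(mv_A, ct_A)), -2.14)
  expect_equal(pct_diff_to_reference(mv_A, mv_A), 0)
  s1 <- measurement_series("x", "d", "t", "A", rep(101, 3))
  s0 <- measurement_series("x", "d", "r", "A", rep(100, 3))
  expect_equal(pct_diff_to_reference(s1, s0), 1)
  other <- measurement_series("x", "other", "uCT", "A", c(1, 2))
  expect_error(pct_diff_to_reference(s1, other),
               class = "orbimetry_error_mismatched_keys")
})

test_that("pct differences satisfy the exact reciprocity identity", {
  set.seed(81)
  for (i in 1:20) {
    a <- measurement_series("s", "d", "t1", "A", stats::runif(3, 1, 30))
    b <- measurement_series("s", "d", "t2", "A", stats::runif(3, 1, 30))
    dab <- pct_diff_to_reference(a, b)
    dba <- pct_diff_to_reference(b, a)
    expect_equal((1 + dab / 100) * (1 + dba / 100), 1, tolerance = 1e-12)
  }
})

test_that("inter-operator difference matches hand values", {
  expect_equal(round_half_up(interoperator_diff(mv_A, mv_B)), 0.09)
  a <- measurement_series("x", "d", "t", "A", rep(2.02, 3))
  b <- measurement_series("x", "d", "t", "B", rep(2.00, 3))
  expect_equal(interoperator_diff(a, b), 1)
  expect_error(interoperator_diff(mv_A, mv_A),
               class = "orbimetry_error_mismatched_keys")
  expect_error(interoperator_diff(mv_A, ct_A),
               class = "orbimetry_error_mismatched_keys")
})

test_that("dispersion is the pooled relative range", {
  expect_equal(round_half_up(dispersion(c(mv_A$values, mv_B$values))), 0.64)
  expect_equal(dispersion(rep(5, 6)), 0)
  expect_equal(dispersion(c(9, 11)), 20)
  expect_error(dispersion(5), class = "orbimetry_error_too_few_values")
  # invariant under permutation and uniform scaling
  set.seed(82)
  v <- stats::runif(8, 1, 10)
  expect_equal(dispersion(sample(v)), dispersion(v))
  expect_equal(dispersion(3.7 * v), dispersion(v), tolerance = 1e-12)
})

meas <- read_measurements_csv(orbimetry_example("landmark_measurements.csv"))

test_that("per-specimen aggregate differences reproduce the printed tables", {
  eu <- aggregate_differences(meas, "Eupholus", "multiview")
  expect_equal(unname(round_half_up(eu)), c(-2.29, -2.43, -2.36))
  ly <- aggregate_differences(meas, "Lycus", "multiview")
  expect_equal(unname(round_half_up(ly[["avg_AB"]])), -0.83)
  ph <- aggregate_differences(meas, "Philodicus", "multiview")
  expect_equal(unname(round_half_up(ph)), c(0.62, 0.44, 0.53))
  ov <- aggregate_differences(meas, "Ovalisia", "multiview")
  expect_equal(unname(round_half_up(ov)), c(0.73, 0.33, 0.53))
  expect_equal(unname(round_half_up(
    aggregate_differences(meas, "Eupholus", "SfM"))), c(-2.02, -2.35, -2.19))
  zero <- aggregate_differences(meas, "Eupholus", "uCT")
  expect_equal(unname(zero), c(0, 0, 0))
  expect_error(aggregate_differences(meas, "Eupholus", "laser"),
               class = "orbimetry_error_empty_input")
})

test_that("global absolute summary reproduces the per-technique totals", {
  mv <- global_absolute_summary(meas, "multiview")
  expect_equal(mv$n, 36)  # 18 distances x 2 operators
  expect_equal(round_half_up(mv$absolute_average), 0.99)
  expect_equal(round_half_up(mv$cumulated), 35.57)
  sfm <- global_absolute_summary(meas, "SfM")
  expect_equal(round_half_up(sfm$absolute_average), 1.22)
  expect_equal(round_half_up(sfm$cumulated), 43.95)
  sl <- global_absolute_summary(meas, "SL")
  expect_equal(round_half_up(sl$absolute_average), 1.74)
  expect_equal(round_half_up(sl$cumulated), 62.49)
  # cumulated = n x absolute_average, exactly
  expect_equal(mv$cumulated, mv$n * mv$absolute_average)
  expect_error(global_absolute_summary(meas, "laser"),
               class = "orbimetry_error_empty_input")
})

test_that("global summary basics hold on tiny inputs", {
  tiny <- data.frame(
    specimen = "s", distance_label = "d",
    technique = rep(c("uCT", "t"), each = 2),
    operator = c("A", "B", "A", "B"), replicate = 1,
    value_mm = c(100, 100, 98, 101))
  g <- global_absolute_summary(tiny, "t")
  expect_equal(g$absolute_average, 1.5)  # |-2| and |+1| averaged
  expect_equal(g$cumulated, 3)
})

test_that("repeatability summary reproduces the 20-replicate run", {
  rep20 <- read_measurements_csv(orbimetry_example("repeatability_lr.csv"))
  vals <- function(tech) rep20$value_mm[rep20$technique == tech]
  ct <- vals("uCT")

  mv <- repeatability_summary(vals("multiview"), ct)
  expect_equal(round_half_up(mv$mean), 5.51)
  expect_equal(round_half_up(mv$stdev), 0.02)
  expect_equal(round_half_up(mv$diff_to_reference_pct), 0.33)
  expect_equal(mv$ci95, c(5.48, 5.55), tolerance = 0.01)

  sl <- repeatability_summary(vals("SL"), ct)
  expect_equal(round_half_up(sl$mean), 5.59)
  expect_equal(round_half_up(sl$diff_to_reference_pct), 1.77)
  expect_equal(sl$ci95, c(5.56, 5.62), tolerance = 0.01)

  ct_self <- repeatability_summary(ct, ct)
  expect_equal(round_half_up(ct_self$mean), 5.50)
  expect_equal(round_half_up(ct_self$stdev), 0.01)
  expect_equal(ct_self$diff_to_reference_pct, 0)
  expect_equal(ct_self$ci95, c(5.47, 5.52), tolerance = 0.01)
  # the interval brackets the mean
  expect_lte(ct_self$ci95[1], ct_self$mean)
  expect_gte(ct_self$ci95[2], ct_self$mean)

  same <- repeatability_summary(rep(4.2, 20), ct)
  expect_equal(same$stdev, 0)
  expect_equal(same$dispersion_pct, 0)
  expect_equal(same$ci95, c(4.2, 4.2))
  expect_error(repeatability_summary(5, ct),
               class = "orbimetry_error_too_few_values")
})
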