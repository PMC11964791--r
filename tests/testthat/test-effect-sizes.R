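test_that("standard errors from confidence intervals follow the normal width", {
  expect_equal(se_from_interval(-0.5, 0.1), 0.6 / (2 * qnorm(0.975)),
               tolerance = 1e-10)
  expect_equal(se_from_interval(-qnorm(0.975), qnorm(0.975)), 1,
               tolerance = 1e-12)
  # doubling the width doubles the SE
  expect_equal(se_from_interval(-1, 1), 2 * se_from_interval(-0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(se_from_interval(-1, 1, level = 0.9),
               2 / (2 * qnorm(0.95)), tolerance = 1e-12)
  expect_error(se_from_interval(0.3, 0.3), "high > low")
  expect_error(se_from_interval(-1, 1, level = 1), "level")
})

test_that("standard errors from p-values invert the Wald test", {
  expect_equal(se_from_p(-0.2, 0.05), 0.2 / qnorm(0.975),
               tolerance = 1e-6)
  # t mode converges to the normal answer for large n
  expect_equal(se_from_p(-0.2, 0.05, n = 500, mode = "t"),
               se_from_p(-0.2, 0.05), tolerance = 0.005)
  # smaller p -> smaller SE at fixed beta
  ps <- c(0.5, 0.1, 0.01, 1e-5, 1e-30)
  ses <- vapply(ps, function(p) se_from_p(0.3, p), numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_true(all(ses > 0))  # tiny p must not underflow to SE = 0
  expect_error(se_from_p(-0.2, 1), "strictly in")
  expect_error(se_from_p(0, 0.05), "inconsistent")
  expect_error(se_from_p(-0.2, 0.05, n = 4, mode = "t"), "sample size")
})

test_that("linear-scale effect curves equal beta1 times the coordinate change", {
  rec <- make_record(beta1 = -0.5, se = 0.1, behavior = "mvpa")
  curve <- study_effect_curve(rec, grid = c(0, 10, 30, 60))
  expect_equal(curve$estimate[1], 0)
  expect_equal(curve$variance[1], 0)
  comp <- close_composition(c(600, 480, 300, 60))
  # oracle: reallocate, recompute both z1 values, difference
  for (i in 2:4) {
    d <- curve$delta_min[i]
    moved <- reallocate_all_for_one(comp, "mvpa", d)
    dz <- pivot_coordinates(moved, "mvpa")[["z1"]] -
      pivot_coordinates(comp, "mvpa")[["z1"]]
    expect_equal(curve$estimate[i], -0.5 * dz, tolerance = 1e-12)
    expect_equal(curve$variance[i], dz^2 * 0.1^2, tolerance = 1e-12)
  }
  # variance / dz^2 constant across the grid
  dzs <- vapply(curve$delta_min[-1], function(d)
    delta_first_coordinate(comp, "mvpa", d), numeric(1))
  ratio <- curve$variance[-1] / dzs^2
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("effect curves preserve sign and monotonicity on the linear scale", {
  for (b1 in c(-0.5, 0.4)) {
    rec <- make_record(beta1 = b1, behavior = "sedentary")
    curve <- study_effect_curve(rec, grid = default_grid())
    pos <- curve$delta_min > 0
    expect_true(all(sign(curve$estimate[pos]) == sign(b1)))
    expect_true(all(sign(curve$estimate[!pos]) == -sign(b1)))
    expect_true(all(diff(sign(b1) * curve$estimate) > 0))
  }
})

test_that("log-scale outcomes are back-transformed by the delta method", {
  rec <- make_record(beta1 = 0.002, se = 0.001, behavior = "sleep",
                     outcome_name = "waist_cm", outcome_scale = "log",
                     mean_outcome = 65)
  curve <- study_effect_curve(rec, grid = c(10, 30))
  comp <- close_composition(c(600, 480, 300, 60))
  for (i in 1:2) {
    dz <- delta_first_coordinate(comp, "sleep", curve$delta_min[i])
    expect_lt(abs(0.002 * dz), 0.01)
    # first-order expansion: within 1% of ybar * beta1 * dz
    expect_equal(curve$estimate[i], 65 * 0.002 * dz, tolerance = 0.01)
    expect_equal(curve$estimate[i], 65 * (exp(0.002 * dz) - 1),
                 tolerance = 1e-12)
    expect_equal(curve$variance[i],
                 (65 * exp(0.002 * dz) * dz * 0.001)^2, tolerance = 1e-12)
    # round trip: absolute change inverts back to the log-scale effect
    expect_equal(log(curve$estimate[i] / 65 + 1) / dz, 0.002,
                 tolerance = 1e-10)
  }
  rec$mean_outcome <- NA_real_
  expect_error(study_effect_curve(rec, grid = c(10)), "mean_outcome")
})

test_that("uncertainty representations are mutually exclusive", {
  rec <- make_record()
  rec$ci_low <- -0.5; rec$ci_high <- -0.1     # se already present
  expect_error(study_effect_curve(rec, grid = c(30)), "exactly one")
  rec2 <- make_record(); rec2$se <- NA_real_  # none present
  expect_error(study_effect_curve(rec2, grid = c(30)), "exactly one")
  rec3 <- make_record()
  expect_error(study_effect_curve(rec3, grid = c(-100)), "infeasible")
})
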