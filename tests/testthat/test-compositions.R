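test_that("closure rescales parts to the day total without changing ratios", {
  expect_equal(unname(close_composition(c(600, 480, 300, 60))),
               c(600, 480, 300, 60))
  # printed geometric means summing to 1441 are scaled by 1440/1441
  got <- close_composition(c(539, 525, 320, 57))
  expect_equal(unname(got), c(539, 525, 320, 57) * 1440 / 1441)
  expect_equal(sum(got), 1440)
  expect_equal(unname(close_composition(c(1, 1, 1, 1))), rep(360, 4))
  # idempotence
  p <- c(123.4, 456.7, 321.9, 87.2)
  expect_equal(close_composition(close_composition(p)),
               close_composition(p), tolerance = 1e-12)
})

test_that("closure rejects invalid parts", {
  expect_error(close_composition(c(600, 0, 300, 60)), "strictly positive")
  expect_error(close_composition(c(600, -5, 300, 60)), "strictly positive")
  expect_error(close_composition(c(600, 300, 60)), "4 parts")
  expect_error(close_composition(c(600, 480, 300, 60), total = 0),
               "positive")
})

test_that("pivot coordinates match the defining log-ratio formula", {
  expect_equal(as.numeric(pivot_coordinates(rep(360, 4), "sleep")),
               c(0, 0, 0))
  comp <- close_composition(c(600, 480, 300, 60))
  for (b in behaviors()) {
    z <- pivot_coordinates(comp, b)
    expect_equal(z[["z1"]], brute_z1(comp, b), tolerance = 1e-12)
  }
  expect_error(pivot_coordinates(comp, "napping"), "unknown behavior")
})

test_that("pivot coordinates are closure-invariant and invertible", {
  set.seed(11)
  comps <- random_compositions(50)
  for (i in 1:10) {
    comp <- comps[i, ]
    k <- stats::runif(1, 0.1, 10)
    expect_equal(as.numeric(pivot_coordinates(comp * k, "lpa")),
                 as.numeric(pivot_coordinates(comp, "lpa")),
                 tolerance = 1e-12)
    # algebraic inversion: exp(z1 sqrt(4/3)) * gmean(others) recovers x_b
    for (b in behaviors()) {
      z1 <- pivot_coordinates(comp, b)[["z1"]]
      others <- comp[setdiff(behaviors(), b)]
      expect_equal(exp(z1 * sqrt(4 / 3)) * prod(others)^(1 / 3),
                   comp[[b]], tolerance = 1e-10)
    }
    # bijectivity onto real 3-space: inverse map round-trips
    z <- pivot_coordinates(comp, "mvpa")
    expect_equal(codameta:::pivot_inverse(z, "mvpa"), comp,
                 tolerance = 1e-10)
  }
})

test_that("all-for-one reallocation shifts minutes as specified", {
  comp <- close_composition(c(600, 480, 300, 60))
  expect_equal(reallocate_all_for_one(comp, "sleep", 0), comp)
  # direct arithmetic: target +60, others scaled by 1320/1380
  got <- reallocate_all_for_one(comp, "mvpa", 60)
  expect_equal(unname(got),
               c(600 * 1320 / 1380, 480 * 1320 / 1380, 300 * 1320 / 1380,
                 120), tolerance = 1e-12)
  expect_error(reallocate_all_for_one(comp, "mvpa", -60), "lower bound")
  expect_error(reallocate_all_for_one(comp, "mvpa", 1380), "upper bound")
})

test_that("reallocation conserves the day and the non-target subcomposition", {
  set.seed(21)
  comps <- random_compositions(1000)
  targets <- sample(behaviors(), 1000, replace = TRUE)
  for (i in 1:1000) {
    comp <- comps[i, ]
    tg <- targets[i]
    d <- stats::runif(1, -0.9 * comp[[tg]], 120)
    out <- reallocate_all_for_one(comp, tg, d)
    expect_equal(sum(out), 1440, tolerance = 1e-10)
    others <- setdiff(behaviors(), tg)
    expect_equal(out[others[1]] / out[others[2]],
                 comp[others[1]] / comp[others[2]], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(out[others[2]] / out[others[3]],
                 comp[others[2]] / comp[others[3]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("first-coordinate change is zero at 0, increasing and concave", {
  comp <- close_composition(c(539, 525, 320, 57))
  expect_identical(delta_first_coordinate(comp, "sleep", 0), 0)
  set.seed(31)
  comps <- random_compositions(30)
  for (i in 1:30) {
    comp <- comps[i, ]
    tg <- sample(behaviors(), 1)
    # concavity holds while the target part stays below half the day
    # (the curvature -1/(x+d)^2 + 1/(T-x-d)^2 changes sign at T/2);
    # every realistic reallocation grid lives in that region
    hi <- min(120, 0.5 * day_minutes() - comp[[tg]] - 1)
    grid <- seq(-0.5 * comp[[tg]], hi, length.out = 25)
    dz <- vapply(grid, function(d) delta_first_coordinate(comp, tg, d),
                 numeric(1))
    expect_true(all(diff(dz) > 0))            # strictly increasing
    expect_true(all(diff(diff(dz)) <= 1e-10)) # concave
  }
})
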