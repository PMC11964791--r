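test_that("fixed-effect pooling matches hand arithmetic", {
  got <- pool_fixed(c(0, 1, 2), c(1, 1, 1))
  expect_equal(got$pooled_estimate, 1)
  expect_equal(got$pooled_se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(got$q_stat, 2)
  expect_equal(got$q_df, 2L)
  # single effect returned unchanged
  one <- pool_fixed(0.7, 0.04)
  expect_equal(one$pooled_estimate, 0.7)
  expect_equal(one$pooled_se, 0.2)
  # rescaling all variances by c rescales SE by sqrt(c), estimate fixed
  a <- pool_fixed(c(0.1, 0.4, -0.2), c(0.02, 0.05, 0.01))
  b <- pool_fixed(c(0.1, 0.4, -0.2), 4 * c(0.02, 0.05, 0.01))
  expect_equal(b$pooled_estimate, a$pooled_estimate, tolerance = 1e-12)
  expect_equal(b$pooled_se, 2 * a$pooled_se, tolerance = 1e-12)
  expect_error(pool_fixed(numeric(0), numeric(0)), "no effects")
})

test_that("REML tau2 matches an independent grid search and metafor", {
  expect_identical(reml_tau2(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1)), 0)
  expect_lt(abs(reml_tau2(c(0, 2), c(0.1, 0.1)) -
                  grid_reml(c(0, 2), c(0.1, 0.1))), 1e-6)
  skip_if_not_installed("metafor")
  set.seed(42)
  for (r in 1:20) {
    k <- sample(3:10, 1)
    yi <- stats::rnorm(k, 0, 0.4)
    vi <- stats::runif(k, 0.01, 0.1)
    t2 <- reml_tau2(yi, vi)
    mf <- metafor::rma(yi = yi, vi = vi, method = "REML",
                       control = list(tau2.max = 100))
    expect_lt(abs(t2 - mf$tau2), 1e-5)  # metafor's own convergence limit
  }
})

test_that("REML tau2 is consistent at large k", {
  set.seed(7)
  k <- 200
  vi <- stats::runif(k, 0.005, 0.02)
  yi <- stats::rnorm(k, 0.3, sqrt(vi + 0.04))
  expect_lt(abs(reml_tau2(yi, vi) - 0.04), 0.2 * 0.04)
})

test_that("random-effects pooling degenerates and symmetrizes correctly", {
  # identical effects: tau2 = 0, identical to fixed-effect result
  re <- pool_random(rep(0.5, 4), rep(0.02, 4))
  fe <- pool_fixed(rep(0.5, 4), rep(0.02, 4))
  expect_equal(re$tau2, 0)
  expect_equal(re$i2, 0)
  expect_equal(re$pooled_estimate, fe$pooled_estimate)
  expect_equal(re$pooled_se, fe$pooled_se)
  # equal variances: pooled = arithmetic mean even with tau2 > 0
  y <- c(-0.3, 0.1, 0.5, 0.9)
  re2 <- pool_random(y, rep(0.01, 4))
  expect_gt(re2$tau2, 0)
  expect_equal(re2$pooled_estimate, mean(y), tolerance = 1e-8)
  # a study with near-infinite variance has no influence
  base <- pool_random(y, rep(0.01, 4))
  with_inf <- pool_random(c(y, 50), c(rep(0.01, 4), 1e12))
  expect_equal(with_inf$pooled_estimate, base$pooled_estimate,
               tolerance = 1e-6)
})

test_that("random-effects SE dominates fixed-effect SE; order is irrelevant", {
  set.seed(13)
  for (r in 1:200) {
    k <- sample(2:12, 1)
    yi <- stats::rnorm(k, 0, 0.5)
    vi <- stats::runif(k, 0.005, 0.1)
    expect_gte(pool_random(yi, vi)$pooled_se,
               pool_fixed(yi, vi)$pooled_se - 1e-12)
  }
  yi <- c(0.2, -0.1, 0.6, 0.05, -0.4); vi <- c(1:5) / 50
  p <- sample(5)
  a <- pool_random(yi, vi); b <- pool_random(yi[p], vi[p])
  for (v in names(a)) expect_equal(a[[v]], b[[v]], tolerance = 1e-12)
})

test_that("pooled results agree with metafor's REML fit", {
  skip_if_not_installed("metafor")
  set.seed(99)
  yi <- stats::rnorm(8, -0.2, 0.3)
  vi <- stats::runif(8, 0.01, 0.08)
  got <- pool_random(yi, vi)
  mf <- metafor::rma(yi = yi, vi = vi, method = "REML", test = "z")
  expect_equal(got$pooled_estimate, unname(mf$beta[1]), tolerance = 1e-6)
  expect_equal(got$pooled_se, mf$se, tolerance = 1e-6)
  expect_lt(abs(got$tau2 - mf$tau2), 1e-6)
  expect_equal(got$i2, mf$I2, tolerance = 1e-3)
  expect_equal(got$q_stat, mf$QE, tolerance = 1e-8)
  expect_equal(got$p_value, mf$pval, tolerance = 1e-6)
})

test_that("dose-response pooling honors the study-count rule and truth signs", {
  recs <- rbind(make_record("s1", beta1 = -0.4, se = 0.1),
                make_record("s2", beta1 = -0.4, se = 0.1))
  dr <- dose_response(recs, "mvpa", "zbmi", grid = c(-30, 10, 30))
  # identical studies: pooled curve equals either study's curve, I2 = 0
  s1 <- study_effect_curve(recs[1, ], grid = c(-30, 10, 30))
  expect_equal(dr$pooled_estimate, s1$estimate, tolerance = 1e-10)
  expect_equal(dr$i2, rep(0, 3))
  expect_equal(dr$tau2, rep(0, 3))
  # negative coefficient: negative pooled effects at all delta > 0,
  # positive (and larger in magnitude, by concavity of dz1) at -delta
  pos <- dr[dr$delta_min == 30, ]; neg <- dr[dr$delta_min == -30, ]
  expect_lt(pos$pooled_estimate, 0)
  expect_gt(neg$pooled_estimate, 0)
  expect_gt(abs(neg$pooled_estimate), abs(pos$pooled_estimate))
  expect_error(dose_response(recs[1, ], "mvpa", "zbmi", grid = c(30)),
               "at-least-2-studies")
})

test_that("infeasible reallocations drop studies, not the analysis", {
  # one study's MVPA geometric mean is below 20 min: -30 infeasible there
  recs <- rbind(make_record("s1", comp = c(610, 500, 315, 15)),
                make_record("s2"), make_record("s3"))
  dr <- dose_response(recs, "mvpa", "zbmi", grid = c(-30, 30))
  expect_equal(dr$k[dr$delta_min == -30], 2L)
  expect_equal(dr$k[dr$delta_min == 30], 3L)
})
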