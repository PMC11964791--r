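# Independent oracles and small fixture generators used across tests.

# Random strictly positive compositions closed to 1440 min.
random_compositions <- function(n) {
  t(sapply(seq_len(n), function(i)
    close_composition(exp(stats::rnorm(4, log(c(540, 500, 280, 60)),
                                       0.4)))))
}

# Brute-force pivot z1: direct evaluation of the defining formula.
brute_z1 <- function(comp, pivot) {
  others <- setdiff(behaviors(), pivot)
  x <- unname(comp[behaviors() == pivot])
  g <- prod(comp[match(others, behaviors())])^(1 / 3)
  sqrt(3 / 4) * log(x / g)
}

# Independent grid search of the restricted likelihood for tau^2 on
# [0, 10]: coarse pass at 1e-3, refined pass at 1e-6 around the best
# coarse point. Own likelihood code, no calls into the package optimizer.
grid_reml <- function(yi, vi, upper = 10) {
  rll_vec <- function(t2) {
    vapply(t2, function(t) {
      w <- 1 / (vi + t)
      mu <- sum(w * yi) / sum(w)
      -0.5 * (sum(log(vi + t)) + log(sum(w)) + sum(w * (yi - mu)^2))
    }, numeric(1))
  }
  coarse <- seq(0, upper, by = 1e-3)
  i <- which.max(rll_vec(coarse))
  lo <- max(0, coarse[i] - 2e-3)
  fine <- seq(lo, coarse[i] + 2e-3, by = 1e-6)
  fine[which.max(rll_vec(fine))]
}

# One-row study record builder with SE uncertainty.
make_record <- function(study_id = "s1", beta1 = -0.3, se = 0.1,
                        comp = c(600, 480, 300, 60), behavior = "mvpa",
                        outcome_name = "zbmi", outcome_scale = "linear",
                        mean_outcome = 0.45, n = 500, mean_age = 10,
                        quality_pct = 80) {
  data.frame(study_id = study_id, n = n, mean_age = mean_age,
             sleep_min = comp[1], sed_min = comp[2], lpa_min = comp[3],
             mvpa_min = comp[4], outcome_name = outcome_name,
             outcome_scale = outcome_scale, mean_outcome = mean_outcome,
             behavior = behavior, beta1 = beta1, se = se,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
             quality_pct = quality_pct, stringsAsFactors = FALSE)
}
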