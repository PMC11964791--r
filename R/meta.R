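#' Fixed-effect inverse-variance pooling
#'
#' Weights each effect by the inverse of its sampling variance:
#' pooled = sum(w y) / sum(w), SE = 1/sqrt(sum(w)), with Cochran's
#' Q = sum(w (y - pooled)^2) on k - 1 degrees of freedom. Serves as the
#' degenerate (tau^2 = 0) case of the random-effects model and as its
#' internal oracle.
#'
#' @param yi Effect estimates.
#' @param vi Sampling variances (strictly positive, same length).
#' @param level Confidence level (default 0.95).
#' @return One-row data frame: `k`, `pooled_estimate`, `pooled_se`,
#'   `ci_low`, `ci_high`, `z_value`, `p_value`, `q_stat`, `q_df`.
#' @export
#' @examples
#' pool_fixed(c(0, 1, 2), c(1, 1, 1))
pool_fixed <- function(yi, vi, level = 0.95) {
  check_effects(yi, vi, k_min = 1L)
  w <- 1 / vi
  est <- sum(w * yi) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (yi - est)^2)
  zq <- stats::qnorm((1 + level) / 2)
  z <- est / se
  data.frame(k = length(yi), pooled_estimate = est, pooled_se = se,
             ci_low = est - zq * se, ci_high = est + zq * se,
             z_value = z, p_value = 2 * stats::pnorm(-abs(z)),
             q_stat = q, q_df = length(yi) - 1L)
}

check_effects <- function(yi, vi, k_min) {
  if (length(yi) == 0L) stop("no effects to pool", call. = FALSE)
  if (length(yi) != length(vi))
    stop("yi and vi must have the same length", call. = FALSE)
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi <= 0))
    stop("all effects must be finite with strictly positive variances",
         call. = FALSE)
  if (length(yi) < k_min)
    stop("need at least ", k_min, " effects, got ", length(yi),
         if (k_min == 2L) "; use pool_fixed() for a single effect" else "",
         call. = FALSE)
  invisible(TRUE)
}

# Restricted log-likelihood of the intercept-only random-effects model,
# profiled over the pooled mean (constants dropped).
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

#' REML estimate of between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model
#' y_i ~ N(mu, v_i + tau^2), profiled over mu, by bounded scalar
#' optimization on tau^2 in [0, 10 * var(y)] (ties at the lower boundary
#' return 0). Converged to absolute tolerance ~1e-10 on tau^2.
#'
#' @inheritParams pool_fixed
#' @return Non-negative scalar tau^2 estimate.
#' @export
#' @examples
#' reml_tau2(c(0, 2), c(0.1, 0.1))
reml_tau2 <- function(yi, vi) {
  check_effects(yi, vi, k_min = 2L)
  upper <- 10 * stats::var(yi)
  if (!is.finite(upper) || upper <= 0) return(0)
  opt <- stats::optimize(reml_loglik, c(0, upper), yi = yi, vi = vi,
                         maximum = TRUE, tol = 1e-10)
  # optimize never evaluates the endpoints; check the tau2 = 0 boundary
  if (reml_loglik(0, yi, vi) >= opt$objective) return(0)
  max(0, opt$maximum)
}

#' Random-effects inverse-variance pooling with REML heterogeneity
#'
#' Pools effects with weights 1 / (v_i + tau^2), tau^2 estimated by
#' [reml_tau2()]. Inference is Wald-type (normal): z = pooled / SE with a
#' two-sided p-value. I^2 is reported as
#' 100 * tau^2 / (tau^2 + v_typ), where v_typ is Higgins' typical
#' within-study variance (k-1) * sum(w) / (sum(w)^2 - sum(w^2)) computed
#' from the fixed-effect weights w = 1/v; the Q-based
#' I^2 = max(0, 100 (Q - df) / Q) is carried as a secondary field.
#'
#' @inheritParams pool_fixed
#' @return One-row data frame: `k`, `pooled_estimate`, `pooled_se`,
#'   `ci_low`, `ci_high`, `z_value`, `p_value`, `tau2`, `i2`, `i2_q`,
#'   `q_stat`, `q_df`.
#' @export
#' @examples
#' pool_random(c(-0.1, -0.3, -0.2, 0.05), c(0.01, 0.02, 0.015, 0.01))
pool_random <- function(yi, vi, level = 0.95) {
  check_effects(yi, vi, k_min = 2L)
  tau2 <- reml_tau2(yi, vi)
  w <- 1 / (vi + tau2)
  est <- sum(w * yi) / sum(w)
  se <- 1 / sqrt(sum(w))
  zq <- stats::qnorm((1 + level) / 2)
  z <- est / se
  fx <- pool_fixed(yi, vi, level)
  wf <- 1 / vi
  v_typ <- (length(yi) - 1L) * sum(wf) / (sum(wf)^2 - sum(wf^2))
  i2 <- 100 * tau2 / (tau2 + v_typ)
  i2_q <- max(0, 100 * (fx$q_stat - fx$q_df) / fx$q_stat)
  data.frame(k = length(yi), pooled_estimate = est, pooled_se = se,
             ci_low = est - zq * se, ci_high = est + zq * se,
             z_value = z, p_value = 2 * stats::pnorm(-abs(z)),
             tau2 = tau2, i2 = i2, i2_q = i2_q,
             q_stat = fx$q_stat, q_df = fx$q_df)
}

#' Pooled dose-response curve across studies
#'
#' Computes each eligible study's effect-size curve for one behavior and
#' outcome, then pools the studies at every grid point with the
#' random-effects model. A grid point is pooled only where at least
#' `min_studies` studies contribute (the "at least two studies" inclusion
#' rule); reallocations infeasible for a study's mean composition (e.g.,
#' removing more MVPA minutes than the study's geometric mean) drop that
#' study from the affected grid points only.
#'
#' @param records Study-record data frame (one row per study x behavior;
#'   see [read_study_records()] for the schema).
#' @param behavior Behavior label.
#' @param outcome Outcome name to pool (matched against `outcome_name`).
#' @param grid Minute reallocations (default +-10..60 by 10).
#' @param min_studies Minimum number of contributing effects per grid
#'   point (default 2).
#' @param se_p_mode Quantile family for p-value inversion.
#' @return Data frame with one row per pooled grid point: `outcome_name`,
#'   `behavior`, `delta_min`, then the [pool_random()] columns.
#' @export
dose_response <- function(records, behavior, outcome,
                          grid = default_grid(), min_studies = 2L,
                          se_p_mode = "normal") {
  check_behavior(behavior)
  rows <- records[records$behavior == behavior &
                    records$outcome_name == outcome, , drop = FALSE]
  if (nrow(rows) < min_studies)
    stop("the '", outcome, "' x '", behavior, "' analysis violates the ",
         "at-least-", min_studies, "-studies rule (", nrow(rows),
         " eligible)", call. = FALSE)
  grid <- grid[grid != 0]
  curves <- lapply(seq_len(nrow(rows)), function(i) {
    rec <- as.list(rows[i, ])
    comp <- close_composition(unlist(rec[unname(comp_columns())]))
    feasible <- grid[grid > -comp[[behavior]] &
                       grid < day_minutes() - comp[[behavior]]]
    study_effect_curve(rec, behavior, feasible, se_p_mode)
  })
  eff <- do.call(rbind, curves)
  out <- lapply(sort(unique(eff$delta_min)), function(d) {
    sub <- eff[eff$delta_min == d, , drop = FALSE]
    if (nrow(sub) < min_studies) return(NULL)
    cbind(data.frame(outcome_name = outcome, behavior = behavior,
                     delta_min = d, stringsAsFactors = FALSE),
          pool_random(sub$estimate, sub$variance))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    stop("no grid point had at least ", min_studies,
         " feasible study effects", call. = FALSE)
  rownames(out) <- NULL
  out
}
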