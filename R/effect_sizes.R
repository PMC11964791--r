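#' Standard error from a reported confidence interval
#'
#' Assuming normal sampling, SE = (high - low) / (2 * z_{(1+level)/2}).
#'
#' @param low,high Interval bounds (`high > low`).
#' @param level Coverage of the interval, in (0, 1); default 0.95.
#' @return Positive standard error.
#' @export
#' @examples
#' se_from_interval(-0.5, 0.1)          # 0.6 / (2 * 1.959964)
se_from_interval <- function(low, high, level = 0.95) {
  if (!is.finite(low) || !is.finite(high) || high <= low)
    stop("invalid interval: need high > low", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  (high - low) / (2 * stats::qnorm((1 + level) / 2))
}

#' Standard error from a two-sided p-value
#'
#' Inverts the Wald test: SE = |beta| / q, where q is the two-sided
#' normal quantile at p (default) or the t quantile with n - df_params
#' degrees of freedom. Only exact numeric p-values are accepted;
#' inequality-censored reports ("< 0.001") carry no invertible
#' information and must be rejected upstream.
#'
#' @param beta Reported coefficient (non-zero).
#' @param p Two-sided p-value, strictly inside (0, 1).
#' @param n Sample size; required for `mode = "t"`.
#' @param mode `"normal"` (default) or `"t"`.
#' @param df_params Parameters charged against the residual df in t mode
#'   (default 5: intercept plus four composition-model terms).
#' @return Positive standard error.
#' @export
#' @examples
#' se_from_p(-0.2, 0.05)                # 0.2 / 1.959964
se_from_p <- function(beta, p, n = NULL, mode = c("normal", "t"),
                      df_params = 5L) {
  mode <- match.arg(mode)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p-value must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(beta) || beta == 0)
    stop("inconsistent inputs: beta = 0 cannot yield p < 1", call. = FALSE)
  # lower.tail = FALSE keeps the inversion accurate for very small p,
  # where 1 - p/2 would round to 1 in double precision
  q <- if (mode == "normal") {
    stats::qnorm(p / 2, lower.tail = FALSE)
  } else {
    if (is.null(n) || !is.finite(n) || n <= df_params)
      stop("t mode needs a sample size larger than the parameter count",
           call. = FALSE)
    stats::qt(p / 2, df = n - df_params, lower.tail = FALSE)
  }
  abs(beta) / q
}

# Resolve the single uncertainty representation of one study-record row
# into a standard error. Exactly one of {se}, {ci_low, ci_high},
# {p_value} must be non-missing.
resolve_se <- function(record, se_p_mode = "normal") {
  has_se <- is.finite(record$se %||% NA_real_)
  has_ci <- is.finite(record$ci_low %||% NA_real_) &&
    is.finite(record$ci_high %||% NA_real_)
  has_p <- is.finite(record$p_value %||% NA_real_)
  if (has_se + has_ci + has_p != 1L)
    stop("study '", record$study_id, "', behavior '", record$behavior,
         "': exactly one of se, (ci_low, ci_high), p_value must be given",
         call. = FALSE)
  if (has_se) {
    if (record$se <= 0) stop("se must be positive", call. = FALSE)
    record$se
  } else if (has_ci) {
    se_from_interval(record$ci_low, record$ci_high)
  } else {
    se_from_p(record$beta1, record$p_value, n = record$n, mode = se_p_mode)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effect-size curve for one study and behavior
#'
#' Converts an extracted first-coordinate coefficient into the predicted
#' absolute outcome change, with variance, for each minute reallocation
#' on a grid. For linear-scale outcomes the change is beta1 * dz1 with
#' variance dz1^2 * SE^2. For log-scale outcomes the change is
#' back-transformed through the study mean outcome,
#' ybar * (exp(beta1 * dz1) - 1), with delta-method variance
#' (ybar * exp(beta1 * dz1) * dz1 * SE)^2.
#'
#' @param record One study-record row (list or 1-row data frame) with
#'   fields `study_id`, `n`, composition columns `sleep_min`, `sed_min`,
#'   `lpa_min`, `mvpa_min`, `outcome_name`, `outcome_scale`
#'   (`"linear"`/`"log"`), `mean_outcome` (required for log scale),
#'   `behavior`, `beta1` and exactly one of `se`, `ci_low`+`ci_high`,
#'   `p_value`.
#' @param behavior Behavior label; defaults to `record$behavior`.
#' @param grid Minute reallocations (default +-10..60 by 10); 0 is
#'   allowed and yields a zero effect with zero variance.
#' @param se_p_mode Quantile family for p-value inversion.
#' @return Data frame: `study_id`, `behavior`, `outcome_name`,
#'   `delta_min`, `estimate`, `variance`.
#' @export
study_effect_curve <- function(record, behavior = NULL,
                               grid = default_grid(),
                               se_p_mode = "normal") {
  record <- as.list(record)
  behavior <- check_behavior(behavior %||% record$behavior)
  comp <- close_composition(unlist(record[unname(comp_columns())]))
  scale <- record$outcome_scale %||% "linear"
  if (!scale %in% c("linear", "log"))
    stop("outcome_scale must be 'linear' or 'log'", call. = FALSE)
  beta1 <- record$beta1
  if (!is.finite(beta1)) stop("beta1 is missing", call. = FALSE)
  se <- resolve_se(record, se_p_mode)
  if (scale == "log" && !is.finite(record$mean_outcome %||% NA_real_))
    stop("log-scale outcome requires mean_outcome for back-transformation",
         call. = FALSE)

  dz <- vapply(grid, function(d) {
    if (d == 0) 0 else delta_first_coordinate(comp, behavior, d)
  }, numeric(1))
  if (scale == "linear") {
    est <- beta1 * dz
    v <- dz^2 * se^2
  } else {
    ybar <- record$mean_outcome
    est <- ybar * (exp(beta1 * dz) - 1)
    v <- (ybar * exp(beta1 * dz) * dz * se)^2
  }
  data.frame(study_id = record$study_id %||% NA_character_,
             behavior = behavior,
             outcome_name = record$outcome_name %||% NA_character_,
             delta_min = as.numeric(grid), estimate = est, variance = v,
             stringsAsFactors = FALSE)
}

#' Default reallocation grid
#'
#' Symmetric grid of +-10 to +-60 minutes in 10-minute steps (12 points).
#' @param sign `"symmetric"` (default) or `"positive"` for increases only.
#' @return Numeric vector of minute reallocations.
#' @export
default_grid <- function(sign = c("symmetric", "positive")) {
  sign <- match.arg(sign)
  g <- seq(10, 60, by = 10)
  if (sign == "symmetric") sort(c(-g, g)) else g
}
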