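#' Restricted cubic spline basis with three knots
#'
#' Harrell's restricted truncated-power parameterization: the spline is
#' cubic between the outer knots and constrained to be linear beyond
#' them, so 3 knots contribute exactly 2 regression columns. The
#' nonlinear column is scaled by (k3 - k1)^2 for numerical stability:
#' n(x) = ( (x-k1)+^3 - (x-k2)+^3 (k3-k1)/(k3-k2)
#'          + (x-k3)+^3 (k2-k1)/(k3-k2) ) / (k3-k1)^2.
#'
#' @param x Numeric vector (e.g., study mean ages in years).
#' @param knots Three strictly increasing knot locations (default ages
#'   5, 10 and 15 years).
#' @return Matrix with columns `linear` (= x) and `nonlinear`.
#' @export
#' @examples
#' rcs_basis(c(4, 10, 16))
rcs_basis <- function(x, knots = c(5, 10, 15)) {
  if (length(knots) != 3L || any(diff(knots) <= 0))
    stop("knots must be 3 strictly increasing values", call. = FALSE)
  if (any(!is.finite(x))) stop("ages must be finite", call. = FALSE)
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  pos3 <- function(u) pmax(u, 0)^3
  nl <- (pos3(x - k1) - pos3(x - k2) * (k3 - k1) / (k3 - k2) +
           pos3(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(linear = x, nonlinear = nl)
}

# REML fit of the mixed-effects meta-regression y ~ N(X gamma, v + tau2).
# Returns coefficients, their covariance, tau2 and the Wald chi-square on
# the moderator columns (all but the intercept).
reml_metareg <- function(yi, vi, X) {
  k <- length(yi)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular design: moderator columns are collinear (identical ",
         "moderator values for all studies?)", call. = FALSE)
  fit_at <- function(tau2) {
    W <- 1 / (vi + tau2)
    XtWX <- crossprod(X * W, X)
    gamma <- solve(XtWX, crossprod(X * W, yi))
    r <- yi - drop(X %*% gamma)
    list(gamma = drop(gamma), XtWX = XtWX, rss = sum(W * r^2))
  }
  rll <- function(tau2) {
    f <- fit_at(tau2)
    -0.5 * (sum(log(vi + tau2)) + determinant(f$XtWX)$modulus[1] + f$rss)
  }
  upper <- 10 * stats::var(yi)
  tau2 <- 0
  if (is.finite(upper) && upper > 0) {
    opt <- stats::optimize(rll, c(0, upper), maximum = TRUE, tol = 1e-10)
    if (rll(0) < opt$objective) tau2 <- max(0, opt$maximum)
  }
  f <- fit_at(tau2)
  vcov <- solve(f$XtWX)
  mod <- seq_len(p)[-1L]
  g <- f$gamma[mod]
  qm <- drop(crossprod(g, solve(vcov[mod, mod, drop = FALSE], g)))
  list(coefficients = f$gamma, vcov = vcov, tau2_residual = tau2,
       q_moderator = qm, q_df = length(mod),
       p_moderator = stats::pchisq(qm, df = length(mod),
                                   lower.tail = FALSE),
       weights = 1 / (vi + tau2))
}

#' Spline meta-regression of study effects on mean age
#'
#' Fits the mixed-effects meta-regression y_i ~ N(X_i gamma, v_i + tau^2)
#' with X = [1, restricted-cubic-spline basis of age], tau^2 by REML, and
#' tests the two spline coefficients jointly with a Wald chi-square
#' (Q_moderator, df = 2). The predicted age-effect curve with pointwise
#' 95% confidence bands is evaluated over a grid spanning the study ages;
#' an age is flagged significant where its band excludes zero.
#'
#' @param yi Study effect sizes (typically the 30-minute reallocation
#'   effects, one per study).
#' @param vi Their sampling variances.
#' @param ages Study mean ages in years.
#' @param knots Spline knots (default ages 5, 10, 15).
#' @param gate Minimum number of effects required (default 10, mirroring
#'   the fewer-than-10-effects exclusion rule for meta-regression).
#' @param age_grid Ages at which to evaluate the fitted curve (default 81
#'   equally spaced points across the observed age range).
#' @param level Confidence level for the pointwise bands.
#' @return List of class `"codameta_metareg"`: `coefficients`, `vcov`,
#'   `tau2_residual`, `q_moderator`, `q_df`, `p_moderator`, `knots`,
#'   `weights` (inverse-variance weights, e.g. bubble sizes), and `curve`
#'   (data frame: `age`, `predicted`, `ci_low`, `ci_high`, `significant`).
#' @export
meta_regress <- function(yi, vi, ages, knots = c(5, 10, 15), gate = 10L,
                         age_grid = NULL, level = 0.95) {
  check_effects(yi, vi, k_min = 1L)
  if (length(ages) != length(yi))
    stop("ages must match effects in length", call. = FALSE)
  if (length(yi) < gate)
    stop("meta-regression gate: fewer than ", gate, " effect estimates (",
         length(yi), ")", call. = FALSE)
  B <- rcs_basis(ages, knots)
  X <- cbind(intercept = 1, B)
  fit <- reml_metareg(yi, vi, X)
  if (is.null(age_grid))
    age_grid <- seq(min(ages), max(ages), length.out = 81L)
  Xg <- cbind(1, rcs_basis(age_grid, knots))
  fit$curve <- predict_curve(fit, Xg, age_grid, level)
  fit$knots <- knots
  class(fit) <- "codameta_metareg"
  fit
}

predict_curve <- function(fit, Xg, age_grid, level) {
  pred <- drop(Xg %*% fit$coefficients)
  se <- sqrt(rowSums((Xg %*% fit$vcov) * Xg))
  zq <- stats::qnorm((1 + level) / 2)
  lo <- pred - zq * se
  hi <- pred + zq * se
  data.frame(age = age_grid, predicted = pred, se = se,
             ci_low = lo, ci_high = hi,
             significant = lo > 0 | hi < 0)
}

#' Single-moderator linear meta-regression
#'
#' As [meta_regress()] but with one linear moderator column (used for
#' study quality ratings): X = [1, moderator], Q_moderator on 1 df.
#'
#' @inheritParams meta_regress
#' @param moderator Study-level moderator values (must vary).
#' @return List of class `"codameta_metareg"` (no spline `curve`; the
#'   fitted line is evaluated over the moderator range instead).
#' @export
moderator_scalar <- function(yi, vi, moderator, gate = 10L, level = 0.95) {
  check_effects(yi, vi, k_min = 1L)
  if (length(moderator) != length(yi))
    stop("moderator must match effects in length", call. = FALSE)
  if (length(yi) < gate)
    stop("meta-regression gate: fewer than ", gate, " effect estimates (",
         length(yi), ")", call. = FALSE)
  if (length(unique(moderator)) < 2L)
    stop("constant moderator: no variation to regress on", call. = FALSE)
  X <- cbind(intercept = 1, moderator = as.numeric(moderator))
  fit <- reml_metareg(yi, vi, X)
  grid <- seq(min(moderator), max(moderator), length.out = 41L)
  fit$curve <- predict_curve(fit, cbind(1, grid), grid, level)
  names(fit$curve)[1] <- "moderator"
  class(fit) <- "codameta_metareg"
  fit
}

#' @export
print.codameta_metareg <- function(x, ...) {
  cat("Mixed-effects meta-regression (REML)\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  residual tau^2 = %.4g\n", x$tau2_residual))
  cat(sprintf("  moderator test: Q = %.3f, df = %d, p = %.4g\n",
              x$q_moderator, x$q_df, x$p_moderator))
  invisible(x)
}
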