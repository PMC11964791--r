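#' Generating parameters for a truth-known synthetic study corpus
#'
#' Bundles every parameter of the simulation model used to validate the
#' pipeline: individual 24-hour compositions are logistic-normal (drawn
#' as trivariate-normal pivot coordinates around a center composition and
#' inverted back to minutes closed to 1440), the outcome is linear in the
#' pivot coordinates with Gaussian residuals, between-study heterogeneity
#' enters as an isotropic Gaussian perturbation (SD `tau`) of the
#' coordinate coefficient vector — which induces SD exactly `tau` on every
#' behavior's first-coordinate coefficient — and an age-effect function
#' scales the coefficient vector by study mean age.
#'
#' @param seed Integer seed; mandatory (no implicit seeding).
#' @param center Composition of geometric means, minutes/day (default
#'   539/525/320/57, a large multi-country childhood cohort's printed
#'   means; closed to 1440).
#' @param sigma_z 3 x 3 covariance of individual pivot coordinates
#'   (sleep pivot). Default diag(c(0.10, 0.15, 0.35)^2): little relative
#'   variation in sleep, moderate in sedentary time, large in the
#'   LPA/MVPA balance.
#' @param beta_z True coordinate coefficient vector (sleep pivot,
#'   outcome units per unit coordinate). The default (-0.45, 0.40, 0.35)
#'   yields per-behavior first-coordinate coefficients of about -0.45
#'   (sleep), +0.53 (sedentary), +0.25 (LPA) and -0.32 (MVPA) — inverse
#'   associations for sleep and MVPA, positive for sedentary time and
#'   LPA, as reported for adiposity outcomes.
#' @param intercept Outcome intercept (default 0.45, a typical mean zBMI).
#' @param residual_sd Residual outcome SD (default 0.25, giving per-study
#'   SE(beta1) near 0.1 at the default n = 500).
#' @param tau Between-study SD of the coefficient vector (default 0.05).
#' @param age_effect Age modifier of the coefficient vector: `"flat"`
#'   (none, default), `"linear"` (multiplier 1 + slope (age - 10.5)), or
#'   `"window"` (full effect for ages in [a_low, a_high], multiplier
#'   `attenuation` outside).
#' @param age_params Named list of age-effect parameters: `slope` for
#'   linear; `a_low`, `a_high`, `attenuation` for window (defaults 6, 13,
#'   0).
#' @param n_studies Number of studies K (default 30).
#' @param n Participants per study (scalar, or length-2 range sampled
#'   uniformly; default 500).
#' @param age_range Bounds of the uniform study-mean-age distribution
#'   (default c(3, 18), the eligible age span).
#' @param uncertainty_mix Probabilities with which each study x behavior
#'   coefficient's uncertainty is encoded as SE, 95% CI, or exact
#'   two-sided normal p-value (default 1/3 each).
#' @param outcome_name,outcome_scale Outcome label and scale recorded on
#'   the simulated study records.
#' @return List of class `"synthetic_truth"` with the above fields plus
#'   `beta1_true`, the implied per-behavior first-coordinate coefficients.
#' @export
synthetic_truth <- function(seed,
                            center = c(539, 525, 320, 57),
                            sigma_z = diag(c(0.10, 0.15, 0.35)^2),
                            beta_z = c(-0.45, 0.40, 0.35),
                            intercept = 0.45,
                            residual_sd = 0.25,
                            tau = 0.05,
                            age_effect = c("flat", "linear", "window"),
                            age_params = list(),
                            n_studies = 30L,
                            n = 500L,
                            age_range = c(3, 18),
                            uncertainty_mix = c(se = 1, ci = 1, p = 1) / 3,
                            outcome_name = "zbmi",
                            outcome_scale = "linear") {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory: the generator never seeds implicitly",
         call. = FALSE)
  age_effect <- match.arg(age_effect)
  center <- close_composition(center)
  sigma_z <- as.matrix(sigma_z)
  ev <- eigen(sigma_z, symmetric = TRUE, only.values = TRUE)$values
  if (!isTRUE(all.equal(sigma_z, t(sigma_z))) || any(ev < -1e-12))
    stop("sigma_z must be a symmetric positive semi-definite 3x3 matrix",
         call. = FALSE)
  if (residual_sd <= 0) stop("residual_sd must be positive", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (age_range[1] < 3 || age_range[2] > 18 || diff(age_range) < 0)
    stop("age_range must lie within [3, 18]", call. = FALSE)
  ap <- utils::modifyList(
    switch(age_effect,
           flat = list(),
           linear = list(slope = 0),
           window = list(a_low = 6, a_high = 13, attenuation = 0)),
    age_params)
  truth <- list(seed = as.integer(seed), center = center,
                sigma_z = sigma_z, beta_z = as.numeric(beta_z),
                intercept = intercept, residual_sd = residual_sd,
                tau = tau, age_effect = age_effect, age_params = ap,
                n_studies = as.integer(n_studies), n = n,
                age_range = age_range,
                uncertainty_mix = uncertainty_mix / sum(uncertainty_mix),
                outcome_name = outcome_name, outcome_scale = outcome_scale)
  truth$beta1_true <- beta1_by_behavior(truth$beta_z)
  class(truth) <- "synthetic_truth"
  truth
}

# First-coordinate coefficient for each behavior implied by a sleep-pivot
# coordinate coefficient vector (orthogonal basis change per rotation).
beta1_by_behavior <- function(beta_z) {
  vapply(behaviors(),
         function(b) drop(pivot_rotation("sleep", b) %*% beta_z)[1],
         numeric(1))
}

# Age multiplier applied to the coefficient vector.
age_multiplier <- function(truth, age) {
  switch(truth$age_effect,
         flat = 1,
         linear = 1 + truth$age_params$slope * (age - 10.5),
         window = if (age >= truth$age_params$a_low &&
                        age <= truth$age_params$a_high) 1
                  else truth$age_params$attenuation)
}

# Deterministic per-study seed below 2^31.
derive_seed <- function(seed, study_index) {
  as.integer((as.double(seed) * 1000003 + study_index * 7919) %% 2147483629)
}

#' Simulate one study's individual-level dataset
#'
#' Draws `n` pivot-coordinate vectors from a trivariate normal centered
#' at the truth center's coordinates, inverts them to compositions closed
#' to 1440 min, and generates the outcome as intercept +
#' (coefficients + study perturbation) . coordinates + noise. The random
#' state is derived deterministically from (seed, study_index), so the
#' same pair always reproduces the same dataset.
#'
#' @param truth A [synthetic_truth()] object.
#' @param study_index Positive integer identifying the study.
#' @param mean_age Study mean age; drawn uniformly from
#'   `truth$age_range` when `NULL`.
#' @return List: `data` (data frame `study_id`, `sleep_min`, `sed_min`,
#'   `lpa_min`, `mvpa_min`, `outcome`), `mean_age`, `coef_z` (the study's
#'   realized coordinate coefficients, sleep pivot) and `beta1_true`
#'   (the study's realized first-coordinate coefficient per behavior).
#' @export
simulate_individuals <- function(truth, study_index, mean_age = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (study_index < 1 || study_index != round(study_index))
    stop("study_index must be a positive integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(truth$seed, study_index))

  if (is.null(mean_age))
    mean_age <- stats::runif(1, truth$age_range[1], truth$age_range[2])
  n <- if (length(truth$n) == 2L)
    sample(truth$n[1]:truth$n[2], 1L) else as.integer(truth$n)

  coef_z <- age_multiplier(truth, mean_age) * truth$beta_z +
    stats::rnorm(3, 0, truth$tau)

  center_z <- pivot_coordinates(truth$center, "sleep")
  L <- chol_psd(truth$sigma_z)
  Z <- matrix(stats::rnorm(n * 3L), n, 3L) %*% L
  Z <- sweep(Z, 2L, as.numeric(center_z), "+")
  comps <- t(apply(Z, 1L, pivot_inverse, pivot = "sleep"))
  y <- truth$intercept + drop(Z %*% coef_z) +
    stats::rnorm(n, 0, truth$residual_sd)

  data <- data.frame(study_id = paste0("study_", study_index),
                     sleep_min = comps[, "sleep"],
                     sed_min = comps[, "sedentary"],
                     lpa_min = comps[, "lpa"],
                     mvpa_min = comps[, "mvpa"],
                     outcome = y, stringsAsFactors = FALSE)
  list(data = data, mean_age = mean_age, coef_z = coef_z,
       beta1_true = beta1_by_behavior(coef_z))
}

# Cholesky-type factor tolerating positive semi-definite matrices.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Simulate a multi-study corpus with retained truth
#'
#' Generates `truth$n_studies` studies via [simulate_individuals()],
#' re-estimates each study's coefficients with [fit_study()], and
#' assembles the study-record table the meta-analytic pipeline consumes.
#' Each study x behavior coefficient's uncertainty is encoded as exactly
#' one of SE, 95% CI or an exact two-sided normal p-value (mixing
#' probabilities `truth$uncertainty_mix`), exercising every
#' standard-error reconstruction path downstream; the fitted SEs are
#' withheld in the truth sidecar for round-trip scoring.
#'
#' @param truth A [synthetic_truth()] object.
#' @return List: `records` (study-record data frame; see
#'   [read_study_records()]), and `truth` — the input parameters plus
#'   per-study realizations: `mean_age`, `beta1_true` (K x 4), `beta1_fit`
#'   and `se_fit` (K x 4 withheld fitted values), `rep_type` (K x 4
#'   encoding used).
#' @export
simulate_corpus <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  K <- truth$n_studies
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(truth$seed, 0L))
  ages <- stats::runif(K, truth$age_range[1], truth$age_range[2])
  reps <- matrix(sample(c("se", "ci", "p"), K * 4L, replace = TRUE,
                        prob = truth$uncertainty_mix), K, 4L,
                 dimnames = list(NULL, behaviors()))
  quality <- stats::runif(K, 55, 95)  # span of published quality ratings

  records <- vector("list", K)
  b1_true <- b1_fit <- se_fit <- matrix(NA_real_, K, 4L,
                                        dimnames = list(NULL, behaviors()))
  for (k in seq_len(K)) {
    sim <- simulate_individuals(truth, k, mean_age = ages[k])
    fit <- fit_study(sim$data)
    gm <- close_composition(exp(colMeans(log(
      as.matrix(sim$data[, unname(comp_columns())])))))
    b1_true[k, ] <- sim$beta1_true
    b1_fit[k, ] <- fit$beta1
    se_fit[k, ] <- fit$se_beta1
    rows <- data.frame(study_id = paste0("study_", k),
                       n = nrow(sim$data), mean_age = ages[k],
                       sleep_min = gm[["sleep"]], sed_min = gm[["sedentary"]],
                       lpa_min = gm[["lpa"]], mvpa_min = gm[["mvpa"]],
                       outcome_name = truth$outcome_name,
                       outcome_scale = truth$outcome_scale,
                       mean_outcome = mean(sim$data$outcome),
                       behavior = behaviors(),
                       beta1 = fit$beta1,
                       se = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p_value = NA_real_,
                       quality_pct = quality[k],
                       stringsAsFactors = FALSE)
    zq <- stats::qnorm(0.975)
    for (i in seq_len(4L)) {
      se_i <- fit$se_beta1[i]
      switch(reps[k, i],
             se = rows$se[i] <- se_i,
             ci = { rows$ci_low[i] <- fit$beta1[i] - zq * se_i
                    rows$ci_high[i] <- fit$beta1[i] + zq * se_i },
             p = rows$p_value[i] <- 2 * stats::pnorm(-abs(fit$beta1[i] /
                                                            se_i)))
    }
    records[[k]] <- rows
  }
  truth$realized <- list(mean_age = ages, beta1_true = b1_true,
                         beta1_fit = b1_fit, se_fit = se_fit,
                         rep_type = reps)
  list(records = do.call(rbind, records), truth = truth)
}

#' Simulate study-level effects for meta-regression checks
#'
#' Draws effects directly from the meta-regression sampling model
#' y_i ~ N(mu(age_i), v_i + tau^2): the lightweight generator used for
#' calibration and power checks of the moderator machinery, where the
#' individual-level layer would add cost but no information (the fitted
#' model only ever sees effects, variances and ages).
#'
#' @param k Number of studies.
#' @param mu_fun Function age -> true mean effect.
#' @param se Within-study standard errors (recycled to length `k`).
#' @param tau Between-study SD on the effect scale.
#' @param age_range Uniform bounds for study mean ages.
#' @param seed Integer seed (mandatory).
#' @return Data frame: `age`, `yi`, `vi`.
#' @export
simulate_effects <- function(k, mu_fun, se = 0.1, tau = 0,
                             age_range = c(3, 18), seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483629))
  age <- stats::runif(k, age_range[1], age_range[2])
  se <- rep_len(se, k)
  mu <- vapply(age, mu_fun, numeric(1))
  yi <- stats::rnorm(k, mu, sqrt(se^2 + tau^2))
  data.frame(age = age, yi = yi, vi = se^2)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic corpus truth\n")
  cat(sprintf("  K = %d studies, n = %s per study, seed = %d\n",
              x$n_studies, paste(x$n, collapse = "-"), x$seed))
  cat("  center (min/day):",
      paste(sprintf("%s %.0f", behaviors(), x$center), collapse = ", "),
      "\n")
  cat("  beta1 per behavior:",
      paste(sprintf("%s %.3f", behaviors(), x$beta1_true), collapse = ", "),
      "\n")
  cat(sprintf("  residual SD %.3g, tau %.3g, age effect '%s'\n",
              x$residual_sd, x$tau, x$age_effect))
  invisible(x)
}
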