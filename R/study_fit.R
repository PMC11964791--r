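#' Re-estimate first-pivot-coordinate coefficients from individual data
#'
#' For each behavior in turn, the composition is expressed in pivot
#' coordinates with that behavior isolated in the first coordinate, and
#' the outcome is regressed by ordinary least squares on the three
#' coordinates, an intercept and any covariates. The coefficient on the
#' first coordinate and its standard error (residual degrees of freedom
#' n - p, homoskedastic) are returned per behavior. The four rotations
#' are orthogonal reparameterizations of one column space, so fitted
#' values, residuals and R-squared are identical across them.
#'
#' @param data Data frame with columns `sleep_min`, `sed_min`, `lpa_min`,
#'   `mvpa_min` (minutes/day, strictly positive), `outcome`, and any
#'   covariate columns. Optional `study_id` column.
#' @param covariates Character vector of covariate column names (default
#'   none). Character/factor covariates are expanded to reference-coded
#'   indicators; the reference is the first observed level.
#' @param keep_fitted If `TRUE`, attach the n x 4 matrix of fitted values
#'   (one column per pivot rotation) as attribute `"fitted"`.
#' @return Data frame with one row per behavior: `behavior`, `beta1`,
#'   `se_beta1`, `n`, `r_squared`. Attribute `"zcoef"` holds the 4 x 3
#'   matrix of full coordinate-coefficient vectors (rows = pivots), and
#'   `"covariates"` the covariate names used.
#' @export
#' @examples
#' truth <- synthetic_truth(seed = 1, n = 80)
#' sim <- simulate_individuals(truth, 1)
#' fit_study(sim$data)
fit_study <- function(data, covariates = character(), keep_fitted = FALSE) {
  cols <- comp_columns()
  need <- c(unname(cols), "outcome")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("individual dataset is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov))
    stop("covariate columns not found: ", paste(miss_cov, collapse = ", "),
         call. = FALSE)
  n <- nrow(data)
  if (n < 10L)
    stop("too few observations: need at least 10 participants, got ", n,
         call. = FALSE)

  X <- as.matrix(data[, unname(cols)])
  if (any(!is.finite(X)) || any(X <= 0))
    stop("invalid compositions: all four behavior columns must be strictly ",
         "positive and finite", call. = FALSE)
  # per-row closure (ilr coordinates are closure-invariant, but keep tidy)
  y <- as.numeric(data$outcome)
  if (any(!is.finite(y))) stop("outcome contains non-finite values",
                               call. = FALSE)

  C <- covariate_matrix(data, covariates)
  p <- 4L + ncol(C)  # intercept + 3 coordinates + covariates
  if (n <= p + 2L)
    stop("too few observations: n = ", n, " for ", p, " parameters",
         call. = FALSE)

  tss <- sum((y - mean(y))^2)
  out <- data.frame(behavior = behaviors(), beta1 = NA_real_,
                    se_beta1 = NA_real_, n = n, r_squared = NA_real_,
                    stringsAsFactors = FALSE)
  zcoef <- matrix(NA_real_, 4L, 3L,
                  dimnames = list(behaviors(), c("z1", "z2", "z3")))
  fitted_mat <- if (keep_fitted)
    matrix(NA_real_, n, 4L, dimnames = list(NULL, behaviors())) else NULL

  for (i in seq_along(behaviors())) {
    b <- behaviors()[i]
    Z <- pivot_coordinates_matrix(X, b)
    M <- cbind(`(Intercept)` = 1, Z, C)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      bad <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
      stop("rank-deficient design: collinear column(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cf <- qr.coef(qrM, y)
    res <- y - drop(M %*% cf)
    rss <- sum(res^2)
    sigma2 <- rss / (n - ncol(M))
    # SE of z1 coefficient from (M'M)^{-1}
    R <- qr.R(qrM)[, order(qrM$pivot), drop = FALSE]
    XtX_inv <- chol2inv(chol(crossprod(R)))
    out$beta1[i] <- cf[["z1"]]
    out$se_beta1[i] <- sqrt(sigma2 * XtX_inv[2L, 2L])
    out$r_squared[i] <- 1 - rss / tss
    zcoef[i, ] <- cf[c("z1", "z2", "z3")]
    if (keep_fitted) fitted_mat[, i] <- y - res
  }
  attr(out, "zcoef") <- zcoef
  attr(out, "covariates") <- covariates
  if (keep_fitted) attr(out, "fitted") <- fitted_mat
  out
}

# Expand covariates to a numeric matrix; character/factor columns become
# reference-coded indicators with the first observed level as reference.
covariate_matrix <- function(data, covariates) {
  if (!length(covariates)) return(matrix(nrow = nrow(data), ncol = 0))
  blocks <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      return(m)
    }
    x <- as.character(x)
    lev <- unique(x)  # first observed level is the reference
    if (length(lev) < 2L)
      stop("covariate '", v, "' is constant", call. = FALSE)
    m <- sapply(lev[-1L], function(l) as.numeric(x == l))
    colnames(m) <- paste0(v, lev[-1L])
    m
  })
  do.call(cbind, blocks)
}
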