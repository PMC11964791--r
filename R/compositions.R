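#' Behavior labels of the 24-hour movement composition
#'
#' The four mutually exclusive and exhaustive parts of the day, in the
#' canonical order used throughout the package: sleep, sedentary time,
#' light-intensity physical activity (LPA) and moderate-to-vigorous
#' physical activity (MVPA).
#'
#' @return Character vector of the four behavior labels.
#' @export
#' @examples
#' behaviors()
behaviors <- function() c("sleep", "sedentary", "lpa", "mvpa")

# CSV column names for composition parts, keyed by behavior label
comp_columns <- function() {
  c(sleep = "sleep_min", sedentary = "sed_min", lpa = "lpa_min",
    mvpa = "mvpa_min")
}

#' Minutes in a day
#' @return 1440, the fixed total of a daily time-use composition.
#' @export
day_minutes <- function() 1440

check_behavior <- function(b) {
  if (length(b) != 1L || !b %in% behaviors())
    stop("unknown behavior label '", b, "'; must be one of: ",
         paste(behaviors(), collapse = ", "), call. = FALSE)
  b
}

#' Close a 4-part time-use composition to a fixed daily total
#'
#' Rescales the parts so they sum to `total` minutes without changing any
#' ratio between parts. Published geometric-mean compositions rarely sum
#' exactly to 1440 (geometric means of parts do not preserve the total),
#' so closure is applied before any coordinate computation.
#'
#' @param parts Numeric vector of 4 strictly positive minutes/day, in the
#'   order `behaviors()`; names, if present, are preserved.
#' @param total Day length in minutes (default 1440).
#' @return Numeric vector of 4 parts summing to `total`, named by behavior.
#' @export
#' @examples
#' close_composition(c(539, 525, 320, 57))  # printed means summing to 1441
close_composition <- function(parts, total = day_minutes()) {
  parts <- as.numeric(parts)
  if (length(parts) != 4L)
    stop("a composition has exactly 4 parts (",
         paste(behaviors(), collapse = ", "), ")", call. = FALSE)
  if (any(!is.finite(parts)) || any(parts <= 0))
    stop("invalid composition: all parts must be strictly positive and finite",
         call. = FALSE)
  if (!is.finite(total) || total <= 0)
    stop("total must be a positive number of minutes", call. = FALSE)
  s <- sum(parts)
  if (s <= 0) stop("invalid composition: parts sum to zero", call. = FALSE)
  out <- parts * (total / s)
  names(out) <- behaviors()
  out
}

# Orthonormal pivot (ilr) contrast matrix for D parts in a given order.
# Column j encodes z_j = sqrt((D-j)/(D-j+1)) * ln(x_j / gmean(x_{j+1..D})).
pivot_contrast <- function(D = 4L) {
  V <- matrix(0, D, D - 1L)
  for (j in seq_len(D - 1L)) {
    r <- D - j
    a <- sqrt(r / (r + 1))
    V[j, j] <- a
    V[(j + 1L):D, j] <- -a / r
  }
  V
}

pivot_order <- function(pivot) {
  check_behavior(pivot)
  c(pivot, setdiff(behaviors(), pivot))
}

#' Pivot (isometric log-ratio) coordinates of a composition
#'
#' Maps a 4-part composition to real 3-space using the sequential binary
#' partition in which the chosen behavior is isolated in the first
#' coordinate: z1 = sqrt(3/4) * ln(x_pivot / g(x_others)), where g() is the
#' geometric mean of the three remaining parts (kept in canonical order).
#' Coordinates are invariant to closure: scaling all parts by a common
#' factor leaves them unchanged.
#'
#' @param comp Numeric vector of 4 strictly positive parts in the order
#'   `behaviors()`.
#' @param pivot Behavior label isolated in the first coordinate.
#' @return Named numeric vector `c(z1, z2, z3)` with attribute
#'   `pivot_order` giving the part ordering used.
#' @export
#' @examples
#' pivot_coordinates(c(600, 480, 300, 60), "sleep")
pivot_coordinates <- function(comp, pivot = "sleep") {
  ord <- pivot_order(pivot)
  comp <- as.numeric(comp)
  if (length(comp) != 4L || any(!is.finite(comp)) || any(comp <= 0))
    stop("invalid composition: need 4 strictly positive finite parts",
         call. = FALSE)
  names(comp) <- behaviors()
  z <- drop(crossprod(pivot_contrast(4L), log(comp[ord])))
  names(z) <- c("z1", "z2", "z3")
  attr(z, "pivot_order") <- ord
  z
}

# z coordinates for a whole matrix of compositions (rows = subjects,
# columns in behaviors() order); used by the fitting and synthetic modules.
pivot_coordinates_matrix <- function(X, pivot = "sleep") {
  ord <- pivot_order(pivot)
  idx <- match(ord, behaviors())
  Z <- log(X[, idx, drop = FALSE]) %*% pivot_contrast(4L)
  colnames(Z) <- c("z1", "z2", "z3")
  Z
}

# Inverse map: 3 pivot coordinates (given pivot) -> composition closed to total
pivot_inverse <- function(z, pivot = "sleep", total = day_minutes()) {
  ord <- pivot_order(pivot)
  x <- exp(drop(pivot_contrast(4L) %*% as.numeric(z)))
  x <- x / sum(x) * total
  out <- numeric(4L)
  out[match(ord, behaviors())] <- x
  names(out) <- behaviors()
  out
}

# Rotation matrix A such that z_to = A %*% z_from for pivot changes
# (both bases are orthonormal on the clr hyperplane, so A is orthogonal).
pivot_rotation <- function(from, to) {
  V <- pivot_contrast(4L)
  P_from <- match(pivot_order(from), behaviors())
  P_to <- match(pivot_order(to), behaviors())
  Vf <- matrix(0, 4, 3); Vf[P_from, ] <- V
  Vt <- matrix(0, 4, 3); Vt[P_to, ] <- V
  crossprod(Vt, Vf)
}

#' All-for-one reallocation of daily minutes
#'
#' Increases the target behavior by `delta` minutes while the three
#' remaining behaviors shrink proportionally to their current sizes, so
#' the day total stays fixed and the subcomposition of the non-target
#' parts is unchanged (all pairwise ratios among them preserved).
#'
#' @param comp Numeric vector of 4 parts closed to `total`.
#' @param target Behavior label that gains the minutes.
#' @param delta Minutes added to the target (negative to remove); must
#'   keep both the target and the remaining parts strictly positive.
#' @param total Day length in minutes (default 1440).
#' @return Reallocated composition (named, summing to `total`).
#' @export
#' @examples
#' reallocate_all_for_one(c(600, 480, 300, 60), "mvpa", 60)
reallocate_all_for_one <- function(comp, target, delta,
                                   total = day_minutes()) {
  comp <- close_composition(comp, total)
  check_behavior(target)
  if (!is.finite(delta)) stop("delta must be finite", call. = FALSE)
  xt <- comp[[target]]
  if (delta <= -xt)
    stop("infeasible reallocation: delta = ", delta,
         " would make ", target, " non-positive (lower bound ", -xt, ")",
         call. = FALSE)
  if (delta >= total - xt)
    stop("infeasible reallocation: delta = ", delta,
         " would exhaust the remaining behaviors (upper bound ",
         total - xt, ")", call. = FALSE)
  scale <- (total - xt - delta) / (total - xt)
  out <- comp * scale
  out[[target]] <- xt + delta
  out
}

#' Change in the first pivot coordinate under an all-for-one reallocation
#'
#' The quantity that multiplies an extracted first-coordinate regression
#' coefficient to predict the outcome change for a `delta`-minute
#' reallocation. Because the non-target subcomposition is preserved, the
#' change has the closed form
#' sqrt(3/4) * ln( (x_t + delta) (T - x_t) / ( x_t (T - x_t - delta) ) ),
#' strictly increasing in `delta` and zero at `delta = 0`.
#'
#' @inheritParams reallocate_all_for_one
#' @return The scalar change in z1 (pivot = `target`).
#' @export
#' @examples
#' delta_first_coordinate(c(600, 480, 300, 60), "mvpa", 30)
delta_first_coordinate <- function(comp, target, delta,
                                   total = day_minutes()) {
  comp <- close_composition(comp, total)
  check_behavior(target)
  if (!is.finite(delta)) stop("delta must be finite", call. = FALSE)
  xt <- comp[[target]]
  if (delta <= -xt || delta >= total - xt)
    stop("infeasible reallocation: delta = ", delta, " for ", target,
         " must lie in (", -xt, ", ", total - xt, ")", call. = FALSE)
  sqrt(3 / 4) * (log((xt + delta) / xt) -
                   log((total - xt - delta) / (total - xt)))
}
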