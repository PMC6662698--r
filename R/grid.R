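#' Discretized circular state space
#'
#' The mnemonic (color) circle is discretized into `n_bins` evenly spaced
#' bins. Bin `k` (0-based) covers `[k*delta, (k+1)*delta)` with its center at
#' `(k + 1/2)*delta`, a half-open partition of the circle.
#'
#' @param n_bins number of bins (default 100).
#' @return an object of class `wm_grid` with fields `n_bins`, `centers`
#'   (radians), and `delta` (bin width, radians).
#' @examples
#' g <- wm_grid()
#' sum(rep(g$delta, g$n_bins)) / (2 * pi)  # covers the circle exactly once
#' @export
wm_grid <- function(n_bins = 100) {
  stopifnot(is.numeric(n_bins), length(n_bins) == 1, n_bins >= 4,
            n_bins == round(n_bins))
  n_bins <- as.integer(n_bins)
  delta <- 2 * pi / n_bins
  structure(
    list(n_bins = n_bins,
         centers = (seq_len(n_bins) - 0.5) * delta,
         delta = delta),
    class = "wm_grid")
}

#' @export
print.wm_grid <- function(x, ...) {
  cat(sprintf("<wm_grid> %d bins, width %.3f deg\n", x$n_bins, rad2deg(x$delta)))
  invisible(x)
}

is_wm_grid <- function(x) inherits(x, "wm_grid")

#' Probability density over the circular grid
#'
#' A `wm_pfield` stores a nonnegative density (probability per radian)
#' sampled at the bin centers of a [wm_grid()], normalized so that
#' `sum(values * delta) == 1`.
#'
#' @param values nonnegative densities per radian, one per bin.
#' @param grid a [wm_grid()].
#' @param normalize renormalize after clipping tiny negative values
#'   (default `TRUE`). Negative inputs below `-1e-12` of total mass raise an
#'   error; smaller ones are treated as rounding and clipped.
#' @return an object of class `wm_pfield`.
#' @export
wm_pfield <- function(values, grid, normalize = TRUE) {
  stopifnot(is_wm_grid(grid), is.numeric(values),
            length(values) == grid$n_bins)
  if (any(!is.finite(values))) stop("non-finite density values", call. = FALSE)
  if (min(values) < -1e-9) {
    stop("density has substantively negative values (min ",
         format(min(values)), ")", call. = FALSE)
  }
  values <- pmax(values, 0)
  mass <- sum(values) * grid$delta
  if (normalize) {
    if (mass <= 0) stop("cannot normalize an all-zero density", call. = FALSE)
    values <- values / mass
  } else if (abs(mass - 1) > 1e-8) {
    stop("density does not integrate to 1 (mass = ", format(mass), ")",
         call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "wm_pfield")
}

#' @rdname wm_pfield
#' @export
pfield_uniform <- function(grid = wm_grid()) {
  wm_pfield(rep(1 / (2 * pi), grid$n_bins), grid, normalize = FALSE)
}

#' @rdname wm_pfield
#' @param mu mean direction, radians.
#' @param sd circular SD, radians.
#' @details `pfield_vonmises()` samples a von Mises density (circular-SD
#'   parameterization) at the bin centers and renormalizes on the grid, so
#'   discretization error does not leak into total mass.
#' @export
pfield_vonmises <- function(grid, mu, sd) {
  wm_pfield(dvonmises_sd(grid$centers, mu, sd), grid, normalize = TRUE)
}

#' @rdname wm_pfield
#' @param theta location of a point mass, radians.
#' @details `pfield_delta()` places a unit point mass at `theta`,
#'   distributed linearly between the two nearest bin centers so the
#'   discretized mean matches the requested location.
#' @export
pfield_delta <- function(grid, theta) {
  stopifnot(is_wm_grid(grid), length(theta) == 1, is.finite(theta))
  u <- wrap_rad(theta - grid$centers[1]) / grid$delta
  i0 <- (as.integer(floor(u)) %% grid$n_bins) + 1L
  fr <- u - floor(u)
  v <- rep(0, grid$n_bins)
  v[i0] <- (1 - fr) / grid$delta
  i1 <- (i0 %% grid$n_bins) + 1L
  v[i1] <- v[i1] + fr / grid$delta
  wm_pfield(v, grid)
}

#' @export
print.wm_pfield <- function(x, ...) {
  cat(sprintf("<wm_pfield> %d bins, mass %.6f, circ mean %.1f deg\n",
              x$grid$n_bins, sum(x$values) * x$grid$delta,
              rad2deg(pfield_mean(x))))
  invisible(x)
}

#' Summaries of a probability field
#'
#' Circular mean and circular SD of a density on the grid, by trigonometric
#' moments weighted by bin mass.
#'
#' @param p a [wm_pfield()].
#' @return angle in radians (`pfield_mean`) or circular SD in radians
#'   (`pfield_sd`).
#' @export
pfield_mean <- function(p) {
  w <- p$values * p$grid$delta
  wrap_rad(atan2(sum(w * sin(p$grid$centers)), sum(w * cos(p$grid$centers))))
}

#' @rdname pfield_mean
#' @export
pfield_sd <- function(p) {
  w <- p$values * p$grid$delta
  r <- sqrt(sum(w * sin(p$grid$centers))^2 + sum(w * cos(p$grid$centers))^2)
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r))
}

#' Interpolate a grid density at arbitrary angles
#'
#' Linear interpolation between adjacent bin centers with periodic wrap;
#' used to evaluate report likelihoods (reports are continuous, the grid is
#' not).
#'
#' @param p a [wm_pfield()] (or a bare numeric vector of densities).
#' @param theta angles in radians.
#' @param grid required if `p` is a bare vector.
#' @return density per radian at `theta`.
#' @export
pfield_interp <- function(p, theta, grid = NULL) {
  if (inherits(p, "wm_pfield")) {
    grid <- p$grid
    v <- p$values
  } else {
    stopifnot(is_wm_grid(grid), length(p) == grid$n_bins)
    v <- p
  }
  interp_circular(v, theta, grid)
}

# vectorized periodic linear interpolation of per-bin values at angles theta
interp_circular <- function(v, theta, grid) {
  n <- grid$n_bins
  d <- grid$delta
  # position relative to first center
  u <- wrap_rad(theta - grid$centers[1]) / d
  i0 <- floor(u)
  frac <- u - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  v[i0] * (1 - frac) + v[i1] * frac
}

#' Mean absolute circular error of a density about a target
#'
#' Quadrature of `E|wrap(theta - target)|` under a grid density; the
#' building block of the normative error-over-time simulations.
#'
#' @param p a [wm_pfield()].
#' @param target target angle, radians.
#' @return expected absolute error in degrees.
#' @export
pfield_mean_abs_error <- function(p, target) {
  err <- abs(circ_error_rad(p$grid$centers, target))
  rad2deg(sum(err * p$values) * p$grid$delta)
}
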