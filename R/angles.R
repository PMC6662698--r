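#' Circular angle utilities
#'
#' Hues are abstract angles on a circle. Internally the package works in
#' radians; all user-facing values (trial tables, profiles, fixed-point
#' locations) are degrees. Positive signed deviations are clockwise.
#'
#' @name angles
NULL

#' Wrap an angle in degrees into `[0, 360)`
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @export
wrap_deg <- function(x) {
  stopifnot(is.numeric(x))
  out <- x %% 360
  # guard against -1e-14 %% 360 == 360 after floating point
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Wrap an angle in radians into `[0, 2*pi)`
#' @param x numeric vector of angles in radians.
#' @return numeric vector in `[0, 2*pi)`.
#' @export
wrap_rad <- function(x) {
  out <- x %% (2 * pi)
  out[out >= 2 * pi] <- out[out >= 2 * pi] - 2 * pi
  out
}

#' Signed circular deviation between a report and a target
#'
#' Computes the angular deviation `report - target`, wrapped into
#' `(-180, 180]`. Positive values are clockwise deviations. The ambiguous
#' 180-degree case is assigned `+180` by convention.
#'
#' @param report numeric vector of reported angles, degrees.
#' @param target numeric vector of target angles, degrees (recycled).
#' @return signed deviation in degrees, in `(-180, 180]`.
#' @examples
#' circ_error(10, 350)  # +20, across the wrap point
#' circ_error(37, 37)   # 0
#' @export
circ_error <- function(report, target) {
  if (!is.numeric(report) || !is.numeric(target) ||
      any(!is.finite(report)) || any(!is.finite(target))) {
    stop("circ_error() requires finite numeric angles", call. = FALSE)
  }
  d <- (report - target) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname circ_error
#' @details `circ_error_rad()` is the radian analogue, wrapping into
#'   `(-pi, pi]`.
#' @export
circ_error_rad <- function(report, target) {
  d <- (report - target) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and circular standard deviation
#'
#' Standard trigonometric-moment definitions: the mean direction is
#' `atan2(mean(sin), mean(cos))` and the circular SD is `sqrt(-2 log R)`
#' where `R` is the mean resultant length.
#'
#' @param x angles in radians.
#' @return `circ_mean_rad()`: mean direction in `[0, 2*pi)`;
#'   `circ_sd_rad()`: circular SD in radians.
#' @export
circ_mean_rad <- function(x) {
  wrap_rad(atan2(mean(sin(x)), mean(cos(x))))
}

#' @rdname circ_mean_rad
#' @export
circ_sd_rad <- function(x) {
  r <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r))
}

#' Von Mises density parameterized by circular standard deviation
#'
#' The concentration is obtained from the circular SD `s` (radians) through
#' the high-concentration map `kappa = 1/s^2`, the convention used for the
#' drift basis, the encoding kernel, and the decoding kernel throughout the
#' package.
#'
#' @param theta angles in radians at which to evaluate.
#' @param mu mean direction, radians.
#' @param sd circular standard deviation, radians.
#' @return density per radian.
#' @export
dvonmises_sd <- function(theta, mu, sd) {
  stopifnot(sd > 0)
  kappa <- 1 / sd^2
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Derivative of the von Mises density with respect to angle
#' @inheritParams dvonmises_sd
#' @return d/dtheta of the density, per radian squared.
#' @export
dvonmises_sd_deriv <- function(theta, mu, sd) {
  kappa <- 1 / sd^2
  -kappa * sin(theta - mu) * dvonmises_sd(theta, mu, sd)
}

#' Draw von Mises variates (circular-SD parameterization)
#'
#' Best-Fisher rejection sampler; used by the stochastic trial simulator.
#'
#' @param n number of draws.
#' @inheritParams dvonmises_sd
#' @return angles in radians, in `[0, 2*pi)`.
#' @export
rvonmises_sd <- function(n, mu, sd) {
  kappa <- 1 / sd^2
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(sum(ok), n - got)
      out[(got + 1):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_rad(out + mu)
}
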