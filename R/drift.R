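#' Von Mises derivative basis for the drift function
#'
#' The drift function G(theta) is expanded in `n_basis` first derivatives of
#' von Mises densities with means `2*pi*j/n_basis` (j = 1..n_basis) and
#' circular SD `2*pi/n_basis`, i.e. bumps separated by one standard
#' deviation around the circle. Each basis curve integrates to zero (it is
#' the derivative of a periodic density), so any expansion conserves
#' probability when used as an advection field.
#'
#' @param n_basis number of basis functions (default 12).
#' @param grid a [wm_grid()] on which the curves are sampled.
#' @return object of class `wm_basis`: `n_basis`, `means` (radians), `sd`
#'   (radians), and `B`, an `n_bins x n_basis` matrix of sampled curves.
#' @export
drift_basis <- function(n_basis = 12, grid = wm_grid()) {
  stopifnot(is_wm_grid(grid))
  if (!is.numeric(n_basis) || n_basis < 2 || n_basis != round(n_basis)) {
    stop("n_basis must be an integer >= 2", call. = FALSE)
  }
  n_basis <- as.integer(n_basis)
  means <- 2 * pi * seq_len(n_basis) / n_basis
  s <- 2 * pi / n_basis
  B <- vapply(means,
              function(mu) dvonmises_sd_deriv(grid$centers, mu, s),
              numeric(grid$n_bins))
  structure(list(n_basis = n_basis, means = wrap_rad(means), sd = s,
                 B = B, grid = grid),
            class = "wm_basis")
}

#' @export
print.wm_basis <- function(x, ...) {
  cat(sprintf("<wm_basis> %d von Mises derivative curves (sd %.1f deg) on %d bins\n",
              x$n_basis, rad2deg(x$sd), x$grid$n_bins))
  invisible(x)
}

#' Evaluate a drift function from basis weights
#'
#' Forms `G = B %*% w` and divides by its maximum absolute value over the
#' grid so that `max|G| = 1`; the drift gain beta then reads directly as the
#' maximum instantaneous drift rate (rad/s). All-zero weights return the
#' zero field with `norm_constant = 0` flagged rather than dividing by zero.
#'
#' @param weights numeric vector, one per basis function.
#' @param basis a [drift_basis()].
#' @return object of class `wm_drift`: `weights`, `values` (normalized G at
#'   bin centers), `norm_constant`, `grid`, `basis`.
#' @export
drift_field <- function(weights, basis = drift_basis()) {
  stopifnot(inherits(basis, "wm_basis"))
  if (length(weights) != basis$n_basis) {
    stop("need ", basis$n_basis, " weights, got ", length(weights),
         call. = FALSE)
  }
  g <- drop(basis$B %*% weights)
  m <- max(abs(g))
  if (m == 0) {
    values <- g
  } else {
    values <- g / m
  }
  structure(list(weights = as.numeric(weights), values = values,
                 norm_constant = m, grid = basis$grid, basis = basis),
            class = "wm_drift")
}

#' @export
print.wm_drift <- function(x, ...) {
  fp <- tryCatch(fixed_points(x), error = function(e) NULL)
  cat(sprintf("<wm_drift> %d basis weights, max|G| = %g", length(x$weights),
              max(abs(x$values))))
  if (!is.null(fp)) cat(sprintf(", %d stable / %d unstable fixed points",
                                nrow(fp$stable), nrow(fp$unstable)))
  cat("\n")
  invisible(x)
}

#' Evaluate a drift field at arbitrary angles
#' @param field a [drift_field()].
#' @param theta angles in radians.
#' @return drift values (rad/s at unit gain).
#' @export
drift_at <- function(field, theta) {
  interp_circular(field$values, theta, field$grid)
}

#' Stable and unstable fixed points of a drift field
#'
#' Stable fixed points (attractors) are zero crossings of G with negative
#' slope — equivalently peaks of the numerical integral of G; unstable
#' fixed points have positive slope. Crossing locations are refined by
#' linear interpolation between the adjacent bins of opposite sign. Weak
#' attractors are removed: a stable fixed point whose peak prominence in the
#' integral of G falls at or below the `prominence_quantile` quantile of the
#' prominences in this field is excluded, together with flanking unstable
#' points so that stability still alternates.
#'
#' @param field a [wm_drift()] field.
#' @param prominence_quantile quantile cutoff in `[0, 1)` (default 0.2);
#'   `0` keeps every crossing.
#' @return list with tibbles `stable` and `unstable` (columns `angle_deg`,
#'   `slope` = dG/dtheta per radian, and for stable points `prominence`).
#' @export
fixed_points <- function(field, prominence_quantile = 0.2) {
  stopifnot(inherits(field, "wm_drift"),
            prominence_quantile >= 0, prominence_quantile < 1)
  g <- field$values
  n <- length(g)
  centers <- field$grid$centers
  delta <- field$grid$delta
  empty <- tibble::tibble(angle_deg = numeric(), slope = numeric())
  if (all(g == 0)) return(list(stable = cbind(empty, prominence = numeric()),
                               unstable = empty))

  g_next <- g[c(2:n, 1)]
  cross <- which(g * g_next < 0 | (g == 0 & g_next != 0))
  if (!length(cross)) {
    return(list(stable = cbind(empty, prominence = numeric()),
                unstable = empty))
  }
  # linear interpolation of the root within [center_i, center_i + delta]
  frac <- ifelse(g[cross] == 0, 0, g[cross] / (g[cross] - g_next[cross]))
  angle <- wrap_rad(centers[cross] + frac * delta)
  slope <- (g_next[cross] - g[cross]) / delta
  stable_mask <- slope < 0

  # prominence of each stable point: peak height of the cumulative integral
  # of G relative to the larger neighboring trough (circular)
  U <- cumsum(g) * delta       # integral of G along the circle
  ord <- order(angle)
  angle <- angle[ord]; slope <- slope[ord]; stable_mask <- stable_mask[ord]
  u_at <- function(a) {
    interp_circular(U, a, field$grid)
  }
  u_vals <- u_at(angle)
  k <- length(angle)
  prom <- rep(NA_real_, k)
  for (i in which(stable_mask)) {
    lo <- if (i == 1) k else i - 1
    hi <- if (i == k) 1 else i + 1
    neighbors <- u_vals[c(lo, hi)]
    prom[i] <- u_vals[i] - max(neighbors)
  }
  keep <- rep(TRUE, k)
  sp <- prom[stable_mask]
  if (sum(stable_mask) > 1 && prominence_quantile > 0) {
    cutoff <- stats::quantile(sp, prominence_quantile, names = FALSE)
    # strictly below the cutoff, with a tolerance so exactly tied
    # prominences (symmetric fields) are never dropped
    weak <- which(stable_mask)[sp < cutoff - 1e-9 * (abs(cutoff) + 1)]
    # never drop every stable point
    if (length(weak) < sum(stable_mask)) {
      keep[weak] <- FALSE
      # drop one flanking unstable point per removed stable point to keep
      # the alternation invariant
      for (i in weak) {
        nb <- c(if (i == 1) k else i - 1, if (i == k) 1 else i + 1)
        nb <- nb[keep[nb] & !stable_mask[nb]]
        if (length(nb)) keep[nb[1]] <- FALSE
      }
    }
  }
  angle <- angle[keep]; slope <- slope[keep]
  stable_mask <- stable_mask[keep]; prom <- prom[keep]
  list(
    stable = tibble::tibble(angle_deg = rad2deg(angle[stable_mask]),
                            slope = slope[stable_mask],
                            prominence = prom[stable_mask]),
    unstable = tibble::tibble(angle_deg = rad2deg(angle[!stable_mask]),
                              slope = slope[!stable_mask])
  )
}

#' Least-squares basis fit to a target drift profile
#'
#' Projects an arbitrary drift profile (sampled at the grid centers) onto
#' the basis by ordinary least squares and returns the re-normalized field.
#' This is how a representative drift function is constructed from the
#' numerical derivative of a response density: attractors land at the modes
#' of the density.
#'
#' @param profile numeric vector of drift values at the grid centers.
#' @param basis a [drift_basis()].
#' @return a [wm_drift()] field (max|G| = 1 unless the profile is flat).
#' @export
fit_drift_profile <- function(profile, basis = drift_basis()) {
  stopifnot(inherits(basis, "wm_basis"))
  if (length(profile) != basis$grid$n_bins || any(!is.finite(profile))) {
    stop("profile must be finite with one value per grid bin", call. = FALSE)
  }
  if (max(abs(profile - mean(profile))) < 1e-12) {
    if (any(profile != 0)) {
      warning("constant drift profile: returning the zero field")
    }
    return(drift_field(rep(0, basis$n_basis), basis))
  }
  w <- stats::lsfit(basis$B, profile, intercept = FALSE)$coefficients
  drift_field(unname(w), basis)
}

#' Export or import a drift field as a two-column table
#'
#' @param field a [wm_drift()] field.
#' @return a tibble with `angle_deg` and `G`.
#' @export
drift_table <- function(field) {
  tibble::tibble(angle_deg = rad2deg(field$grid$centers), G = field$values)
}
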