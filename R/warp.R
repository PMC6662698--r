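#' Nonlinear mapping between a circular stimulus space and a square
#' perceptual space
#'
#' Control model for clustering without attractors: stimulus angles live
#' on a circle, but the hypothetical true perceptual space is the
#' perimeter of a unit square centered on the circle's center. The maps
#' are radial projections: a ray at the stimulus angle meets the square's
#' boundary, and the perceptual coordinate is the arc length along the
#' perimeter from the point where the zero-angle ray lands. The two maps
#' are exact inverses and preserve angular order.
#'
#' @param angle angles in radians, `[0, 2 pi)`.
#' @param half_side half the square's side (default 0.5, the unit square).
#' @return `circle_to_square()`: perimeter arc length in
#'   `[0, 8 * half_side)`; `square_to_circle()`: angles in `[0, 2 pi)`.
#' @export
circle_to_square <- function(angle, half_side = 0.5) {
  a <- wrap_rad(angle)
  # boundary point of the ray at angle a
  scale <- half_side / pmax(abs(cos(a)), abs(sin(a)))
  x <- scale * cos(a)
  y <- scale * sin(a)
  # arc length clockwise from (half_side, 0), i.e. counterclockwise along
  # increasing angle: right edge up, top edge leftward, left edge down,
  # bottom edge rightward
  s <- half_side
  out <- numeric(length(a))
  on_right <- abs(x - s) < 1e-12
  on_top <- abs(y - s) < 1e-12 & !on_right
  on_left <- abs(x + s) < 1e-12 & !on_right & !on_top
  on_bottom <- !(on_right | on_top | on_left)
  out[on_right] <- ifelse(y[on_right] >= 0, y[on_right],
                          8 * s + y[on_right])
  out[on_top] <- s + (s - x[on_top])
  out[on_left] <- 3 * s + (s - y[on_left])
  out[on_bottom] <- 5 * s + (x[on_bottom] + s)
  out %% (8 * s)
}

#' @rdname circle_to_square
#' @param coord perimeter arc length in `[0, 8 * half_side)`.
#' @export
square_to_circle <- function(coord, half_side = 0.5) {
  s <- half_side
  u <- coord %% (8 * s)
  x <- numeric(length(u)); y <- numeric(length(u))
  seg <- findInterval(u, c(0, s, 3 * s, 5 * s, 7 * s))
  # segment 1: right edge upward from (s, 0); 2: top right-to-left;
  # 3: left downward; 4: bottom left-to-right; 5: right edge from (s,-s) up
  i <- seg == 1; x[i] <- s; y[i] <- u[i]
  i <- seg == 2; x[i] <- s - (u[i] - s); y[i] <- s
  i <- seg == 3; x[i] <- -s; y[i] <- s - (u[i] - 3 * s)
  i <- seg == 4; x[i] <- -s + (u[i] - 5 * s); y[i] <- -s
  i <- seg == 5; x[i] <- s; y[i] <- -s + (u[i] - 7 * s)
  wrap_rad(atan2(y, x))
}

#' Simulate the perceptual-warp control model
#'
#' Targets are drawn uniformly on the stimulus circle, projected onto the
#' discretized square perimeter (encoding), diffused for `n_steps`
#' timesteps of a uniform-integer random walk (each step between
#' `-step_max` and `+step_max` perimeter points, wrapping around), and
#' projected back to stimulus angles (report). Because the walk is on a
#' cyclic lattice, the total displacement after `n_steps` steps is sampled
#' from the exact n-step distribution (the step distribution convolved
#' `n_steps` times via FFT on the cyclic group), which is equal in
#' distribution to stepping one at a time.
#'
#' This model produces clustered reports (density piles up where the
#' square-to-circle map compresses the perimeter) but no attractive bias
#' at the cluster peaks, the qualitative signature that distinguishes it
#' from attractor dynamics.
#'
#' @param n_angles number of simulated targets (default 100,000).
#' @param n_steps diffusion timesteps (default 1,000).
#' @param step_max maximum step size in perimeter points (default 4).
#' @param n_points perimeter discretization (default 1,024).
#' @param seed integer seed.
#' @param half_side square half-side (default 0.5).
#' @return a trial table (load 1, `delay_s` coding `n_steps`) with
#'   `target_deg` and `report_deg`.
#' @export
simulate_warp <- function(n_angles = 100000, n_steps = 1000, step_max = 4,
                          n_points = 1024, seed = 1, half_side = 0.5) {
  stopifnot(n_angles > 0, n_steps > 0, step_max >= 0,
            step_max < n_points / 2)
  set.seed(seed)
  target <- stats::runif(n_angles, 0, 2 * pi)
  per <- 8 * half_side
  coord <- circle_to_square(target, half_side)
  pos <- round(coord / per * n_points) %% n_points
  if (step_max > 0) {
    # exact n-step displacement pmf on Z_{n_points} via FFT convolution
    step_pmf <- numeric(n_points)
    steps <- -step_max:step_max
    step_pmf[(steps %% n_points) + 1] <- 1 / length(steps)
    disp_pmf <- Re(stats::fft(stats::fft(step_pmf)^n_steps, inverse = TRUE)) /
      n_points
    disp_pmf <- pmax(disp_pmf, 0)
    disp_pmf <- disp_pmf / sum(disp_pmf)
    disp <- sample.int(n_points, n_angles, replace = TRUE,
                       prob = disp_pmf) - 1L
    pos <- (pos + disp) %% n_points
  }
  report <- square_to_circle(pos / n_points * per, half_side)
  as_trials(tibble::tibble(
    subject = "warp", load = 1, delay_s = n_steps,
    target_deg = wrap_deg(rad2deg(target)),
    report_deg = wrap_deg(rad2deg(report)),
    trial_index = seq_len(n_angles)))
}
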