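#' Task design for the synthetic generator
#'
#' Describes a delayed-estimation experiment: trial counts per load, the
#' delay levels, the target environment (uniform, or biased with four
#' 20-degree-wide clusters of common colors drawn with 50% probability and
#' a random phase), the minimum same-trial color separation (22 degrees),
#' and the species flag (controls whether the decoding-noise term applies).
#'
#' @param loads integer vector of loads presented.
#' @param n_per_load trials per load (recycled against `loads`).
#' @param delays_s delay levels in seconds, or a length-2 range from which
#'   delays are drawn uniformly when `continuous_delay = TRUE`.
#' @param environment `"uniform"` or `"biased"`.
#' @param n_clusters,cluster_width_deg,biased_fraction biased-environment
#'   shape: equally spaced clusters of common colors (defaults 4 clusters,
#'   20 degrees wide, half of draws).
#' @param cluster_phase_deg first cluster center; `NULL` draws a random
#'   phase at sampling time.
#' @param min_separation_deg minimum pairwise same-trial separation.
#' @param species `"human"` or `"monkey"`.
#' @param continuous_delay draw delays uniformly from `range(delays_s)`.
#' @return a list of class `wm_design`.
#' @export
task_design <- function(loads = c(1, 3), n_per_load = 100,
                        delays_s = c(1, 7),
                        environment = c("uniform", "biased"),
                        n_clusters = 4, cluster_width_deg = 20,
                        biased_fraction = 0.5, cluster_phase_deg = NULL,
                        min_separation_deg = 22,
                        species = c("human", "monkey"),
                        continuous_delay = FALSE) {
  environment <- match.arg(environment)
  species <- match.arg(species)
  stopifnot(all(loads %in% 1:3), all(delays_s > 0),
            cluster_width_deg <= 360 / n_clusters,
            biased_fraction >= 0, biased_fraction <= 1,
            min_separation_deg >= 0)
  if (max(loads) > 1 && min_separation_deg * max(loads) > 350) {
    stop("separation constraint unsatisfiable at this load", call. = FALSE)
  }
  structure(list(loads = as.integer(loads),
                 n_per_load = rep_len(n_per_load, length(loads)),
                 delays_s = delays_s, environment = environment,
                 n_clusters = n_clusters,
                 cluster_width_deg = cluster_width_deg,
                 biased_fraction = biased_fraction,
                 cluster_phase_deg = cluster_phase_deg,
                 min_separation_deg = min_separation_deg,
                 species = species, continuous_delay = continuous_delay),
            class = "wm_design")
}

# draw one color from the design's environment
draw_colors <- function(design, n, phase) {
  if (design$environment == "uniform") return(stats::runif(n, 0, 360))
  biased <- stats::runif(n) < design$biased_fraction
  out <- stats::runif(n, 0, 360)
  nb <- sum(biased)
  if (nb) {
    centers <- wrap_deg(phase + 360 * (seq_len(design$n_clusters) - 1) /
                          design$n_clusters)
    pick <- sample.int(design$n_clusters, nb, replace = TRUE)
    out[biased] <- wrap_deg(centers[pick] +
      stats::runif(nb, -design$cluster_width_deg / 2,
                   design$cluster_width_deg / 2))
  }
  out
}

#' Sample per-trial target and non-target colors
#'
#' Colors on the same trial are drawn independently from the environment
#' and re-drawn (rejection sampling) until all pairwise circular distances
#' are at least `min_separation_deg`.
#'
#' @param design a [task_design()].
#' @param seed integer seed.
#' @return a tibble with `load`, `delay_s`, `target_deg`,
#'   `nontarget1_deg`, `nontarget2_deg`, `trial_index`, plus the cluster
#'   phase used as attribute `"cluster_phase_deg"`.
#' @export
sample_targets <- function(design, seed = 1) {
  stopifnot(inherits(design, "wm_design"))
  set.seed(seed)
  phase <- design$cluster_phase_deg %||% stats::runif(1, 0, 360)
  rows <- list()
  for (li in seq_along(design$loads)) {
    L <- design$loads[li]
    n <- design$n_per_load[li]
    cols <- matrix(NA_real_, n, 3)
    for (item in seq_len(L)) cols[, item] <- draw_colors(design, n, phase)
    if (L > 1 && design$min_separation_deg > 0) {
      repeat {
        d12 <- abs(circ_error(cols[, 1], cols[, 2]))
        bad <- d12 < design$min_separation_deg
        if (L == 3) {
          d13 <- abs(circ_error(cols[, 1], cols[, 3]))
          d23 <- abs(circ_error(cols[, 2], cols[, 3]))
          bad <- bad | d13 < design$min_separation_deg |
            d23 < design$min_separation_deg
        }
        if (!any(bad)) break
        for (item in seq_len(L)) {
          cols[bad, item] <- draw_colors(design, sum(bad), phase)
        }
      }
    }
    delays <- if (design$continuous_delay) {
      stats::runif(n, min(design$delays_s), max(design$delays_s))
    } else {
      sample(design$delays_s, n, replace = TRUE)
    }
    rows[[li]] <- tibble::tibble(
      load = L, delay_s = delays, target_deg = cols[, 1],
      nontarget1_deg = if (L >= 2) cols[, 2] else NA_real_,
      nontarget2_deg = if (L >= 3) cols[, 3] else NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  out$trial_index <- seq_len(nrow(out))
  attr(out, "cluster_phase_deg") <- phase
  out
}

#' Ground truth for simulation
#'
#' Bundles a drift field, dynamics, mixture parameters and a seed into a
#' frozen record that both the simulator and the normative analyses
#' consume. `wm_truth_default()` builds the package's representative
#' ground truth: a four-attractor drift field obtained by projecting the
#' derivative of a four-mode response density onto the basis, with
#' load-dependent gains in which drift and diffusion both increase with
#' load and encoding dynamics are stronger than memory dynamics.
#'
#' @param field a [drift_field()].
#' @param dyn a [dynamics_params()].
#' @param mix a [mixture_params()].
#' @param seed master seed recorded with the truth.
#' @return a list of class `wm_truth`.
#' @export
wm_truth <- function(field, dyn, mix, seed = 1) {
  stopifnot(inherits(field, "wm_drift"), inherits(dyn, "wm_dynamics"),
            inherits(mix, "wm_mixture"))
  structure(list(field = field, dyn = dyn, mix = mix, seed = seed),
            class = "wm_truth")
}

#' @rdname wm_truth
#' @param attractors_deg stable fixed-point locations for the default
#'   truth (default four, 90 degrees apart).
#' @param mode_sd_deg width of the response modes used to build the field.
#' @param grid state-space grid.
#' @param species `"human"` adds decoding noise; `"monkey"` does not.
#' @export
wm_truth_default <- function(attractors_deg = c(45, 135, 225, 315),
                             mode_sd_deg = 20, grid = wm_grid(),
                             species = c("human", "monkey"), seed = 1) {
  species <- match.arg(species)
  basis <- drift_basis(12, grid)
  dens <- Reduce(`+`, lapply(deg2rad(attractors_deg), function(mu) {
    dvonmises_sd(grid$centers, mu, deg2rad(mode_sd_deg))
  })) / length(attractors_deg)
  field <- fit_drift_profile(numeric_deriv_circ(dens, grid$delta), basis)
  dyn <- dynamics_params(
    beta = c(`1` = 0.25, `2` = 0.4, `3` = 0.5),
    sigma = c(`1` = 0.25, `2` = 0.33, `3` = 0.4),
    beta_star = c(`1` = 0.8, `2` = 1.0, `3` = 1.2),
    sigma_star = c(`1` = 0.25, `2` = 0.3, `3` = 0.35))
  mix <- mixture_params(
    a_lambda = c(`1` = 0.008, `2` = 0.01, `3` = 0.012),
    b_lambda = c(`1` = 0.03, `2` = 0.04, `3` = 0.05),
    a_alpha = 0.004, b_alpha = 0.02,
    sigma_dec = if (species == "human") 0.1 else NULL)
  wm_truth(field, dyn, mix, seed = seed)
}

#' Simulate a dataset of reports from a ground truth
#'
#' Two generative routes are available. `"mixture"` samples each report
#' from the analytic per-trial report distribution (Fokker-Planck
#' propagation, with within-bin linear jitter so reports are continuous).
#' `"sde"` runs the underlying stochastic process per item: a von Mises
#' initialization (SD 0.1 rad), Euler-Maruyama encoding and delay
#' integration with step `dt`, then guess/swap lapses and decoding noise.
#' The two routes agree in distribution up to discretization error.
#'
#' @param truth a [wm_truth()].
#' @param design a [task_design()].
#' @param seed integer seed (defaults to the truth's).
#' @param mode `"mixture"` or `"sde"`.
#' @param dt Euler-Maruyama step, seconds (SDE mode).
#' @param subject subject label for the output table.
#' @return a validated trial table with `report_deg` filled in.
#' @export
simulate_trials <- function(truth, design, seed = NULL,
                            mode = c("mixture", "sde"), dt = 0.01,
                            subject = "sim") {
  stopifnot(inherits(truth, "wm_truth"), inherits(design, "wm_design"))
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  seed <- seed %||% truth$seed
  tt <- sample_targets(design, seed = seed)
  tt$subject <- subject
  set.seed(seed + 1)
  tt$report_deg <- if (mode == "mixture") {
    sim_reports_mixture(truth, tt)
  } else {
    sim_reports_sde(truth, tt, dt)
  }
  as_trials(tt)
}

# sample from the analytic report distribution, batched by condition
sim_reports_mixture <- function(truth, tt) {
  grid <- truth$field$grid
  n <- nrow(tt)
  out <- numeric(n)
  dec <- if (!is.null(truth$mix$sigma_dec))
    decoding_kernel(grid, truth$mix$sigma_dec)
  conds <- dplyr::distinct(tt, .data$load, .data$delay_s)
  for (ci in seq_len(nrow(conds))) {
    L <- conds$load[ci]; t <- conds$delay_s[ci]
    key <- as.character(L)
    rows <- which(tt$load == L & tt$delay_s == t)
    K <- propagator(generator_matrix(truth$field, truth$dyn$beta[[key]],
                                     truth$dyn$sigma[[key]]), t) %*%
      propagator(generator_matrix(truth$field, truth$dyn$beta_star[[key]],
                                  truth$dyn$sigma_star[[key]]),
                 truth$dyn$encode_duration)
    if (!is.null(dec)) K <- dec %*% K
    rates <- mixture_rates(truth$mix, L, t)
    lam <- rates[["lambda"]]; alp <- rates[["alpha"]]
    D <- K %*% init_density_matrix(grid, deg2rad(tt$target_deg[rows]))
    D <- (1 - lam - alp) * D + lam / (2 * pi)
    if (L > 1 && alp > 0) {
      m <- L - 1
      D <- D + (alp / m) * (K %*% init_density_matrix(
        grid, deg2rad(tt$nontarget1_deg[rows])))
      if (m == 2) {
        D <- D + (alp / m) * (K %*% init_density_matrix(
          grid, deg2rad(tt$nontarget2_deg[rows])))
      }
    }
    out[rows] <- sample_columns(D, grid)
  }
  out
}

# sample one angle per column of a density matrix, with within-bin jitter
sample_columns <- function(D, grid) {
  w <- sweep(D, 2, colSums(D), `/`)
  cum <- apply(w, 2, cumsum)
  u <- stats::runif(ncol(D))
  idx <- colSums(cum < rep(u, each = nrow(D))) + 1L
  idx[idx > grid$n_bins] <- grid$n_bins
  jitter <- stats::runif(ncol(D), -0.5, 0.5) * grid$delta
  wrap_deg(rad2deg(grid$centers[idx] + jitter))
}

# per-item Euler-Maruyama path simulation
sim_reports_sde <- function(truth, tt, dt) {
  grid <- truth$field$grid
  n <- nrow(tt)
  evolve <- function(theta, beta, sigma, duration) {
    steps <- max(1L, round(duration / dt))
    h <- duration / steps
    for (s in seq_len(steps)) {
      g <- drift_at(truth$field, theta)
      theta <- wrap_rad(theta + beta * g * h +
                          sigma * sqrt(h) * stats::rnorm(length(theta)))
    }
    theta
  }
  run_items <- function(ang_deg, load, delay) {
    key <- as.character(load[1])
    th <- rvonmises_sd(length(ang_deg), 0, 0.1)  # encode noise around item
    th <- wrap_rad(th + deg2rad(ang_deg))
    th <- evolve(th, truth$dyn$beta_star[[key]], truth$dyn$sigma_star[[key]],
                 truth$dyn$encode_duration)
    # delay durations vary per trial: group identical delays
    out <- numeric(length(th))
    for (d in unique(delay)) {
      sel <- delay == d
      out[sel] <- evolve(th[sel], truth$dyn$beta[[key]],
                         truth$dyn$sigma[[key]], d)
    }
    out
  }
  report <- numeric(n)
  for (L in unique(tt$load)) {
    rows <- which(tt$load == L)
    mem_t <- run_items(tt$target_deg[rows], tt$load[rows], tt$delay_s[rows])
    mem_n1 <- if (L >= 2) run_items(tt$nontarget1_deg[rows], tt$load[rows],
                                    tt$delay_s[rows])
    mem_n2 <- if (L >= 3) run_items(tt$nontarget2_deg[rows], tt$load[rows],
                                    tt$delay_s[rows])
    rates <- t(vapply(rows, function(i) {
      mixture_rates(truth$mix, tt$load[i], tt$delay_s[i])
    }, numeric(2)))
    u <- stats::runif(length(rows))
    th <- mem_t
    is_guess <- u < rates[, 1]
    is_swap <- !is_guess & u < rates[, 1] + rates[, 2]
    if (any(is_swap)) {
      pick1 <- L == 2 | stats::runif(length(rows)) < 0.5
      th[is_swap & pick1] <- mem_n1[is_swap & pick1]
      if (L >= 3) th[is_swap & !pick1] <- mem_n2[is_swap & !pick1]
    }
    th[is_guess] <- stats::runif(sum(is_guess), 0, 2 * pi)
    if (!is.null(truth$mix$sigma_dec)) {
      noise <- rvonmises_sd(length(rows), 0, truth$mix$sigma_dec)
      th <- wrap_rad(th + noise)
    }
    report[rows] <- rad2deg(th)
  }
  wrap_deg(report)
}

#' Expected absolute memory error over time
#'
#' Quadrature (no sampling): for each target in the environment the
#' item's density is encoded, propagated to each time in `t_grid`, and its
#' expected absolute circular error computed; the curve is the
#' environment-weighted average. Guess and swap probabilities are set to
#' zero so the curve isolates the memory of the target. The
#' diffusion-only counterpart (`include_drift = FALSE`) zeroes the drift
#' gains during both encoding and memory.
#'
#' @param truth a [wm_truth()].
#' @param t_grid increasing vector of delay times, seconds.
#' @param load which load's parameters to use (default the highest).
#' @param bias_fraction fraction of targets drawn from within
#'   `bias_width_deg` of the attractors (0 = uniform environment).
#' @param bias_width_deg half-width of the biased bands (default 10).
#' @param include_drift keep drift on (`TRUE`) or zero it (`FALSE`).
#' @param n_targets number of evenly spaced targets used for the
#'   environment average.
#' @return a tibble with `t_s` and `mean_abs_error_deg`.
#' @export
error_over_time <- function(truth, t_grid, load = NULL, bias_fraction = 0,
                            bias_width_deg = 10, include_drift = TRUE,
                            n_targets = 60) {
  stopifnot(inherits(truth, "wm_truth"), all(diff(t_grid) > 0) || length(t_grid) == 1,
            bias_fraction >= 0, bias_fraction <= 1)
  grid <- truth$field$grid
  key <- as.character(load %||% max(as.integer(names(truth$dyn$beta))))
  beta <- if (include_drift) truth$dyn$beta[[key]] else 0
  beta_star <- if (include_drift) truth$dyn$beta_star[[key]] else 0
  targets <- 2 * pi * (seq_len(n_targets) - 0.5) / n_targets
  wts <- environment_weights(targets, truth$field, bias_fraction,
                             deg2rad(bias_width_deg))
  enc_K <- propagator(generator_matrix(truth$field, beta_star,
                                       truth$dyn$sigma_star[[key]]),
                      truth$dyn$encode_duration)
  gen <- generator_matrix(truth$field, beta, truth$dyn$sigma[[key]])
  P_enc <- enc_K %*% init_density_matrix(grid, targets)
  err_rows <- vapply(targets, function(th) {
    abs(circ_error_rad(grid$centers, th))
  }, numeric(grid$n_bins))  # n_bins x n_targets
  out <- numeric(length(t_grid))
  prev_t <- 0
  P <- P_enc
  for (i in seq_along(t_grid)) {
    dt_step <- t_grid[i] - prev_t
    if (dt_step > 0) P <- propagator(gen, dt_step) %*% P
    prev_t <- t_grid[i]
    per_target <- colSums(err_rows * P) * grid$delta
    out[i] <- rad2deg(sum(per_target * wts))
  }
  tibble::tibble(t_s = t_grid, mean_abs_error_deg = out)
}

# environment weights over a set of targets: mixture of uniform and a
# distribution uniform within +-width of the attractors
environment_weights <- function(targets, field, bias_fraction, width_rad) {
  n <- length(targets)
  w_unif <- rep(1 / n, n)
  if (bias_fraction == 0) return(w_unif)
  att <- deg2rad(fixed_points(field)$stable$angle_deg)
  if (!length(att)) return(w_unif)
  near <- vapply(targets, function(th) {
    any(abs(circ_error_rad(th, att)) <= width_rad)
  }, logical(1))
  if (!any(near)) return(w_unif)
  w_bias <- ifelse(near, 1 / sum(near), 0)
  w <- (1 - bias_fraction) * w_unif + bias_fraction * w_bias
  w / sum(w)
}

#' Relative error of diffusion-only vs full dynamics across environments
#'
#' Percent increase in expected absolute error of the diffusion-only model
#' over the full drift + diffusion model, `100 (err_diff - err_full) /
#' err_full`, on a grid of times by environment bias fractions. Positive
#' entries mean attractors reduce memory error. The diffusion-only error
#' does not depend on the environment bias and is computed once.
#'
#' @inheritParams error_over_time
#' @param bias_fractions vector in `[0, 1]`; row 0 is the uniform
#'   environment.
#' @return a tibble with `bias_fraction`, `t_s`, `pct_error_increase`.
#' @export
error_heatmap <- function(truth, t_grid, bias_fractions = seq(0, 1, 0.25),
                          load = NULL, bias_width_deg = 10, n_targets = 60) {
  diff_only <- error_over_time(truth, t_grid, load = load,
                               include_drift = FALSE, n_targets = n_targets)
  purrr::map_dfr(bias_fractions, function(bf) {
    full <- error_over_time(truth, t_grid, load = load, bias_fraction = bf,
                            bias_width_deg = bias_width_deg,
                            n_targets = n_targets)
    tibble::tibble(
      bias_fraction = bf, t_s = t_grid,
      pct_error_increase = 100 * (diff_only$mean_abs_error_deg -
                                    full$mean_abs_error_deg) /
        full$mean_abs_error_deg)
  })
}

#' Graded juice reward schedule
#'
#' The monkey reward schedule: drops follow a von Mises profile over
#' response error, centered at zero with circular SD 22 degrees, scaled to
#' a peak of 12 drops with non-integer values rounded up; errors beyond
#' 60 degrees earn nothing.
#'
#' @param error_deg response error(s) in degrees (signed or absolute).
#' @return integer drops of juice.
#' @examples
#' juice_reward(0)   # 12
#' juice_reward(61)  # 0
#' @export
juice_reward <- function(error_deg) {
  e <- abs(circ_error(error_deg, 0))
  sd_rad <- deg2rad(22)
  rel <- exp((cos(deg2rad(e)) - 1) / sd_rad^2)  # vm(e)/vm(0)
  drops <- ceiling(12 * rel)
  drops[e > 60] <- 0L
  as.integer(drops)
}
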