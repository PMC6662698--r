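#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted dynamical model
#'
#' One row per free parameter with its bound constraints, broom style.
#'
#' @param x a [fit_wm()] result.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `lower`, `upper`, `load`.
#' @export
tidy.wm_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    lower = x$spec$lower,
    upper = x$spec$upper,
    load = x$spec$load)
}

#' @rdname tidy.wm_fit
#' @details `glance()` returns the one-row model summary: log-likelihood,
#'   AIC/BIC, parameter and trial counts, and optimizer diagnostics.
#' @export
glance.wm_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant$label,
    logLik = x$logLik, AIC = x$AIC, BIC = x$BIC,
    n_params = x$n_params, n_trials = x$n_trials,
    n_starts = nrow(x$diagnostics),
    n_converged = sum(x$diagnostics$convergence == 0),
    best_start = x$best_start, seed = x$seed)
}

#' Tidy a screening mixture fit
#' @param x a [fit_guess_mixture()] result.
#' @param ... unused.
#' @return one-row tibble of mixture probabilities and precision.
#' @export
tidy.wm_mixfit <- function(x, ...) {
  tibble::tibble(p_target = x$p_target, p_guess = x$p_guess,
                 p_swap = x$p_swap, kappa = x$kappa, sd_deg = x$sd_deg,
                 converged = x$converged, verdict = x$verdict)
}

#' Plot a drift field
#'
#' Drift rate (at unit gain) across color space, with stable fixed points
#' (attractors) and unstable fixed points marked.
#'
#' @param object a [drift_field()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_drift <- function(object, ...) {
  df <- drift_table(object)
  fp <- fixed_points(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$G)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "color (deg)", y = "drift G (max-normalized)") +
    ggplot2::theme_minimal()
  if (nrow(fp$stable)) {
    p <- p + ggplot2::geom_vline(xintercept = fp$stable$angle_deg,
                                 colour = "firebrick", linetype = 2)
  }
  if (nrow(fp$unstable)) {
    p <- p + ggplot2::geom_vline(xintercept = fp$unstable$angle_deg,
                                 colour = "steelblue", linetype = 2)
  }
  p
}

#' Plot a probability field
#' @param object a [wm_pfield()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_pfield <- function(object, ...) {
  df <- tibble::tibble(angle_deg = rad2deg(object$grid$centers),
                       density = object$values * pi / 180)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "color (deg)", y = "density (per deg)") +
    ggplot2::theme_minimal()
}

#' Plot a bias/precision profile
#'
#' Bias (top) and circular SD (bottom) of reports as a function of target
#' color, with anchor positions marked.
#'
#' @param object a [bias_profile()] result.
#' @param ... unused.
#' @return a ggplot object (bias panel; use `$profile` for custom plots).
#' @export
autoplot.wm_bias_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$profile,
                            cols = c("bias_deg", "sd_deg"),
                            names_to = "measure", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_deg,
                                        y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "target color (deg)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$anchors)) {
    p <- p + ggplot2::geom_vline(xintercept = object$anchors$anchor_deg,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot error-over-time curves
#'
#' Convenience wrapper for comparing the full and diffusion-only models'
#' expected absolute error curves.
#'
#' @param truth a [wm_truth()].
#' @param t_grid times in seconds.
#' @param bias_fraction environment bias fraction.
#' @param ... passed to [error_over_time()].
#' @return a ggplot object.
#' @export
plot_error_over_time <- function(truth, t_grid, bias_fraction = 0, ...) {
  full <- error_over_time(truth, t_grid, bias_fraction = bias_fraction, ...)
  diff_only <- error_over_time(truth, t_grid, include_drift = FALSE, ...)
  df <- dplyr::bind_rows(
    dplyr::mutate(full, model = "drift + diffusion"),
    dplyr::mutate(diff_only, model = "diffusion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s,
                                   y = .data$mean_abs_error_deg,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time in memory (s)", y = "mean |error| (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
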