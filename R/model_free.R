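#' Circular kernel density estimate
#'
#' Von Mises kernel density with a kernel expressed by its circular SD
#' (default 10 degrees, the convention used for every density estimate in
#' the package). The estimate is evaluated at the centers of `grid` and is
#' normalized to integrate to 1 over the circle (density per radian).
#'
#' @param x angles in radians.
#' @param sd kernel circular SD, radians (default 10 degrees).
#' @param grid evaluation grid; default 360 evenly spaced points.
#' @return numeric vector of densities per radian at the grid centers.
#' @export
circ_kde <- function(x, sd = deg2rad(10), grid = wm_grid(360)) {
  stopifnot(length(x) >= 1, sd > 0, is_wm_grid(grid))
  kappa <- 1 / sd^2
  # sum of kernels via trigonometric identity:
  # sum_i exp(kappa cos(theta - x_i)) =
  #   exp evaluated through C = sum cos(k x), but kappa is large so do the
  #   direct (n_grid x chunk) computation in blocks to bound memory
  n <- length(x)
  dens <- numeric(grid$n_bins)
  block <- max(1L, floor(2e6 / grid$n_bins))
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    dens <- dens + rowSums(exp(kappa * (cos(outer(grid$centers, x[i:j], `-`)) - 1)))
    i <- j + 1L
  }
  dens / (sum(dens) * grid$delta)
}

#' Discrete entropy of a circular density in bits
#'
#' `H = -sum f log2(f) dtheta` over the estimation grid with densities per
#' radian; for a uniform circular density this equals `log2(2 pi)`, about
#' 2.65 bits.
#'
#' @param f densities per radian on `grid`.
#' @param grid the evaluation grid.
#' @return entropy in bits.
#' @export
circ_entropy_bits <- function(f, grid = wm_grid(360)) {
  stopifnot(length(f) == grid$n_bins, all(f >= 0))
  nz <- f > 0
  -sum(f[nz] * log2(f[nz])) * grid$delta
}

#' Screening mixture model for guess rate
#'
#' Fits the standard three-component mixture of continuous-report errors —
#' a von Mises component at the target, a uniform guessing component, and
#' (when non-targets are present) von Mises components at the non-targets —
#' by expectation-maximization, and issues the screening verdict used to
#' exclude disengaged subjects: estimated guess rate above `threshold`
#' (default 20%).
#'
#' @param trials a trial table with at least 50 trials.
#' @param threshold guess-rate exclusion cutoff (default 0.20).
#' @param max_iter,tol EM controls.
#' @return a list of class `wm_mixfit`: `p_target`, `p_guess`, `p_swap`,
#'   `kappa`, `sd_deg` (memory-component circular SD), `converged`,
#'   `verdict` (`"keep"`/`"exclude"`, or NA if not converged).
#' @export
fit_guess_mixture <- function(trials, threshold = 0.20, max_iter = 500,
                              tol = 1e-8) {
  trials <- as_trials(trials)
  if (nrow(trials) < 50) stop("need at least 50 trials to screen", call. = FALSE)
  err <- deg2rad(circ_error(trials$report_deg, trials$target_deg))
  err_na <- function(a, b) {
    d <- (a - b) %% 360
    deg2rad(ifelse(d > 180, d - 360, d))
  }
  nt_err <- cbind(err_na(trials$report_deg, trials$nontarget1_deg),
                  err_na(trials$report_deg, trials$nontarget2_deg))
  has_nt <- rowSums(!is.na(nt_err)) > 0
  use_swap <- any(has_nt)
  n <- length(err)

  p_t <- 0.7; p_g <- 0.2; p_s <- if (use_swap) 0.1 else 0
  kappa <- 8
  dvm <- function(x, k) exp(k * cos(x)) / (2 * pi * besselI(k, 0, TRUE) * exp(k)) * exp(k)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_t <- exp(kappa * (cos(err) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
    f_g <- rep(1 / (2 * pi), n)
    f_s <- rep(0, n)
    if (use_swap) {
      cnt <- rowSums(!is.na(nt_err))
      fs <- exp(kappa * (cos(nt_err) - 1)) /
        (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
      fs[is.na(fs)] <- 0
      f_s[cnt > 0] <- rowSums(fs, na.rm = TRUE)[cnt > 0] / cnt[cnt > 0]
    }
    num_t <- p_t * f_t; num_g <- p_g * f_g; num_s <- p_s * f_s
    tot <- num_t + num_g + num_s
    ll <- sum(log(tot))
    r_t <- num_t / tot; r_g <- num_g / tot; r_s <- num_s / tot
    p_t <- mean(r_t); p_g <- mean(r_g); p_s <- mean(r_s)
    # M-step for kappa: resultant of target-component responsibilities
    # (swap-component deviations pooled in, same concentration)
    wsum <- sum(r_t)
    csum <- sum(r_t * cos(err))
    if (use_swap) {
      w_nt <- r_s / pmax(rowSums(!is.na(nt_err)), 1)
      csum <- csum + sum(w_nt * cos(nt_err[, 1]), na.rm = TRUE) +
        sum(w_nt * cos(nt_err[, 2]), na.rm = TRUE)
      wsum <- wsum + sum(r_s)
    }
    Rbar <- min(max(csum / wsum, 1e-6), 1 - 1e-9)
    kappa <- a1inv(Rbar)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
    ll_old <- ll
  }
  verdict <- if (!converged) NA_character_
             else if (p_g > threshold) "exclude" else "keep"
  structure(list(p_target = p_t, p_guess = p_g, p_swap = p_s,
                 kappa = kappa, sd_deg = rad2deg(1 / sqrt(kappa)),
                 logLik = ll, converged = converged, verdict = verdict,
                 threshold = threshold, n_iter = it),
            class = "wm_mixfit")
}

#' @export
print.wm_mixfit <- function(x, ...) {
  cat(sprintf("<wm_mixfit> p_target %.3f | p_guess %.3f | p_swap %.3f | sd %.1f deg (%s)\n",
              x$p_target, x$p_guess, x$p_swap, x$sd_deg,
              if (is.na(x$verdict)) "not converged" else x$verdict))
  invisible(x)
}

# inverse of A1(kappa) = I1/I0 (Banerjee approximation, then 2 Newton steps)
a1inv <- function(R) {
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  for (i in 1:2) {
    A <- besselI(k, 1, TRUE) / besselI(k, 0, TRUE)
    dA <- 1 - A^2 - A / k
    k <- max(k - (A - R) / dA, 1e-6)
  }
  min(k, 1e4)
}

#' Entropy-based clustering metric
#'
#' Quantifies clustering of reports relative to targets as the entropy
#' difference `C = H(reports) - H(targets)` in bits; negative `C` means
#' reports pile up at preferred colors. Both densities are estimated by
#' circular KDE (10-degree kernel) on a 360-point grid with densities per
#' radian. A uniform component of area `guess_rate` is subtracted from both
#' densities (floored at zero) and each is renormalized, removing the
#' entropy inflation caused by random guessing. When `conditions` is given,
#' trials are subsampled (fixed seed) to an equal count per condition
#' before estimation, reducing the bias of the entropy estimate.
#'
#' @param data a data frame containing reports and targets.
#' @param reports,targets column names (tidy-select style strings) or
#'   numeric vectors of angles in degrees.
#' @param guess_rate uniform area to remove, in `[0, 1)`.
#' @param conditions optional factor (or column name) defining conditions
#'   for equal-count subsampling.
#' @param seed subsampling seed.
#' @return a tibble with `C_bits`, `H_resp_bits`, `H_targ_bits`,
#'   `guess_rate`, `n_used`.
#' @export
clustering_metric <- function(data = NULL, reports = "report_deg",
                              targets = "target_deg", guess_rate = 0,
                              conditions = NULL, seed = 1) {
  if (guess_rate < 0 || guess_rate >= 1) {
    stop("guess_rate must be in [0, 1)", call. = FALSE)
  }
  if (is.data.frame(data)) {
    rep_v <- data[[reports]]
    tar_v <- data[[targets]]
    cond_v <- if (is.character(conditions) && length(conditions) == 1)
      data[[conditions]] else conditions
  } else {
    rep_v <- reports; tar_v <- targets; cond_v <- conditions
  }
  stopifnot(length(rep_v) == length(tar_v))
  keep <- seq_along(rep_v)
  if (!is.null(cond_v)) {
    cond_v <- as.factor(cond_v)
    n_min <- min(table(cond_v))
    set.seed(seed)
    keep <- unlist(lapply(split(seq_along(rep_v), cond_v),
                          function(ix) sample(ix, n_min)))
  }
  g <- wm_grid(360)
  strip <- function(f) {
    f2 <- pmax(f - guess_rate / (2 * pi), 0)
    f2 / (sum(f2) * g$delta)
  }
  f_resp <- strip(circ_kde(deg2rad(rep_v[keep]), grid = g))
  f_targ <- strip(circ_kde(deg2rad(tar_v[keep]), grid = g))
  H_resp <- circ_entropy_bits(f_resp, g)
  H_targ <- circ_entropy_bits(f_targ, g)
  tibble::tibble(C_bits = H_resp - H_targ, H_resp_bits = H_resp,
                 H_targ_bits = H_targ, guess_rate = guess_rate,
                 n_used = length(keep))
}

#' Nonuniformity tests for circular reports
#'
#' Two complementary tests: the Hodges-Ajne omnibus test of the reports
#' against circular uniformity (count-based, closed form), and a
#' two-sample Kuiper statistic of reports against targets with a
#' permutation null (pooled relabeling), which asks whether the reports
#' are distributed like the targets.
#'
#' @param reports,targets angles in degrees.
#' @param n_perm permutation draws for the Kuiper null (warning below 100).
#' @param seed permutation seed.
#' @return tibble with `hodges_ajne_p`, `kuiper_stat`, `kuiper_perm_p`.
#' @export
test_nonuniformity <- function(reports, targets, n_perm = 1000, seed = 1) {
  stopifnot(length(reports) >= 10, length(targets) >= 10)
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  ha <- hodges_ajne_p(deg2rad(reports))
  v_obs <- kuiper_two(reports, targets)
  set.seed(seed)
  pooled <- c(reports, targets)
  n1 <- length(reports)
  v_null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), n1)
    kuiper_two(pooled[idx], pooled[-idx])
  }, numeric(1))
  p_k <- (1 + sum(v_null >= v_obs)) / (n_perm + 1)
  tibble::tibble(hodges_ajne_p = ha, kuiper_stat = v_obs, kuiper_perm_p = p_k)
}

# Hodges-Ajne test: m = minimal number of points in a closed half circle
hodges_ajne_p <- function(x) {
  n <- length(x)
  x <- sort(wrap_rad(x))
  # for each datum as half-plane boundary, count points in [x_i, x_i + pi)
  counts <- vapply(seq_len(n), function(i) {
    d <- wrap_rad(x - x[i])
    sum(d < pi - 1e-9)  # half-open half circle, tolerant of exact ties
  }, numeric(1))
  m <- min(n - counts, counts)
  # perfectly balanced data (every half circle holds n/2 points) are the
  # least extreme configuration possible
  if (n - 2 * m <= 0) return(1)
  A <- pi * sqrt(n) / (2 * (n - 2 * m))
  p <- if (n > 50) {
    sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  } else {
    2^(1 - n) * (n - 2 * m) * choose(n, m)
  }
  min(max(p, 0), 1)
}

# two-sample Kuiper statistic V = D+ + D- of the two empirical CDFs
kuiper_two <- function(a, b) {
  a <- sort(wrap_deg(a)); b <- sort(wrap_deg(b))
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, a) / length(a)
  Fb <- findInterval(pts, b) / length(b)
  d <- Fa - Fb
  max(d) + max(-d)
}

#' Significant peaks in the response distribution
#'
#' Local maxima of the circular KDE of the reports are candidate clusters.
#' The null distribution of peak amplitudes is built by resampling the
#' targets with replacement `n_boot` times and collecting the peak
#' amplitudes of each resample's KDE; observed peaks above the null's 95th
#' percentile are retained as significant. A global p-value for "any
#' clustering at all" compares the observed maximum peak amplitude to a
#' permutation null built by re-splitting the pooled reports and targets
#' (exchangeable under the null that reports are distributed like
#' targets, so the p-value is exactly uniform there).
#'
#' @param reports,targets angles in degrees (at least 100 reports).
#' @param n_boot bootstrap resamples of the target distribution.
#' @param seed resampling seed.
#' @param amplitude_quantile retention cutoff on the pooled null peak
#'   amplitudes (default 0.95).
#' @return list with `peaks` (tibble: `angle_deg`, `amplitude`,
#'   `significant`), `threshold`, and `p_global`.
#' @export
response_peaks <- function(reports, targets, n_boot = 1000, seed = 1,
                           amplitude_quantile = 0.95) {
  stopifnot(length(reports) >= 100)
  g <- wm_grid(360)
  obs <- circ_kde(deg2rad(reports), grid = g)
  obs_peaks <- local_maxima_circ(obs)
  set.seed(seed)
  null_amps <- vector("list", n_boot)
  null_max <- numeric(n_boot)
  tr <- deg2rad(targets)
  pooled <- c(deg2rad(reports), tr)
  n_rep <- length(reports)
  for (b in seq_len(n_boot)) {
    f <- circ_kde(sample(tr, length(tr), replace = TRUE), grid = g)
    pk <- local_maxima_circ(f)
    null_amps[[b]] <- f[pk]
    fp <- circ_kde(sample(pooled, n_rep), grid = g)
    pkp <- local_maxima_circ(fp)
    null_max[b] <- if (length(pkp)) max(fp[pkp]) else max(fp)
  }
  thr <- stats::quantile(unlist(null_amps), amplitude_quantile, names = FALSE)
  amps <- obs[obs_peaks]
  p_global <- (1 + sum(null_max >= max(amps))) / (n_boot + 1)
  list(peaks = tibble::tibble(angle_deg = rad2deg(g$centers[obs_peaks]),
                              amplitude = amps,
                              significant = amps > thr),
       threshold = thr, p_global = p_global, n_boot = n_boot)
}

# indices of strict local maxima with circular wrap
local_maxima_circ <- function(v) {
  n <- length(v)
  which(v > v[c(2:n, 1)] & v > v[c(n, 1:(n - 1))])
}

#' Bias and precision of reports across color space
#'
#' Bins targets into `bin_width_deg` bins and computes, per bin, the
#' circular mean signed error (bias, clockwise positive) and the circular
#' SD of errors. At each supplied anchor angle the local bias slope
#' (dimensionless, deg/deg) is estimated by ordinary least squares on
#' (target offset from anchor, bias) pairs within +-`window_deg`, together
#' with the mean per-bin SD in the same window. An attractive fixed point
#' shows a negative slope and a locally reduced SD.
#'
#' @param trials a trial table.
#' @param bin_width_deg target bin width; must divide 360 (4 for the dense
#'   human sampling, 6 for the coarser 64-color sampling).
#' @param anchors angles (degrees) at which to evaluate slope and local SD.
#' @param window_deg half-window for the slope/SD estimates (default 15).
#' @return list of class `wm_bias_profile` with tibbles `profile`
#'   (`bin_center_deg`, `bias_deg`, `sd_deg`, `n`) and `anchors`
#'   (`anchor_deg`, `slope`, `slope_se`, `mean_sd_deg`, `n`).
#' @export
bias_profile <- function(trials, bin_width_deg = 4, anchors = numeric(0),
                         window_deg = 15) {
  trials <- add_error(as_trials(trials))
  if (360 %% bin_width_deg != 0) stop("bin width must divide 360", call. = FALSE)
  n_bins <- 360 / bin_width_deg
  bin <- floor(trials$target_deg / bin_width_deg) %% n_bins
  centers <- (seq_len(n_bins) - 0.5) * bin_width_deg
  err_rad <- deg2rad(trials$error_deg)
  prof <- purrr::map_dfr(seq_len(n_bins) - 1, function(b) {
    e <- err_rad[bin == b]
    if (!length(e)) {
      tibble::tibble(bin_center_deg = centers[b + 1], bias_deg = NA_real_,
                     sd_deg = NA_real_, n = 0L)
    } else {
      mu <- atan2(mean(sin(e)), mean(cos(e)))
      tibble::tibble(bin_center_deg = centers[b + 1],
                     bias_deg = rad2deg(mu),
                     sd_deg = rad2deg(circ_sd_rad(e)),
                     n = length(e))
    }
  })
  anchor_tab <- purrr::map_dfr(anchors, function(a) {
    off <- circ_error(trials$target_deg, a)
    sel <- abs(off) <= window_deg
    if (sum(sel) < 3) {
      return(tibble::tibble(anchor_deg = a, slope = NA_real_,
                            slope_se = NA_real_, mean_sd_deg = NA_real_,
                            n = sum(sel)))
    }
    fit <- stats::lm(trials$error_deg[sel] ~ off[sel])
    co <- summary(fit)$coefficients
    bin_off <- abs(circ_error(prof$bin_center_deg, a)) <= window_deg
    tibble::tibble(anchor_deg = a,
                   slope = co[2, 1], slope_se = co[2, 2],
                   mean_sd_deg = mean(prof$sd_deg[bin_off], na.rm = TRUE),
                   n = sum(sel))
  })
  structure(list(profile = prof, anchors = anchor_tab,
                 bin_width_deg = bin_width_deg, window_deg = window_deg),
            class = "wm_bias_profile")
}

#' @export
print.wm_bias_profile <- function(x, ...) {
  cat(sprintf("<wm_bias_profile> %d bins of %g deg", nrow(x$profile),
              x$bin_width_deg))
  if (nrow(x$anchors)) {
    cat(sprintf("; mean anchor slope %.3f", mean(x$anchors$slope, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Differential error growth near stable vs unstable fixed points
#'
#' Compares how much absolute error grows from the shortest to the longest
#' delay for targets near stable fixed points (attractors) versus near
#' unstable fixed points. Under attractor dynamics error should grow
#' faster near unstable fixed points; the one-sided bootstrap p-value
#' tests `delta_err_UFP > delta_err_SFP` by resampling trials.
#'
#' @param trials a trial table with at least two delay levels.
#' @param stable_deg,unstable_deg fixed-point angles in degrees.
#' @param window_deg half-window defining "near" (default 15).
#' @param n_boot bootstrap iterations.
#' @param seed bootstrap seed.
#' @return tibble with `delta_err_sfp`, `delta_err_ufp`, `difference`,
#'   `p_boot`, and the trial counts used.
#' @export
error_growth <- function(trials, stable_deg, unstable_deg, window_deg = 15,
                         n_boot = 1000, seed = 1) {
  trials <- add_error(as_trials(trials))
  delays <- sort(unique(trials$delay_s))
  if (length(delays) < 2) stop("need at least two delay levels", call. = FALSE)
  if (!length(stable_deg) || !length(unstable_deg)) {
    stop("need at least one stable and one unstable fixed point", call. = FALSE)
  }
  t_short <- delays[1]; t_long <- delays[length(delays)]
  near <- function(targ, pts) {
    d <- vapply(pts, function(p) abs(circ_error(targ, p)), numeric(length(targ)))
    apply(matrix(d, ncol = length(pts)), 1, min) <= window_deg
  }
  use <- trials$delay_s %in% c(t_short, t_long)
  tt <- trials[use, ]
  cls <- dplyr::case_when(near(tt$target_deg, stable_deg) ~ "sfp",
                          near(tt$target_deg, unstable_deg) ~ "ufp",
                          TRUE ~ NA_character_)
  tt <- tt[!is.na(cls), ]; cls <- cls[!is.na(cls)]
  growth <- function(idx) {
    s <- tt[idx, ]; cl <- cls[idx]
    g <- function(class) {
      lo <- abs(s$error_deg[cl == class & s$delay_s == t_short])
      hi <- abs(s$error_deg[cl == class & s$delay_s == t_long])
      if (!length(lo) || !length(hi)) return(NA_real_)
      mean(hi) - mean(lo)
    }
    c(sfp = g("sfp"), ufp = g("ufp"))
  }
  obs <- growth(seq_len(nrow(tt)))
  set.seed(seed)
  boot_diff <- vapply(seq_len(n_boot), function(b) {
    gg <- growth(sample.int(nrow(tt), replace = TRUE))
    gg[["ufp"]] - gg[["sfp"]]
  }, numeric(1))
  p <- mean(boot_diff <= 0, na.rm = TRUE)
  tibble::tibble(delta_err_sfp = obs[["sfp"]], delta_err_ufp = obs[["ufp"]],
                 difference = obs[["ufp"]] - obs[["sfp"]],
                 p_boot = max(p, 1 / (n_boot + 1)),
                 n_sfp = sum(cls == "sfp"), n_ufp = sum(cls == "ufp"))
}

#' Alignment of attractors with reference colors
#'
#' Tests whether fitted attractor locations sit closer to a set of
#' reference points (e.g. commonly presented colors) than chance. The
#' statistic is the mean circular distance from each attractor to its
#' nearest reference point, pooled over units (subjects); the null
#' re-pairs each unit's attractors with a randomly rotated copy of its
#' reference set, `n_perm` times.
#'
#' @param attractors list of numeric vectors (degrees), one per unit.
#' @param references list of numeric vectors (degrees), one per unit.
#' @param n_perm permutation draws (warning below 100).
#' @param seed permutation seed.
#' @return tibble with `mean_distance_deg`, `null_mean_deg`, `p_perm`.
#' @export
attractor_alignment <- function(attractors, references, n_perm = 1000,
                                seed = 1) {
  if (!is.list(attractors)) attractors <- list(attractors)
  if (!is.list(references)) references <- list(references)
  stopifnot(length(attractors) == length(references),
            all(lengths(attractors) >= 1), all(lengths(references) >= 1))
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  nearest <- function(a, r) {
    vapply(a, function(ai) min(abs(circ_error(ai, r))), numeric(1))
  }
  stat <- function(shift) {
    mean(unlist(purrr::map2(attractors, seq_along(references), function(a, i) {
      nearest(a, wrap_deg(references[[i]] + shift[i]))
    })))
  }
  obs <- stat(rep(0, length(references)))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    stat(stats::runif(length(references), 0, 360))
  }, numeric(1))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  tibble::tibble(mean_distance_deg = obs, null_mean_deg = mean(null),
                 p_perm = p)
}
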