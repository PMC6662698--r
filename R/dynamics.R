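#' Continuous-time Markov generator for drift-diffusion on the ring
#'
#' Discretizes the Fokker-Planck operator
#' `-d/dtheta [beta G(theta) p] + (sigma^2/2) d^2 p / dtheta^2`
#' with periodic boundary, as nearest-neighbor hopping rates between bins.
#' The rates use exponentially fitted (Scharfetter-Gummel) upwinding: with
#' diffusion coefficient `D = sigma^2/2` and interface velocity `v`, the
#' clockwise and counterclockwise rates across an interface are
#' `(D/delta^2) B(-v delta/D)` and `(D/delta^2) B(v delta/D)` where
#' `B(x) = x/(exp(x) - 1)`. This keeps every off-diagonal entry
#' nonnegative (a valid continuous-time Markov generator) for any `beta`
#' and `sigma`, reduces to plain first-order upwinding as `sigma -> 0`,
#' and, unlike plain upwinding, does not add numerical diffusion of order
#' `|v| delta / 2` on a 100-bin grid. Every column sums to zero, so
#' probability is conserved exactly.
#'
#' @param field a [drift_field()] (or `NULL` for pure diffusion).
#' @param beta drift gain, rad/s (max instantaneous drift rate).
#' @param sigma diffusion scale, rad/sqrt(s); must be >= 0.
#' @param grid a [wm_grid()]; defaults to the field's grid.
#' @return object of class `wm_generator`: dense matrix `M` (units 1/s)
#'   plus the `(beta, sigma)` used.
#' @export
generator_matrix <- function(field, beta, sigma, grid = NULL) {
  if (is.null(grid)) {
    stopifnot(inherits(field, "wm_drift"))
    grid <- field$grid
  }
  stopifnot(is_wm_grid(grid))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (!is.numeric(beta) || !is.finite(beta)) stop("beta must be finite", call. = FALSE)
  n <- grid$n_bins
  d <- grid$delta
  v <- if (is.null(field)) rep(0, n) else beta * field$values
  # velocity at the interface between bin i and bin i+1 (circular)
  v_int <- (v + v[c(2:n, 1)]) / 2
  D <- sigma^2 / 2
  if (D > 0) {
    w <- v_int * d / D
    up <- (D / d^2) * bernoulli_B(-w)   # rate i -> i+1 across interface i
    down <- (D / d^2) * bernoulli_B(w)  # rate i+1 -> i across interface i
  } else {
    up <- pmax(v_int, 0) / d
    down <- pmax(-v_int, 0) / d
  }
  M <- matrix(0, n, n)
  nxt <- c(2:n, 1)
  idx <- seq_len(n)
  M[cbind(nxt, idx)] <- up             # leave i clockwise
  M[cbind(idx, nxt)] <- down           # leave i+1 counterclockwise
  M[cbind(idx, idx)] <- -(up + down[c(n, 1:(n - 1))])
  structure(list(M = M, beta = beta, sigma = sigma, grid = grid),
            class = "wm_generator")
}

#' @export
print.wm_generator <- function(x, ...) {
  cat(sprintf("<wm_generator> %d x %d, beta = %g rad/s, sigma = %g rad/sqrt(s)\n",
              nrow(x$M), ncol(x$M), x$beta, x$sigma))
  invisible(x)
}

# Bernoulli function B(x) = x / (exp(x) - 1), numerically safe:
# B(0) = 1, B(x) ~ -x for x << 0, B(x) ~ x exp(-x) for x >> 0
bernoulli_B <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  big <- x > 700
  mid <- !small & !big
  out[small] <- 1 - x[small] / 2
  out[big] <- 0
  out[mid] <- x[mid] / expm1(x[mid])
  out
}

# dense matrix exponential; Matrix's scaling-and-squaring on a dgeMatrix
expm_dense <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))
}

#' Matrix-exponential propagation of a probability field
#'
#' Returns `expm(M t) p0`, renormalized to remove accumulated rounding
#' error; tiny negative densities from the matrix exponential are clipped
#' (beyond `-1e-9` they raise an internal-consistency error).
#'
#' @param p0 a [wm_pfield()].
#' @param gen a [generator_matrix()] (or a plain propagator matrix from
#'   [propagator()]).
#' @param t elapsed time, seconds (>= 0).
#' @return a [wm_pfield()] at time `t`.
#' @export
propagate <- function(p0, gen, t) {
  stopifnot(inherits(p0, "wm_pfield"))
  if (!is.numeric(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  if (t == 0) return(p0)
  K <- if (inherits(gen, "wm_generator")) expm_dense(gen$M * t) else gen
  wm_pfield(drop(K %*% p0$values), p0$grid, normalize = TRUE)
}

#' Precompute a propagator matrix `expm(M t)`
#'
#' Likelihood evaluation reuses one propagator per unique (load, delay)
#' condition; when `t` is a small integer multiple of a base time the
#' exponential is built once and powered up by repeated multiplication,
#' which is exact for a time-homogeneous generator.
#'
#' @inheritParams propagate
#' @return a dense `n x n` matrix.
#' @export
propagator <- function(gen, t) {
  stopifnot(inherits(gen, "wm_generator"), t >= 0)
  if (t == 0) return(diag(nrow(gen$M)))
  expm_dense(gen$M * t)
}

# propagators for several times sharing one generator: compute the smallest
# by expm, others by exact matrix powers when integer multiples, else expm.
propagators_for <- function(gen, times) {
  times <- sort(unique(times))
  out <- vector("list", length(times))
  names(out) <- format(times, digits = 15)
  base_t <- times[1]
  base_K <- propagator(gen, base_t)
  for (i in seq_along(times)) {
    r <- times[i] / base_t
    if (abs(r - round(r)) < 1e-12 && round(r) <= 64) {
      out[[i]] <- matpow(base_K, as.integer(round(r)))
    } else {
      out[[i]] <- propagator(gen, times[i])
    }
  }
  out
}

matpow <- function(K, k) {
  if (k == 1) return(K)
  R <- NULL
  P <- K
  while (k > 0) {
    if (k %% 2 == 1) R <- if (is.null(R)) P else R %*% P
    k <- k %/% 2
    if (k > 0) P <- P %*% P
  }
  R
}

#' Encoding stage: initialize and propagate a memory for 1 s
#'
#' A remembered item starts as a narrow von Mises density centered on the
#' stimulus (circular SD 0.1 rad) and is propagated for a fixed 1 s
#' encoding period under drift gain `beta_star` and diffusion `sigma_star`.
#'
#' @param target_deg stimulus angle, degrees.
#' @param field a [drift_field()].
#' @param beta_star encoding drift gain, rad/s.
#' @param sigma_star encoding diffusion, rad/sqrt(s).
#' @param encode_duration encoding period, seconds (default 1).
#' @param init_sd initial circular SD, radians (default 0.1).
#' @return a [wm_pfield()], the memory state at the start of the delay.
#' @export
encode_item <- function(target_deg, field, beta_star, sigma_star,
                        encode_duration = 1, init_sd = 0.1) {
  p0 <- pfield_vonmises(field$grid, deg2rad(target_deg), init_sd)
  gen <- generator_matrix(field, beta_star, sigma_star)
  propagate(p0, gen, encode_duration)
}

#' Dynamics and mixture parameter containers
#'
#' `dynamics_params()` collects the per-load drift/diffusion gains for the
#' memory delay (`beta`, `sigma`) and the encoding stage (`beta_star`,
#' `sigma_star`); each is a named numeric vector keyed by load ("1", "2",
#' "3"). All four are rates (change per second); encoding runs for a fixed
#' `encode_duration`.
#'
#' @param beta,sigma,beta_star,sigma_star named numeric vectors per load.
#' @param encode_duration encoding period, seconds.
#' @return a list of class `wm_dynamics`.
#' @export
dynamics_params <- function(beta, sigma, beta_star, sigma_star,
                            encode_duration = 1) {
  loads <- names(beta)
  stopifnot(!is.null(loads),
            identical(loads, names(sigma)),
            identical(loads, names(beta_star)),
            identical(loads, names(sigma_star)),
            all(sigma >= 0), all(sigma_star >= 0), encode_duration > 0)
  structure(list(beta = beta, sigma = sigma, beta_star = beta_star,
                 sigma_star = sigma_star, encode_duration = encode_duration),
            class = "wm_dynamics")
}

#' @rdname dynamics_params
#'
#' @details `mixture_params()` holds the observation-stage parameters: the
#' guess (lapse) probability `lambda(t) = a_lambda t + b_lambda` per load,
#' the swap probability `alpha(t) = a_alpha t + b_alpha` shared across
#' loads above 1 (identically zero at load 1), and the optional decoding
#' noise `sigma_dec` (circular SD in radians of a von Mises convolved with
#' the report density; `NULL` disables it, the monkey-style model). After
#' evaluating the linear forms each probability is clipped to `[0, 1]`; if
#' their sum exceeds 1 both are rescaled proportionally.
#'
#' @param a_lambda,b_lambda named numeric per load: guess slope (1/s) and
#'   intercept.
#' @param a_alpha,b_alpha swap slope and intercept (scalars).
#' @param sigma_dec decoding SD in radians, or `NULL`.
#' @export
mixture_params <- function(a_lambda, b_lambda, a_alpha = 0, b_alpha = 0,
                           sigma_dec = NULL) {
  stopifnot(!is.null(names(a_lambda)),
            identical(names(a_lambda), names(b_lambda)),
            length(a_alpha) == 1, length(b_alpha) == 1)
  if (!is.null(sigma_dec)) stopifnot(sigma_dec > 0)
  structure(list(a_lambda = a_lambda, b_lambda = b_lambda,
                 a_alpha = a_alpha, b_alpha = b_alpha,
                 sigma_dec = sigma_dec),
            class = "wm_mixture")
}

# evaluate (lambda, alpha) at time t for one load; returns c(lambda, alpha)
mixture_rates <- function(mix, load, t) {
  key <- as.character(load)
  if (!key %in% names(mix$a_lambda)) {
    stop("no mixture parameters for load ", load, call. = FALSE)
  }
  lam <- min(max(mix$a_lambda[[key]] * t + mix$b_lambda[[key]], 0), 1)
  alp <- if (load == 1) 0 else min(max(mix$a_alpha * t + mix$b_alpha, 0), 1)
  s <- lam + alp
  if (s > 1) {
    lam <- lam / s
    alp <- alp / s
  }
  c(lambda = lam, alpha = alp)
}

# circulant von Mises convolution matrix for decoding noise
decoding_kernel <- function(grid, sigma_dec) {
  k <- dvonmises_sd(grid$centers - grid$centers[1], 0, sigma_dec)
  k <- k / (sum(k) * grid$delta)
  n <- grid$n_bins
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  matrix(k[idx], n, n) * grid$delta
}

#' Predicted report distribution for a single trial
#'
#' Implements the full observation model: each remembered item (target and
#' non-targets) is encoded and propagated through the delay; the report
#' density is the mixture
#' `(1 - lambda - alpha) p_target + (alpha/m) sum_i p_nontarget_i +
#' lambda/(2 pi)`, optionally convolved with a von Mises decoding kernel.
#'
#' @param trial one-row data frame (or list) with `target_deg`,
#'   `nontarget1_deg`, `nontarget2_deg`, `load`, `delay_s`.
#' @param field a [drift_field()].
#' @param dyn a [dynamics_params()].
#' @param mix a [mixture_params()].
#' @return a [wm_pfield()] over the reported angle.
#' @export
report_distribution <- function(trial, field, dyn, mix) {
  load <- as.integer(trial$load)
  t <- as.numeric(trial$delay_s)
  key <- as.character(load)
  if (!key %in% names(dyn$beta)) stop("no dynamics for load ", load, call. = FALSE)
  nts <- c(trial$nontarget1_deg, trial$nontarget2_deg)
  nts <- nts[!is.na(nts)]
  m <- length(nts)
  rates <- mixture_rates(mix, load, t)
  if (rates[["alpha"]] > 0 && m == 0) {
    stop("swap probability > 0 with no non-targets (load 1)", call. = FALSE)
  }
  gen_star <- generator_matrix(field, dyn$beta_star[[key]], dyn$sigma_star[[key]])
  gen_mem <- generator_matrix(field, dyn$beta[[key]], dyn$sigma[[key]])
  K <- propagator(gen_mem, t) %*% propagator(gen_star, dyn$encode_duration)
  evolve <- function(ang_deg) {
    drop(K %*% pfield_vonmises(field$grid, deg2rad(ang_deg), 0.1)$values)
  }
  dens <- (1 - rates[["lambda"]] - rates[["alpha"]]) * evolve(trial$target_deg) +
    rates[["lambda"]] / (2 * pi)
  if (m > 0 && rates[["alpha"]] > 0) {
    nt_dens <- Reduce(`+`, lapply(nts, evolve)) / m
    dens <- dens + rates[["alpha"]] * nt_dens
  }
  if (!is.null(mix$sigma_dec)) {
    dens <- drop(decoding_kernel(field$grid, mix$sigma_dec) %*% dens)
  }
  wm_pfield(dens, field$grid, normalize = TRUE)
}

#' Log-likelihood of observed reports under the dynamical model
#'
#' Evaluates the report density (per radian, linearly interpolated between
#' bin centers) at each trial's report and sums the logs. Propagators are
#' shared across trials within each (load, delay) condition, and the
#' decoding convolution is folded into the propagator, so cost scales with
#' the number of conditions rather than trials.
#'
#' @param trials a trial table ([as_trials()]).
#' @param field a [drift_field()].
#' @param dyn a [dynamics_params()].
#' @param mix a [mixture_params()].
#' @param per_trial return the vector of per-trial log-likelihoods instead
#'   of the sum.
#' @return total log-likelihood in nats (or a vector if `per_trial`).
#' @export
loglik_trials <- function(trials, field, dyn, mix, per_trial = FALSE) {
  ctx <- loglik_context(as_trials(trials), field$grid)
  loglik_with_context(ctx, field, dyn, mix, per_trial = per_trial)
}

# Precomputed per-dataset quantities that do not depend on parameters:
# for each (load, delay) condition, the transposed initial-density
# matrices of all items and the report-interpolation indices. Building
# this once per fit keeps the optimizer's objective to matrix
# exponentials plus O(n_bins * n_trials) arithmetic.
loglik_context <- function(trials, grid) {
  conds <- dplyr::distinct(trials, .data$load, .data$delay_s)
  conds <- dplyr::arrange(conds, .data$load, .data$delay_s)
  blocks <- lapply(seq_len(nrow(conds)), function(ci) {
    L <- conds$load[ci]; t <- conds$delay_s[ci]
    rows <- which(trials$load == L & trials$delay_s == t)
    rep_rad <- deg2rad(trials$report_deg[rows])
    u <- wrap_rad(rep_rad - grid$centers[1]) / grid$delta
    i0 <- (as.integer(floor(u)) %% grid$n_bins) + 1L
    blk <- list(
      load = L, delay = t, rows = rows,
      i0 = i0, i1 = (i0 %% grid$n_bins) + 1L, frac = u - floor(u),
      P0t_target = t(init_density_matrix(grid, deg2rad(trials$target_deg[rows]))))
    if (L >= 2) {
      blk$P0t_nt1 <- t(init_density_matrix(grid, deg2rad(trials$nontarget1_deg[rows])))
    }
    if (L >= 3) {
      blk$P0t_nt2 <- t(init_density_matrix(grid, deg2rad(trials$nontarget2_deg[rows])))
    }
    blk
  })
  list(grid = grid, n = nrow(trials), blocks = blocks,
       loads = sort(unique(trials$load)))
}

# cached propagator: `cache` is an environment (or NULL to disable)
cached_propagator <- function(cache, key, make) {
  if (is.null(cache)) return(make())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- make()
  # finite-difference gradients revisit the unperturbed point constantly,
  # so a small cache suffices; flush wholesale before it grows large
  if (length(ls(cache)) > 256) rm(list = ls(cache), envir = cache)
  assign(key, val, envir = cache)
  val
}

par_key <- function(...) paste(format(c(...), digits = 17), collapse = "|")

loglik_with_context <- function(ctx, field, dyn, mix, per_trial = FALSE,
                                cache = NULL) {
  grid <- ctx$grid
  ll <- numeric(ctx$n)
  dec <- if (!is.null(mix$sigma_dec)) {
    cached_propagator(cache, par_key("dec", mix$sigma_dec),
                      function() decoding_kernel(grid, mix$sigma_dec))
  }
  wkey <- par_key(field$weights)
  enc_K <- list(); mem_base <- list()
  for (L in ctx$loads) {
    key <- as.character(L)
    if (!key %in% names(dyn$beta)) stop("no dynamics for load ", L, call. = FALSE)
    enc_K[[key]] <- cached_propagator(
      cache, par_key("enc", L, wkey, dyn$beta_star[[key]], dyn$sigma_star[[key]]),
      function() propagator(
        generator_matrix(field, dyn$beta_star[[key]], dyn$sigma_star[[key]]),
        dyn$encode_duration))
  }
  # memory propagators per (load, delay), sharing work across delays
  mem_K <- list()
  for (L in ctx$loads) {
    key <- as.character(L)
    ts <- sort(unique(vapply(ctx$blocks[vapply(ctx$blocks, function(b) b$load, 0) == L],
                             function(b) b$delay, numeric(1))))
    mkey <- par_key("mem", L, wkey, dyn$beta[[key]], dyn$sigma[[key]])
    mem_K[[key]] <- cached_propagator(
      cache, par_key(mkey, ts),
      function() propagators_for(
        generator_matrix(field, dyn$beta[[key]], dyn$sigma[[key]]), ts))
    names(mem_K[[key]]) <- format(ts, digits = 15)
  }
  for (blk in ctx$blocks) {
    key <- as.character(blk$load)
    K <- mem_K[[key]][[format(blk$delay, digits = 15)]] %*% enc_K[[key]]
    if (!is.null(dec)) K <- dec %*% K
    rates <- mixture_rates(mix, blk$load, blk$delay)
    lam <- rates[["lambda"]]; alp <- rates[["alpha"]]
    # rows of K interpolated at each report: KW is n_trials x n_bins
    KW <- K[blk$i0, , drop = FALSE] * (1 - blk$frac) +
      K[blk$i1, , drop = FALSE] * blk$frac
    dens <- rowSums(KW * blk$P0t_target)
    mixd <- (1 - lam - alp) * dens + lam / (2 * pi)
    if (blk$load > 1 && alp > 0) {
      m <- blk$load - 1
      nt_dens <- rowSums(KW * blk$P0t_nt1)
      if (m == 2) nt_dens <- nt_dens + rowSums(KW * blk$P0t_nt2)
      mixd <- mixd + alp * nt_dens / m
    }
    ll[blk$rows] <- log(pmax(mixd, 0))
  }
  if (per_trial) ll else sum(ll)
}

# matrix of initial von Mises densities (sd 0.1 rad), one column per angle
init_density_matrix <- function(grid, mu_rad, init_sd = 0.1) {
  kappa <- 1 / init_sd^2
  D <- exp(kappa * (cos(outer(grid$centers, mu_rad, `-`)) - 1))
  sweep(D, 2, colSums(D) * grid$delta, `/`)
}

# interpolate column j of density matrix P at angle theta[j]
interp_cols <- function(P, theta, grid) {
  n <- grid$n_bins
  u <- wrap_rad(theta - grid$centers[1]) / grid$delta
  i0 <- floor(u)
  frac <- u - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  cols <- seq_along(theta)
  P[cbind(i0, cols)] * (1 - frac) + P[cbind(i1, cols)] * frac
}
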