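#' Model variants
#'
#' A variant switches parts of the full model off: drift during memory
#' (`beta = 0`), drift during encoding (`beta_star = 0`), the decoding
#' convolution, and the parameterization of the guess rate. Drift basis
#' weights are only free when at least one drift stage is on.
#'
#' @param memory_drift free per-load memory drift gain `beta` (else 0).
#' @param encoding_drift free per-load encoding drift gain `beta_star`.
#' @param decoding_error include the decoding convolution SD `sigma_dec`
#'   (the human-style model); `FALSE` is the monkey-style model.
#' @param guess one of `"linear-per-load"` (slope and intercept per load),
#'   `"constant-per-load"`, `"constant-shared"`, `"zero"`.
#' @param n_basis number of drift basis functions.
#' @param label optional display label.
#' @return a list of class `wm_variant`.
#' @export
wm_variant <- function(memory_drift = TRUE, encoding_drift = TRUE,
                       decoding_error = FALSE,
                       guess = c("linear-per-load", "constant-per-load",
                                 "constant-shared", "zero"),
                       n_basis = 12, label = NULL) {
  guess <- match.arg(guess)
  if (is.null(label)) {
    label <- paste0(
      if (memory_drift) "drift" else "beta0",
      "+", if (encoding_drift) "enc-drift" else "betastar0",
      if (decoding_error) "+dec", "+guess-", guess)
  }
  structure(list(memory_drift = memory_drift, encoding_drift = encoding_drift,
                 decoding_error = decoding_error, guess = guess,
                 n_basis = as.integer(n_basis), label = label),
            class = "wm_variant")
}

#' @export
print.wm_variant <- function(x, ...) {
  cat("<wm_variant>", x$label, "\n")
  invisible(x)
}

# --- parameter vector <-> model objects ------------------------------------

# table of free parameters for a variant given the loads present
par_spec <- function(variant, loads) {
  loads <- sort(unique(as.integer(loads)))
  has_swap <- any(loads > 1)
  rows <- list()
  add <- function(name, load, lower, upper, init) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, load = load, lower = lower, upper = upper, init = init)
  }
  for (L in loads) {
    add("sigma", L, 1e-3, 3, 0.3)
    add("sigma_star", L, 1e-3, 3, 0.3)
    if (variant$memory_drift) add("beta", L, 0, 10, 0.5)
    if (variant$encoding_drift) add("beta_star", L, 0, 10, 0.5)
  }
  if (variant$memory_drift || variant$encoding_drift) {
    for (j in seq_len(variant$n_basis)) add("w", j, -5, 5, 0)
  }
  switch(variant$guess,
    "linear-per-load" = for (L in loads) {
      add("a_lambda", L, -0.5, 0.5, 0.01)
      add("b_lambda", L, 1e-4, 1, 0.05)
    },
    "constant-per-load" = for (L in loads) add("b_lambda", L, 1e-4, 1, 0.05),
    "constant-shared" = add("b_lambda", NA, 1e-4, 1, 0.05),
    "zero" = NULL)
  if (has_swap && variant$guess != "zero") {
    add("a_alpha", NA, -0.5, 0.5, 0.005)
    add("b_alpha", NA, 1e-4, 1, 0.02)
  }
  if (variant$decoding_error) add("sigma_dec", NA, 1e-3, 1, 0.2)
  dplyr::bind_rows(rows)
}

# parameter vector -> (weights, wm_dynamics, wm_mixture)
unpack_par <- function(par, spec, variant, loads) {
  loads <- sort(unique(as.integer(loads)))
  keys <- as.character(loads)
  get1 <- function(name, load = NULL) {
    i <- if (is.null(load)) which(spec$name == name)
         else which(spec$name == name & spec$load == load)
    if (length(i)) par[i] else NULL
  }
  pull_load <- function(name, default) {
    out <- stats::setNames(rep(default, length(loads)), keys)
    for (L in loads) {
      v <- get1(name, L)
      if (!is.null(v)) out[[as.character(L)]] <- v
    }
    out
  }
  weights <- if (variant$memory_drift || variant$encoding_drift) {
    par[spec$name == "w"]
  } else {
    rep(0, variant$n_basis)
  }
  dyn <- dynamics_params(
    beta = pull_load("beta", 0),
    sigma = pull_load("sigma", 1e-3),
    beta_star = pull_load("beta_star", 0),
    sigma_star = pull_load("sigma_star", 1e-3))
  b_shared <- get1("b_lambda", NA)
  mix <- mixture_params(
    a_lambda = pull_load("a_lambda", 0),
    b_lambda = if (variant$guess == "constant-shared")
      stats::setNames(rep(b_shared, length(loads)), keys)
      else pull_load("b_lambda", 0),
    a_alpha = get1("a_alpha") %||% 0,
    b_alpha = get1("b_alpha") %||% 0,
    sigma_dec = if (variant$decoding_error) get1("sigma_dec") else NULL)
  list(weights = weights, dyn = dyn, mix = mix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# informed start: drift weights from the derivative of the response KDE,
# diffusion from the spread of errors
informed_start <- function(trials, spec, variant, basis) {
  init <- spec$init
  if (any(spec$name == "w")) {
    kde <- circ_kde(deg2rad(trials$report_deg), sd = deg2rad(10),
                    grid = basis$grid)
    dprof <- numeric_deriv_circ(kde, basis$grid$delta)
    # ridge-regularized projection: the plain least-squares solution can
    # amplify the high harmonics of the KDE derivative into huge mutually
    # canceling coefficients, which makes the normalized drift field
    # hypersensitive to the weights and wrecks the optimization geometry
    BtB <- crossprod(basis$B)
    w <- tryCatch(
      drop(solve(BtB + 1e-3 * max(diag(BtB)) * diag(basis$n_basis),
                 crossprod(basis$B, dprof))),
      error = function(e) rep(0, basis$n_basis))
    # rescale so the raw (pre-normalization) profile has max 1: the drift
    # field is scale-invariant in the weights, and this scale makes the
    # objective locally well conditioned
    mx <- max(abs(basis$B %*% w))
    if (is.finite(mx) && mx > 0) w <- w / mx
    init[spec$name == "w"] <- pmin(pmax(w, spec$lower[spec$name == "w"]),
                                   spec$upper[spec$name == "w"])
  }
  for (L in unique(spec$load[spec$name == "sigma"])) {
    rows <- trials$load == L
    s <- circ_sd_rad(deg2rad(circ_error(trials$report_deg[rows],
                                        trials$target_deg[rows])))
    tbar <- mean(trials$delay_s[rows])
    init[spec$name == "sigma" & spec$load == L] <-
      min(max(s / sqrt(tbar + 1), 0.05), 3)
  }
  pmin(pmax(init, spec$lower), spec$upper)
}

numeric_deriv_circ <- function(v, delta) {
  n <- length(v)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * delta)
}

#' Maximum-likelihood fit of the dynamical model
#'
#' Fits all free parameters of a [wm_variant()] to a trial table by
#' bound-constrained quasi-Newton optimization (L-BFGS-B, finite-difference
#' gradients) from multiple starting points: one informed start (drift
#' weights seeded from the derivative of the response density, diffusion
#' from the error spread) plus `n_starts - 1` Latin-hypercube draws inside
#' the bounds. The best converged start wins.
#'
#' @param trials a trial table.
#' @param variant a [wm_variant()].
#' @param n_starts number of optimizer starts (default 10).
#' @param seed integer seed controlling the start draws.
#' @param grid state-space discretization (default 100 bins).
#' @param maxit L-BFGS-B iteration cap per cycle.
#' @param n_cycles maximum optimizer restart cycles per start; restarting
#'   from the incumbent resets the quasi-Newton Hessian, which keeps
#'   progress going along this likelihood's long shallow valleys
#'   (encoding and memory gains trade off against each other).
#' @param cycle_tol stop cycling when a restart improves the negative
#'   log-likelihood by less than this.
#' @return object of class `wm_fit`; see [tidy.wm_fit()] and
#'   [glance.wm_fit()] for tabular views.
#' @export
fit_wm <- function(trials, variant = wm_variant(), n_starts = 10,
                   seed = 1, grid = wm_grid(), maxit = 200,
                   n_cycles = 6, cycle_tol = 0.1) {
  trials <- as_trials(trials)
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  loads <- sort(unique(trials$load))
  basis <- drift_basis(variant$n_basis, grid)
  spec <- par_spec(variant, loads)
  k <- nrow(spec)

  ctx <- loglik_context(trials, grid)
  cache <- new.env(parent = emptyenv())
  neg_ll <- function(par) {
    pieces <- unpack_par(par, spec, variant, loads)
    field <- drift_field(pieces$weights, basis)
    ll <- tryCatch(loglik_with_context(ctx, field, pieces$dyn, pieces$mix,
                                       cache = cache),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  set.seed(seed)
  starts <- matrix(NA_real_, n_starts, k)
  starts[1, ] <- informed_start(trials, spec, variant, basis)
  if (n_starts > 1) {
    H <- lhs::randomLHS(n_starts - 1, k)
    lo <- spec$lower; hi <- spec$upper
    # draw weights in a gentler [-1, 1] box; other params across full bounds
    wmask <- spec$name == "w"
    lo[wmask] <- -1; hi[wmask] <- 1
    for (i in 2:n_starts) starts[i, ] <- lo + H[i - 1, ] * (hi - lo)
  }

  # one-sided finite-difference gradient sharing the propagator cache:
  # perturbing a single parameter only recomputes the matrix exponentials
  # it touches, so a full gradient costs far less than 2k fresh evaluations
  neg_ll_grad <- function(par) {
    f0 <- neg_ll(par)
    g <- numeric(k)
    for (j in seq_len(k)) {
      h <- 1e-6 * max(1, abs(par[j]))
      pj <- par
      if (par[j] + h <= spec$upper[j]) {
        pj[j] <- par[j] + h
        g[j] <- (neg_ll(pj) - f0) / h
      } else {
        pj[j] <- par[j] - h
        g[j] <- (f0 - neg_ll(pj)) / h
      }
    }
    g
  }

  run_start <- function(par0) {
    out <- NULL
    for (cycle in seq_len(n_cycles)) {
      res <- tryCatch(
        stats::optim(par0, neg_ll, gr = neg_ll_grad, method = "L-BFGS-B",
                     lower = spec$lower, upper = spec$upper,
                     control = list(maxit = maxit, factr = 1e7)),
        error = function(e) list(value = Inf, convergence = 99L, par = par0,
                                 message = conditionMessage(e)))
      if (!is.finite(res$value)) return(res)
      improved <- is.null(out) || out$value - res$value > cycle_tol
      if (is.null(out) || res$value < out$value) out <- res
      if (!improved) break
      par0 <- res$par
    }
    out
  }
  runs <- lapply(seq_len(n_starts), function(i) run_start(starts[i, ]))
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(values) | values >= 1e10)) {
    stop("no optimizer start converged to a finite likelihood; diagnostics: ",
         paste(vapply(runs, function(r) as.character(r$convergence),
                      character(1)), collapse = ","), call. = FALSE)
  }
  best <- which.min(values)
  par <- runs[[best]]$par
  pieces <- unpack_par(par, spec, variant, loads)
  field <- drift_field(pieces$weights, basis)
  ll <- -values[best]
  n <- nrow(trials)
  diagnostics <- tibble::tibble(
    start = seq_len(n_starts),
    value = values,
    convergence = vapply(runs, function(r) as.integer(r$convergence),
                         integer(1)))
  structure(list(
    variant = variant, field = field, dyn = pieces$dyn, mix = pieces$mix,
    par = stats::setNames(par, paste0(spec$name,
                                      ifelse(is.na(spec$load), "",
                                             paste0("_", spec$load)))),
    spec = spec, logLik = ll, n_params = k, n_trials = n,
    AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll,
    diagnostics = diagnostics, seed = seed, best_start = best,
    loads = loads,
    data_fingerprint = c(n, sum(trials$report_deg), sum(trials$target_deg))),
    class = "wm_fit")
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("<wm_fit>", x$variant$label, "\n")
  cat(sprintf("  %d trials, %d parameters\n", x$n_trials, x$n_params))
  cat(sprintf("  logLik %.2f | AIC %.2f | BIC %.2f (best of %d starts)\n",
              x$logLik, x$AIC, x$BIC, nrow(x$diagnostics)))
  invisible(x)
}

#' @export
logLik.wm_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n_trials,
            class = "logLik")
}

#' Compare fitted model variants by information criteria
#'
#' Computes delta-AIC/BIC and Akaike/Schwarz weights
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` across a set of fits of
#' the same dataset; a weight reads as the probability that the variant is
#' the best model in the set.
#'
#' @param ... `wm_fit` objects (or a single list of them).
#' @return a tibble with one row per variant.
#' @export
compare_wm <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "wm_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "wm_fit")))
  fp <- lapply(fits, function(f) f$data_fingerprint)
  if (!all(vapply(fp, function(x) isTRUE(all.equal(x, fp[[1]])), TRUE))) {
    stop("fits were not computed on the identical dataset", call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  wt <- function(x) {
    d <- x - min(x)
    exp(-d / 2) / sum(exp(-d / 2))
  }
  tibble::tibble(
    variant = vapply(fits, function(f) f$variant$label, character(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    AIC = aic, delta_AIC = aic - min(aic), weight_AIC = wt(aic),
    BIC = bic, delta_BIC = bic - min(bic), weight_BIC = wt(bic))
}

#' Cross-validated log-likelihood of a variant
#'
#' K-fold cross-validation stratified by load-by-delay condition: each fold
#' holds out a balanced share of every condition, the variant is refit to
#' the remainder, and the held-out per-trial log-likelihood is averaged.
#'
#' @inheritParams fit_wm
#' @param k_folds number of folds (default 10).
#' @param n_starts optimizer starts per fold fit.
#' @return list with `mean_loglik` (per held-out trial), `fold_logliks`,
#'   and `k_folds`.
#' @export
crossval_wm <- function(trials, variant = wm_variant(), k_folds = 10,
                        seed = 1, n_starts = 2, grid = wm_grid(),
                        maxit = 200) {
  trials <- as_trials(trials)
  stopifnot(k_folds >= 2)
  set.seed(seed)
  cond <- interaction(trials$load, trials$delay_s, drop = TRUE)
  fold <- integer(nrow(trials))
  for (cc in levels(cond)) {
    rows <- which(cond == cc)
    if (length(rows) < k_folds) {
      stop("condition ", cc, " has fewer trials than folds; ",
           "use fewer folds", call. = FALSE)
    }
    fold[rows] <- sample(rep_len(seq_len(k_folds), length(rows)))
  }
  fold_ll <- numeric(k_folds)
  fold_n <- integer(k_folds)
  for (f in seq_len(k_folds)) {
    train <- trials[fold != f, ]
    test <- trials[fold == f, ]
    if (!setequal(unique(train$load), unique(trials$load))) {
      stop("a training fold lost a load level; use fewer folds", call. = FALSE)
    }
    fit <- fit_wm(train, variant, n_starts = n_starts, seed = seed + f,
                  grid = grid, maxit = maxit)
    fold_ll[f] <- loglik_trials(test, fit$field, fit$dyn, fit$mix)
    fold_n[f] <- nrow(test)
  }
  list(mean_loglik = sum(fold_ll) / sum(fold_n),
       fold_logliks = fold_ll, fold_n = fold_n, k_folds = k_folds)
}

#' Bootstrap uncertainty for fitted parameters
#'
#' Two resampling modes mirroring how uncertainty is usually quantified in
#' this design: `"trials"` resamples one subject's trials with replacement
#' and refits (suitable for high-trial-count subjects), and
#' `"subject_params"` resamples a set of per-subject fitted parameter
#' tables with replacement and takes the mean on each iteration.
#'
#' @param x a trial table (`mode = "trials"`) or a list of `wm_fit` objects
#'   (`mode = "subject_params"`).
#' @param mode resampling mode.
#' @param n_iter bootstrap iterations (a warning is recorded below 100).
#' @param seed integer seed.
#' @param contrast optional function mapping a one-replicate tidy parameter
#'   tibble to named numbers; one-sided p-values `P(contrast <= 0)` are
#'   reported for each.
#' @param ... passed to [fit_wm()] in `"trials"` mode (variant, n_starts,
#'   maxit, ...).
#' @return list with `draws` (tibble of parameter values per iteration),
#'   `ci` (2.5/97.5 percentile intervals), and `contrast_p` (or NULL).
#' @export
bootstrap_wm <- function(x, mode = c("subject_params", "trials"),
                         n_iter = 1000, seed = 1, contrast = NULL, ...) {
  mode <- match.arg(mode)
  if (n_iter < 100) warning("n_iter < 100: bootstrap intervals will be crude")
  set.seed(seed)
  if (mode == "subject_params") {
    stopifnot(is.list(x), length(x) >= 2,
              all(vapply(x, inherits, TRUE, "wm_fit")))
    tabs <- lapply(seq_along(x), function(i) {
      out <- tidy(x[[i]])
      out$subject <- i
      out
    })
    all_par <- dplyr::bind_rows(tabs)
    draws <- purrr::map_dfr(seq_len(n_iter), function(it) {
      pick <- sample(seq_along(x), length(x), replace = TRUE)
      rep_tab <- dplyr::bind_rows(tabs[pick])
      out <- dplyr::summarise(dplyr::group_by(rep_tab, .data$term),
                              estimate = mean(.data$estimate), .groups = "drop")
      out$iter <- it
      out
    })
  } else {
    trials <- as_trials(x)
    draws <- purrr::map_dfr(seq_len(n_iter), function(it) {
      idx <- sample.int(nrow(trials), replace = TRUE)
      fit <- fit_wm(trials[idx, ], seed = seed + it, ...)
      out <- tidy(fit)[, c("term", "estimate")]
      out$iter <- it
      out
    })
  }
  ci <- dplyr::summarise(dplyr::group_by(draws, .data$term),
                         lower = unname(stats::quantile(.data$estimate, 0.025)),
                         upper = unname(stats::quantile(.data$estimate, 0.975)),
                         .groups = "drop")
  contrast_p <- NULL
  if (!is.null(contrast)) {
    vals <- purrr::map_dfr(split(draws, draws$iter), function(d) {
      tibble::as_tibble(as.list(contrast(d)))
    })
    contrast_p <- vapply(vals, function(v) mean(v <= 0), numeric(1))
  }
  list(draws = draws, ci = ci, contrast_p = contrast_p, n_iter = n_iter,
       mode = mode, seed = seed)
}
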