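test_that("the basis is n curves of zero-integral von Mises derivatives", {
  g <- wm_grid()
  b <- drift_basis(12, g)
  expect_equal(ncol(b$B), 12)
  expect_equal(diff(sort(b$means))[1], 2 * pi / 12)
  # each curve integrates to ~0 (derivative of a periodic density)
  expect_true(all(abs(colSums(b$B) * g$delta) < 1e-6))
  expect_error(drift_basis(1, g), "n_basis")
})

test_that("each basis curve crosses zero with negative slope at its mean", {
  g <- wm_grid(720)
  b <- drift_basis(12, g)
  for (j in c(1, 5, 12)) {
    at_mean <- dvonmises_sd_deriv(b$means[j], b$means[j], b$sd)
    expect_lt(abs(at_mean), 1e-12)
    eps <- 1e-4
    expect_lt(dvonmises_sd_deriv(b$means[j] + eps, b$means[j], b$sd), 0)
    expect_gt(dvonmises_sd_deriv(b$means[j] - eps, b$means[j], b$sd), 0)
  }
})

test_that("drift fields are max-normalized, with the zero field flagged", {
  b <- drift_basis(12, wm_grid())
  set.seed(7)
  for (i in 1:5) {
    f <- drift_field(rnorm(12), b)
    expect_equal(max(abs(f$values)), 1)
  }
  z <- drift_field(rep(0, 12), b)
  expect_true(all(z$values == 0))
  expect_equal(z$norm_constant, 0)
  expect_error(drift_field(rnorm(5), b), "12 weights")
})

test_that("a single positive weight yields one attractor at that mean", {
  b <- drift_basis(12, wm_grid())
  w <- rep(0, 12); w[4] <- 1
  f <- drift_field(w, b)
  fp <- fixed_points(f)
  expect_equal(nrow(fp$stable), 1)
  expect_lt(abs(circ_error(fp$stable$angle_deg, 120)), 2)
})

test_that("fixed points of closed-form profiles land at the analytic roots", {
  g <- wm_grid()
  b <- drift_basis(12, g)
  f1 <- fit_drift_profile(-sin(g$centers), b)
  fp1 <- fixed_points(f1)
  expect_lt(min(abs(circ_error(fp1$stable$angle_deg, 0))), 1)
  expect_lt(min(abs(circ_error(fp1$unstable$angle_deg, 180))), 1)
  expect_true(all(fp1$stable$slope < 0))
  expect_true(all(fp1$unstable$slope > 0))

  fp4 <- fixed_points(fx_field())
  expect_equal(nrow(fp4$stable), 4)
  expect_equal(nrow(fp4$unstable), 4)
  for (a in c(0, 90, 180, 270)) {
    expect_lt(min(abs(circ_error(fp4$stable$angle_deg, a))), 1)
  }
})

test_that("constant-sign fields have no fixed points; zero field empty", {
  g <- wm_grid()
  b <- drift_basis(12, g)
  f <- drift_field(rep(0, 12), b)
  f$values <- rep(0.5, g$n_bins)  # constant positive drift
  fp <- fixed_points(f)
  expect_equal(nrow(fp$stable), 0)
  expect_equal(nrow(fp$unstable), 0)
  fp0 <- fixed_points(drift_field(rep(0, 12), b))
  expect_equal(nrow(fp0$stable) + nrow(fp0$unstable), 0)
})

test_that("fixed points match a brute-force scan on a 10x finer grid", {
  g <- wm_grid()
  fine <- wm_grid(1000)
  b <- drift_basis(12, g)
  b_fine <- drift_basis(12, fine)
  set.seed(42)
  for (i in 1:25) {
    w <- rnorm(12)
    f <- drift_field(w, b)
    fp <- fixed_points(f, prominence_quantile = 0)
    gv <- drift_field(w, b_fine)$values
    sgn_change <- which(gv * gv[c(2:1000, 1)] < 0)
    stable_fine <- fine$centers[sgn_change[gv[sgn_change] > 0]]
    expect_equal(nrow(fp$stable), length(stable_fine))
    if (length(stable_fine)) {
      d <- vapply(fp$stable$angle_deg, function(a) {
        min(abs(circ_error(a, stable_fine * 180 / pi)))
      }, numeric(1))
      expect_lt(max(d), 2 * 360 / 100)
    }
  }
})

test_that("weak attractors below the prominence cutoff are removed", {
  g <- wm_grid()
  b <- drift_basis(12, g)
  # two strong attractors and one shallow one
  prof <- -sin(2 * g$centers) - 0.05 * sin(6 * (g$centers - 0.3))
  f <- fit_drift_profile(prof, b)
  all_fp <- fixed_points(f, prominence_quantile = 0)
  cut_fp <- fixed_points(f, prominence_quantile = 0.4)
  expect_lte(nrow(cut_fp$stable), nrow(all_fp$stable))
  expect_equal(nrow(cut_fp$stable), nrow(cut_fp$unstable))
})

test_that("profile fitting recovers in-span targets exactly", {
  b <- drift_basis(12, wm_grid())
  set.seed(3)
  w <- rnorm(12)
  target <- drop(b$B %*% w)
  f <- fit_drift_profile(target, b)
  # recovered weights reproduce the profile shape up to normalization
  expect_lt(max(abs(f$values - target / max(abs(target)))), 1e-6)
  expect_lt(max(abs(f$weights - w)), 1e-6)
  z <- fit_drift_profile(rep(0, 100), b)
  expect_true(all(z$values == 0))
  expect_warning(fit_drift_profile(rep(2, 100), b), "constant")
})

test_that("fitted fields place attractors at density modes", {
  g <- wm_grid()
  b <- drift_basis(12, g)
  modes <- c(45, 135, 225, 315) * pi / 180
  dens <- Reduce(`+`, lapply(modes, function(m) {
    dvonmises_sd(g$centers, m, 0.3)
  }))
  n <- length(dens)
  dprof <- (dens[c(2:n, 1)] - dens[c(n, 1:(n - 1))]) / (2 * g$delta)
  f <- fit_drift_profile(dprof, b)
  fp <- fixed_points(f)
  for (m in c(45, 135, 225, 315)) {
    expect_lt(min(abs(circ_error(fp$stable$angle_deg, m))), 360 / 100 + 1e-6)
  }
})

test_that("drift fields are continuous across the wrap point", {
  b <- drift_basis(12, wm_grid())
  set.seed(11)
  for (i in 1:10) {
    f <- drift_field(rnorm(12), b)
    jumps <- abs(diff(c(f$values, f$values[1])))
    expect_lt(max(jumps), 5 * stats::median(jumps[jumps > 0]) + 0.2)
  }
})
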