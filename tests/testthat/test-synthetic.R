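test_that("same-trial colors respect the minimum separation", {
  d <- task_design(loads = 3, n_per_load = 10000, delays_s = 1)
  tt <- sample_targets(d, seed = 12)
  d12 <- abs(circ_error(tt$target_deg, tt$nontarget1_deg))
  d13 <- abs(circ_error(tt$target_deg, tt$nontarget2_deg))
  d23 <- abs(circ_error(tt$nontarget1_deg, tt$nontarget2_deg))
  expect_gte(min(c(d12, d13, d23)), 22)
})

test_that("uniform environments produce uniform targets", {
  d <- task_design(loads = 1, n_per_load = 50000, delays_s = 1)
  tt <- sample_targets(d, seed = 13)
  counts <- tabulate(floor(tt$target_deg / 10) + 1, 36)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("biased environments put the advertised mass in clusters", {
  d <- task_design(loads = 1, n_per_load = 50000, delays_s = 1,
                   environment = "biased", cluster_phase_deg = 30)
  tt <- sample_targets(d, seed = 14)
  centers <- wrap_deg(30 + c(0, 90, 180, 270))
  in_cluster <- vapply(tt$target_deg, function(a) {
    any(abs(circ_error(a, centers)) <= 10)
  }, logical(1))
  # 50% from clusters plus the uniform half's overlap: 0.5 + 0.5 * 80/360
  expect_lt(abs(mean(in_cluster) - (0.5 + 0.5 * 80 / 360)), 0.01)
})

test_that("unsatisfiable separation constraints are rejected", {
  expect_error(task_design(loads = 3, min_separation_deg = 170),
               "unsatisfiable")
})

test_that("simulation is reproducible and respects its error structure", {
  truth <- wm_truth_default(species = "monkey")
  d <- task_design(loads = c(1, 3), n_per_load = 400, delays_s = c(1, 7))
  t1 <- simulate_trials(truth, d, seed = 15)
  t2 <- simulate_trials(truth, d, seed = 15)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_trials(truth, d, seed = 16)
  expect_false(isTRUE(all.equal(t1$report_deg, t3$report_deg)))
  expect_error(simulate_trials(truth, d, seed = 1, mode = "sde", dt = 0),
               "dt")
})

test_that("mean absolute error grows with delay and load", {
  truth <- wm_truth_default(species = "monkey")
  d <- task_design(loads = c(1, 3), n_per_load = 4000, delays_s = c(1, 7))
  tr <- add_error(simulate_trials(truth, d, seed = 17))
  m <- tapply(abs(tr$error_deg), list(tr$load, tr$delay_s), mean)
  expect_gt(m["1", "7"], m["1", "1"])
  expect_gt(m["3", "7"], m["3", "1"])
  expect_gt(m["3", "1"], m["1", "1"])
  expect_gt(m["3", "7"], m["1", "7"])
})

test_that("SDE and mixture simulation routes agree in distribution", {
  truth <- wm_truth_default(species = "monkey")
  d <- task_design(loads = 1, n_per_load = 30000, delays_s = 3)
  tm <- simulate_trials(truth, d, seed = 18, mode = "mixture")
  ts <- simulate_trials(truth, d, seed = 19, mode = "sde")
  hm <- tabulate(floor(tm$report_deg / 10) + 1, 36) / nrow(tm)
  hs <- tabulate(floor(ts$report_deg / 10) + 1, 36) / nrow(ts)
  expect_lt(0.5 * sum(abs(hm - hs)), 0.03)
})

test_that("halving the integration step leaves the SDE route unchanged", {
  truth <- wm_truth_default(species = "monkey")
  d <- task_design(loads = 1, n_per_load = 30000, delays_s = 2)
  h1 <- simulate_trials(truth, d, seed = 20, mode = "sde", dt = 0.01)
  h2 <- simulate_trials(truth, d, seed = 21, mode = "sde", dt = 0.005)
  f1 <- tabulate(floor(h1$report_deg / 20) + 1, 18) / nrow(h1)
  f2 <- tabulate(floor(h2$report_deg / 20) + 1, 18) / nrow(h2)
  # TV stays at the Monte-Carlo noise floor for 30k draws over 18 bins
  expect_lt(0.5 * sum(abs(f1 - f2)), 0.02)
})

test_that("expected error curves respect their analytic bounds", {
  truth <- wm_truth_default()
  tg <- c(0.25, 1, 3, 10, 40, 200)
  full <- error_over_time(truth, tg)
  expect_true(all(full$mean_abs_error_deg <= 90))
  expect_true(all(full$mean_abs_error_deg >= full$mean_abs_error_deg[1]))
  dif <- error_over_time(truth, c(500, 2000), include_drift = FALSE)
  # diffusion-only long-time limit: uniform, E|error| = 90 degrees
  expect_lt(abs(dif$mean_abs_error_deg[2] - 90), 0.5)
  same <- error_over_time(truth, c(1, 5), bias_fraction = 0,
                          include_drift = FALSE)
  same2 <- error_over_time(truth, c(1, 5), bias_fraction = 0.7,
                           include_drift = FALSE)
  # the diffusion-only model does not care about the environment (up to
  # the sub-bin placement of the quadrature targets)
  expect_equal(same$mean_abs_error_deg, same2$mean_abs_error_deg,
               tolerance = 0.01)
})

test_that("the error heatmap is consistent with the curve comparison", {
  truth <- wm_truth_default()
  tg <- c(1, 5, 20)
  hm <- error_heatmap(truth, tg, bias_fractions = c(0, 0.5))
  full0 <- error_over_time(truth, tg, bias_fraction = 0)
  dif <- error_over_time(truth, tg, include_drift = FALSE)
  manual <- 100 * (dif$mean_abs_error_deg - full0$mean_abs_error_deg) /
    full0$mean_abs_error_deg
  expect_equal(hm$pct_error_increase[hm$bias_fraction == 0], manual)
  # more biased environments favor attractors at long delays
  at20 <- hm[hm$t_s == 20, ]
  expect_gt(at20$pct_error_increase[at20$bias_fraction == 0.5],
            at20$pct_error_increase[at20$bias_fraction == 0])
})

test_that("the juice schedule matches its closed form", {
  expect_identical(juice_reward(0), 12L)
  expect_identical(juice_reward(61), 0L)
  expect_identical(juice_reward(-61), 0L)
  # pinned from the closed-form oracle ceil(12 exp(kappa (cos 22deg - 1)))
  expect_identical(juice_reward(22), 8L)
  expect_identical(juice_reward(60), 1L)
  e <- c(5, 15, 30, 45)
  kappa <- 1 / (22 * pi / 180)^2
  expect_identical(juice_reward(e),
                   as.integer(ceiling(12 * exp(kappa * (cos(e * pi / 180) - 1)))))
  # monotone non-increasing in |error|
  r <- juice_reward(0:90)
  expect_true(all(diff(r) <= 0))
})
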