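test_that("uniform circular densities carry log2(2 pi) bits of entropy", {
  g <- wm_grid(360)
  expect_equal(circ_entropy_bits(rep(1 / (2 * pi), 360), g), log2(2 * pi))
  # evenly spaced hue set through the KDE: still exactly uniform
  targ <- rep(seq(0, 360 - 360 / 64, length.out = 64), 40)
  cm <- clustering_metric(reports = targ, targets = targ)
  expect_equal(cm$H_targ_bits, log2(2 * pi), tolerance = 1e-6)
})

test_that("clustering is zero for identical samples, negative for clustered", {
  set.seed(21)
  targ <- runif(5000, 0, 360)
  cm0 <- clustering_metric(reports = targ, targets = targ)
  expect_equal(cm0$C_bits, 0)
  # responses resampled from the targets: C indistinguishable from 0
  cm1 <- clustering_metric(reports = sample(targ, 5000, TRUE), targets = targ)
  expect_lt(abs(cm1$C_bits), 0.02)
  # four narrow response modes over uniform targets: strongly negative
  modes <- c(40, 130, 220, 310)
  rep4 <- wrap_deg(modes[sample.int(4, 5000, TRUE)] + rnorm(5000, 0, 15))
  cm4 <- clustering_metric(reports = rep4, targets = targ)
  expect_lt(cm4$C_bits, -0.1)
  expect_error(clustering_metric(reports = targ, targets = targ,
                                 guess_rate = 1), "guess_rate")
})

test_that("guess-rate removal undoes a uniform contamination", {
  set.seed(22)
  targ <- runif(8000, 0, 360)
  modes <- c(40, 130, 220, 310)
  clustered <- wrap_deg(modes[sample.int(4, 8000, TRUE)] + rnorm(8000, 0, 12))
  lam <- 0.3
  contaminated <- ifelse(runif(8000) < lam, runif(8000, 0, 360), clustered)
  raw <- clustering_metric(reports = contaminated, targets = targ)
  corrected <- clustering_metric(reports = contaminated, targets = targ,
                                 guess_rate = lam)
  clean <- clustering_metric(reports = clustered, targets = targ)
  # correction moves C toward the uncontaminated value
  expect_lt(abs(corrected$C_bits - clean$C_bits),
            abs(raw$C_bits - clean$C_bits))
})

test_that("equal-count subsampling uses the requested conditions", {
  set.seed(23)
  targ <- runif(900, 0, 360)
  cond <- rep(c("a", "b", "c"), c(500, 300, 100))
  cm <- clustering_metric(reports = targ, targets = targ, conditions = cond)
  expect_equal(cm$n_used, 300)
})

test_that("Hodges-Ajne flags half-circle concentration, not uniformity", {
  set.seed(24)
  half <- runif(50, 0, 180)
  ha <- test_nonuniformity(half, runif(50, 0, 360), n_perm = 100,
                           seed = 1)$hodges_ajne_p
  expect_lt(ha, 1e-6)
  even <- seq(0, 360 - 6, by = 6)  # 60 points, exactly evenly spaced
  ha2 <- test_nonuniformity(even, runif(60, 0, 360), n_perm = 100,
                            seed = 1)$hodges_ajne_p
  expect_gt(ha2, 0.9)
})

test_that("the permuted Kuiper test is reproducible and detects mismatch", {
  set.seed(25)
  targ <- runif(200, 0, 360)
  rep_clust <- wrap_deg(c(40, 220)[sample.int(2, 200, TRUE)] +
                          rnorm(200, 0, 10))
  r1 <- test_nonuniformity(rep_clust, targ, n_perm = 300, seed = 7)
  r2 <- test_nonuniformity(rep_clust, targ, n_perm = 300, seed = 7)
  expect_equal(r1$kuiper_perm_p, r2$kuiper_perm_p)
  expect_lt(r1$kuiper_perm_p, 0.01)
  expect_warning(test_nonuniformity(rep_clust, targ, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("response peaks recover planted modes and are seed-stable", {
  set.seed(26)
  targ <- runif(4000, 0, 360)
  modes <- wrap_deg(c(13, 103, 193, 283))
  rep4 <- ifelse(runif(4000) < 0.7,
                 wrap_deg(modes[sample.int(4, 4000, TRUE)] + rnorm(4000, 0, 10)),
                 runif(4000, 0, 360))
  pk <- response_peaks(rep4, targ, n_boot = 200, seed = 4)
  sig <- pk$peaks[pk$peaks$significant, ]
  expect_gte(nrow(sig), 4)
  for (m in modes) {
    expect_lt(min(abs(circ_error(sig$angle_deg, m))), 5)
  }
  expect_lt(pk$p_global, 0.01)
  pk2 <- response_peaks(rep4, targ, n_boot = 200, seed = 4)
  expect_identical(pk$peaks, pk2$peaks)
})

test_that("bias profiles are rotation-equivariant", {
  tr <- fx_small_trials(2000, seed = 301)
  shift <- 40  # a whole number of 4-degree bins
  tr_rot <- tr
  tr_rot$target_deg <- wrap_deg(tr$target_deg + shift)
  tr_rot$report_deg <- wrap_deg(tr$report_deg + shift)
  bp <- bias_profile(tr, bin_width_deg = 4, anchors = c(45, 135))
  bp_rot <- bias_profile(tr_rot, bin_width_deg = 4,
                         anchors = c(45, 135) + shift)
  expect_equal(bp$anchors$slope, bp_rot$anchors$slope, tolerance = 1e-10)
  rotated_bias <- bp_rot$profile$bias_deg[
    match(wrap_deg(bp$profile$bin_center_deg + shift),
          bp_rot$profile$bin_center_deg)]
  expect_equal(bp$profile$bias_deg, rotated_bias, tolerance = 1e-10)
  expect_error(bias_profile(tr, bin_width_deg = 7), "divide")
})

test_that("a drift-free simulation shows flat bias around any anchor", {
  truth0 <- wm_truth(drift_field(rep(0, 12), drift_basis(12, wm_grid())),
                     wm_truth_default(species = "monkey")$dyn,
                     wm_truth_default(species = "monkey")$mix)
  d <- task_design(loads = 1, n_per_load = 6000, delays_s = c(1, 7))
  tr <- simulate_trials(truth0, d, seed = 55)
  bp <- bias_profile(tr, bin_width_deg = 4, anchors = c(45, 135, 225, 315))
  expect_true(all(abs(bp$anchors$slope) < 2 * bp$anchors$slope_se))
})

test_that("error growth contrasts are deterministic and null under beta=0", {
  truth0 <- wm_truth(drift_field(rep(0, 12), drift_basis(12, wm_grid())),
                     wm_truth_default(species = "monkey")$dyn,
                     wm_truth_default(species = "monkey")$mix)
  d <- task_design(loads = 1, n_per_load = 8000, delays_s = c(1, 7))
  tr <- simulate_trials(truth0, d, seed = 66)
  eg1 <- error_growth(tr, c(45, 135, 225, 315), c(0, 90, 180, 270),
                      n_boot = 300, seed = 8)
  eg2 <- error_growth(tr, c(45, 135, 225, 315), c(0, 90, 180, 270),
                      n_boot = 300, seed = 8)
  expect_equal(eg1$p_boot, eg2$p_boot)
  # no drift: SFP/UFP labels are arbitrary, growth difference is small
  expect_lt(abs(eg1$difference), 2)
  expect_gt(eg1$p_boot, 0.01)
  expect_error(error_growth(tr[tr$delay_s == 1, ], 45, 90), "delay")
})

test_that("attractor alignment is exact at zero distance and bounded", {
  att <- list(c(10, 100, 190, 280), c(33, 123))
  ref <- list(c(10, 100, 190, 280), c(33, 123, 213, 303))
  al <- attractor_alignment(att, ref, n_perm = 200, seed = 3)
  expect_equal(al$mean_distance_deg, 0)
  expect_lte(al$p_perm, 1 / 100)
  expect_gt(al$p_perm, 0)
  al2 <- attractor_alignment(att, ref, n_perm = 200, seed = 3)
  expect_equal(al$p_perm, al2$p_perm)
})

test_that("the screening mixture classifies engagement correctly", {
  set.seed(27)
  n <- 1500
  targ <- runif(n, 0, 360)
  mk <- function(rep_v) tibble::tibble(
    subject = "s", load = 1, delay_s = 1, target_deg = targ,
    report_deg = rep_v)
  clean <- wrap_deg(targ + rvonmises_sd(n, 0, 0.25) * 180 / pi)
  fit_c <- fit_guess_mixture(mk(clean))
  expect_lt(fit_c$p_guess, 0.05)
  expect_equal(fit_c$verdict, "keep")
  fit_u <- fit_guess_mixture(mk(runif(n, 0, 360)))
  expect_gt(fit_u$p_guess, 0.9)
  expect_equal(fit_u$verdict, "exclude")
  blend <- ifelse(runif(n) < 0.5, clean, runif(n, 0, 360))
  fit_b <- fit_guess_mixture(mk(blend))
  expect_lt(abs(fit_b$p_guess - 0.5), 0.07)
  expect_equal(fit_b$p_target + fit_b$p_guess + fit_b$p_swap, 1,
               tolerance = 1e-6)
  expect_error(fit_guess_mixture(mk(clean)[1:20, ]), "50 trials")
})

test_that("the screening mixture attributes swaps to non-targets", {
  set.seed(28)
  n <- 1500
  targ <- runif(n, 0, 360)
  nt <- wrap_deg(targ + 180)
  is_swap <- runif(n) < 0.25
  rep_v <- wrap_deg(ifelse(is_swap, nt, targ) + rvonmises_sd(n, 0, 0.2) * 180 / pi)
  tr <- tibble::tibble(subject = "s", load = 2, delay_s = 1,
                       target_deg = targ, nontarget1_deg = nt,
                       report_deg = rep_v)
  fit <- fit_guess_mixture(tr)
  expect_lt(abs(fit$p_swap - 0.25), 0.06)
  expect_lt(fit$p_guess, 0.1)
})
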