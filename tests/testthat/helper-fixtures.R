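# Shared fixtures, built in code. Heavier objects are memoized per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- make()
  fixture_env[[name]]
}

# a four-attractor drift field on the default 100-bin grid
fx_field <- function(grid = wm_grid()) {
  memo(paste0("field", grid$n_bins), function() {
    basis <- drift_basis(12, grid)
    fit_drift_profile(-sin(4 * grid$centers), basis)
  })
}

# small single-load trial table with reports generated by the truth
fx_small_trials <- function(n = 200, seed = 101) {
  memo(paste0("small", n, "_", seed), function() {
    truth <- wm_truth_default(species = "monkey")
    d <- task_design(loads = 1, n_per_load = n, delays_s = c(1, 7))
    simulate_trials(truth, d, seed = seed)
  })
}

# manual trial tibble
fx_manual_trials <- function() {
  tibble::tibble(
    subject = "s1",
    load = c(1, 2, 3),
    delay_s = c(1, 1, 7),
    target_deg = c(10, 100, 250),
    nontarget1_deg = c(NA, 200, 30),
    nontarget2_deg = c(NA, NA, 140),
    report_deg = c(15, 95, 260),
    trial_index = 1:3)
}

expect_mass_one <- function(p, tol = 1e-8) {
  expect_s3_class(p, "wm_pfield")
  expect_true(all(p$values >= 0))
  expect_lt(abs(sum(p$values) * p$grid$delta - 1), tol)
}
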