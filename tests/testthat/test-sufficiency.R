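test_that("plateau detection handles linear, constant and saturating curves", {
  lad <- seq(0.1, 1, 0.1)
  # strictly linear: still climbing, no plateau below the final ratio
  lin <- make_curve(seq(0.1, 0.9, length.out = 10), ratios = lad)
  expect_true(is.na(estimate_plateau(lin, epsilon = 0.01)))
  # constant: plateau at the first ladder ratio
  expect_equal(estimate_plateau(make_curve(rep(0.7, 10), ratios = lad), 0.01), 0.1)
  expect_error(estimate_plateau(make_curve(c(0.1, 0.2, 0.3)), smoothing_window = 3),
               "points")
})

test_that("noiseless plateaus recover the analytic inversion within one step", {
  lad <- ratio_ladder(0.02, 1, 0.02)
  for (tau in c(0.1, 0.15, 0.2)) {
    spec <- curve_family_spec(tau = tau, noise_sd = 0)
    cv <- simulate_learning_curves(spec, lad, 3, seed = 1)
    det <- estimate_plateau(cv, epsilon = 0.01, smoothing_window = 3)
    # exact inversion of value(1) - value(r) = epsilon for the family
    rstar <- -tau * log(0.01 / (spec$d_inf - spec$d0) + exp(-1 / tau))
    expect_lte(abs(det - rstar), 0.02 + 1e-9)
  }
})

test_that("minimal data for target follows the closed form and degenerate cases", {
  lad <- ratio_ladder(0.02, 1, 0.02)
  spec <- curve_family_spec(noise_sd = 0)
  cv <- simulate_learning_curves(spec, lad, 3, seed = 1)
  expect_equal(minimal_data_for_target(cv, 0), 0.02)       # trivially reached
  expect_true(is.na(minimal_data_for_target(cv, 0.99)))    # unreachable
  target <- spec$d_inf - 0.05
  # smoothing perturbs a noiseless monotone curve only at the edges
  got <- minimal_data_for_target(cv, target, smoothing_window = 1)
  rstar <- -spec$tau * log(0.05 / (spec$d_inf - spec$d0))
  expect_lte(abs(got - rstar), 0.02 + 1e-9)
})

test_that("sufficiency estimates are monotone in target and epsilon", {
  lad <- ratio_ladder(0.02, 1, 0.02)
  cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0.005), lad, 3, seed = 9)
  targets <- c(0.5, 0.6, 0.7, 0.8)
  mins <- vapply(targets, function(t) {
    r <- minimal_data_for_target(cv, t)
    if (is.na(r)) 2 else r  # NA = unreachable sorts above every ratio
  }, numeric(1))
  expect_true(all(diff(mins) >= 0))
  p_loose <- estimate_plateau(cv, epsilon = 0.05)
  p_tight <- estimate_plateau(cv, epsilon = 0.005)
  if (!is.na(p_loose) && !is.na(p_tight)) expect_lte(p_loose, p_tight)
})

test_that("reports pair sources per depth and find the cheapest configuration", {
  lad <- ratio_ladder(0.1, 1, 0.1)
  obs <- simulate_learning_curves(curve_family_spec(noise_sd = 0, depth_effect = 0.02),
                                  lad, 3:6, seed = 1)
  rep1 <- sufficiency_report(obs, forecast = obs, target_dsc = 0.8, epsilon = 0.01)
  expect_equal(nrow(rep1$estimates), 8)  # 2 sources x 4 depths
  # forecast == observed -> identical estimates from both sources
  o <- rep1$estimates[rep1$estimates$source == "observed", -2]
  f <- rep1$estimates[rep1$estimates$source == "forecast", -2]
  rownames(o) <- rownames(f) <- NULL
  expect_equal(o, f)
  # with a positive depth effect the deepest model reaches the target at the
  # smallest ratio (possibly tied at the ladder resolution, in which case the
  # summary prefers the cheaper depth)
  mins <- with(rep1$estimates[rep1$estimates$source == "observed", ],
               setNames(minimal_ratio_for_target, depth))
  expect_true(all(mins[["6"]] <= mins))
  expect_equal(rep1$summary$best_ratio, unname(mins[["6"]]))
  expect_true(rep1$summary$target_reachable)
  # misaligned ladders are refused
  other <- simulate_learning_curves(curve_family_spec(), ratio_ladder(0.15, 0.9, 0.15),
                                    3, seed = 1)
  expect_error(sufficiency_report(obs, other), "ladder")
})
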