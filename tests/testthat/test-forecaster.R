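test_that("a constant curve is predicted to stay constant", {
  cv <- make_curve(rep(0.8, 30))
  fc <- fit_forecaster(cv, forecaster_spec("uni_one_step", epochs = 300, seed = 1),
                       observed_fraction = 0.8)
  preds <- vapply(7:24, function(t) predict_one_step(fc, cv, t), numeric(1))
  expect_true(all(abs(preds - 0.8) < 0.01))
})

test_that("fitting is deterministic and validates prefixes", {
  cv <- simulate_learning_curves(curve_family_spec(), ratio_ladder(0.05, 1, 0.05),
                                 c(3, 4), seed = 2)
  sp <- forecaster_spec("uni_full_step", epochs = 50, seed = 3)
  f1 <- fit_forecaster(cv, sp, 0.5)
  f2 <- fit_forecaster(cv, sp, 0.5)
  p1 <- predict_full_step(f1, cv[cv$depth == 3, ][1:10, ], 5)
  expect_identical(p1, predict_full_step(f2, cv[cv$depth == 3, ][1:10, ], 5))
  expect_error(fit_forecaster(cv, forecaster_spec(window = 12), 0.5),
               "observed prefix")
})

test_that("the linear baseline is OLS on the prefix and exact on a line", {
  cv <- make_curve(0.2 + 0.5 * (1:20) / 20, ratios = (1:20) / 20)
  fc <- fit_forecaster(cv, forecaster_spec("linear_baseline"), 0.5)
  pred <- predict_full_step(fc, cv[1:10, ], 10, future_ratios = cv$data_ratio[11:20])
  expect_equal(pred, cv$dsc[11:20], tolerance = 1e-9)
  expect_equal(predict_one_step(fc, cv, 15), cv$dsc[15], tolerance = 1e-9)
})

test_that("one-step equals the first full-step forecast with shared weights", {
  cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0.005),
                                 ratio_ladder(0.05, 1, 0.05), 3, seed = 5)
  for (variant in c("uni_full_step", "bi_full_step")) {
    fc <- fit_forecaster(cv, forecaster_spec(variant, epochs = 100, seed = 5), 0.5)
    one <- predict_one_step(fc, cv, 11)
    roll <- predict_full_step(fc, cv[1:10, ], 3, future_ratios = cv$data_ratio[11:13])
    expect_identical(one, roll[1])
    expect_length(roll, 3)
  }
  fc <- fit_forecaster(cv, forecaster_spec(epochs = 50, seed = 5), 0.5)
  expect_error(predict_full_step(fc, cv[1:10, ], 0), "horizon")
  expect_error(predict_one_step(fc, cv, 4), "observed points")
})

test_that("predictions are clamped to [0, 1]", {
  cv <- make_curve(rep(0.9, 20))
  fc <- fit_forecaster(cv, forecaster_spec("uni_one_step", epochs = 20, seed = 1), 0.8)
  fc$weights$by <- 50  # force a huge positive increment
  expect_equal(predict_one_step(fc, cv, 10), 1.0)
})

test_that("bi-directional forecasts never read values at or beyond the target", {
  cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0.005),
                                 ratio_ladder(0.02, 1, 0.02), 3, seed = 6)
  fc <- fit_forecaster(cv, forecaster_spec("bi_one_step", epochs = 100, seed = 6), 0.5)
  poisoned <- cv
  poisoned$dsc[30:50] <- 9999  # sentinel values beyond the point being forecast
  expect_identical(predict_one_step(fc, cv, 30), predict_one_step(fc, poisoned, 30))
  fcf <- fit_forecaster(cv, forecaster_spec("bi_full_step", epochs = 100, seed = 6), 0.5)
  expect_identical(
    predict_full_step(fcf, cv[1:25, ], 10, future_ratios = cv$data_ratio[26:35]),
    predict_full_step(fcf, poisoned[1:25, ], 10, future_ratios = cv$data_ratio[26:35]))
})

test_that("evaluation tables mirror the variants-by-depth layout", {
  cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0),
                                 ratio_ladder(0.1, 1, 0.1), 3:6, seed = 7)
  specs <- lapply(c("uni_one_step", "uni_full_step", "bi_one_step", "bi_full_step"),
                  function(v) forecaster_spec(v, window = 3, epochs = 40, seed = 7))
  evals <- evaluate_forecasters(cv, specs, observed_fraction = 0.5)
  tab <- forecast_evaluation_table(evals)
  expect_equal(dim(tab), c(4, 5))  # 4 variants x (depths 3..6 + Average)
  expect_equal(colnames(tab), c("3", "4", "5", "6", "Average"))
  expect_match(tab[1, 1], "\\d\\.\\d{4} ± \\d\\.\\d{4}")
  for (e in evals) {
    expect_equal(e$per_depth$depth, 3:6)
    expect_true(all(e$per_depth$mae_mean >= 0))
    expect_equal(sum(e$per_depth$n), unname(e$overall[["n"]]))
  }
})

test_that("a perfect-oracle forecaster scores zero MAE everywhere", {
  cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0),
                                 ratio_ladder(0.1, 1, 0.1), c(3, 4), seed = 8)
  per <- lapply(dicecast:::split_curves(cv), function(c1) {
    err <- abs(c1$dsc[6:10] - c1$dsc[6:10])
    mae_stats(c1$dsc[6:10], c1$dsc[6:10])
  })
  for (p in per) expect_equal(unname(p), c(0, 0))
})

test_that("recurrent variants beat constant-last-value persistence on noisy curves", {
  lad <- ratio_ladder(0.02, 1, 0.02)
  variants <- c("uni_one_step", "uni_full_step", "bi_one_step", "bi_full_step")
  wins <- matrix(NA, 3, length(variants), dimnames = list(NULL, variants))
  for (s in 1:3) {
    cv <- simulate_learning_curves(curve_family_spec(noise_sd = 0.01), lad, 3:6,
                                   seed = 100 + s)
    cs <- dicecast:::split_curves(cv)
    naive <- mean(vapply(cs, function(c1) mean(abs(c1$dsc[25] - c1$dsc[26:50])),
                         numeric(1)))
    evals <- evaluate_forecasters(cv,
      specs = lapply(variants, function(v) forecaster_spec(v, seed = s)),
      observed_fraction = 0.5)
    for (e in evals) wins[s, e$variant] <- e$overall[["mae_mean"]] < naive
  }
  expect_true(all(wins))
})
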