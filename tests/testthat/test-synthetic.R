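test_that("2D generator: shapes, ranges, blob fraction bounds, determinism", {
  expect_length(synth_seg_2d(0, 64), 0)
  s <- synth_seg_2d(100, 64, difficulty = 0.5, seed = 21)
  fracs <- vapply(s, function(x) mean(x$mask), numeric(1))
  expect_true(all(fracs >= 0.02 & fracs <= 0.40))
  expect_true(all(vapply(s, function(x) all(x$pixels >= 0 & x$pixels <= 1), logical(1))))
  expect_true(all(vapply(s, function(x) all(x$mask %in% c(0, 1)), logical(1))))
  expect_equal(dim(s[[1]]$pixels), c(64, 64, 3))
  s2 <- synth_seg_2d(100, 64, difficulty = 0.5, seed = 21)
  expect_identical(s, s2)  # bit-identical under the same seed
  expect_error(synth_seg_2d(5, 8), "too small")
})

test_that("3D generator: 4 channels, nonempty compact lesions, determinism", {
  expect_length(synth_seg_3d(0, 32), 0)
  s <- synth_seg_3d(20, 32, seed = 5)
  expect_equal(dim(s[[1]]$pixels), c(32, 32, 32, 4))
  expect_true(all(vapply(s, function(x) sum(x$mask) > 0, logical(1))))
  expect_true(all(vapply(s, function(x) all(x$pixels >= 0 & x$pixels <= 1), logical(1))))
  expect_identical(s, synth_seg_3d(20, 32, seed = 5))
})

test_that("curve simulator matches its closed form and is monotone when noiseless", {
  spec <- curve_family_spec(d_inf = 0.9, d0 = 0.3, tau = 0.2, noise_sd = 0)
  lad <- ratio_ladder(0.2, 1, 0.2)
  cv <- simulate_learning_curves(spec, lad, 3, seed = 1)
  expect_equal(cv$dsc[1], 0.9 - 0.6 * exp(-1), tolerance = 1e-12)
  expect_true(all(diff(cv$dsc) > 0))
  # asymptote: large multiples of tau approach d_inf (+ depth shift)
  expect_equal(curve_family_value(spec, 50 * 0.2), 0.9, tolerance = 1e-9)
  sp2 <- curve_family_spec(depth_effect = 0.05)
  cvs <- simulate_learning_curves(curve_family_spec(noise_sd = 0, depth_effect = 0.05),
                                  lad, c(3, 5), seed = 1)
  expect_true(all(cvs$dsc <= 0.87 + 0.05 * 2 + 1e-12))
  expect_error(curve_family_spec(d_inf = 0.5, d0 = 0.6), "d0 <= d_inf")
  expect_error(curve_family_spec(tau = 0), "tau")
})

test_that("2D datasets round-trip through PNG + manifest", {
  s <- synth_seg_2d(3, 16, seed = 2)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(s, dir)
  back <- read_dataset(manifest)
  expect_length(back, 3)
  expect_identical(back[[2]]$sample_id, s[[2]]$sample_id)
  expect_identical(back[[2]]$mask, s[[2]]$mask)
  # PNG stores 8/16-bit samples; pixels agree to quantization error
  expect_lt(max(abs(back[[2]]$pixels - s[[2]]$pixels)), 1 / 255)
})

test_that("3D datasets round-trip through NIfTI + manifest", {
  s <- synth_seg_3d(2, 16, seed = 3)
  dir <- withr::local_tempdir()
  back <- read_dataset(write_dataset(s, dir))
  expect_equal(back[[1]]$mask, s[[1]]$mask)
  expect_equal(back[[1]]$pixels, s[[1]]$pixels, tolerance = 1e-6)
})

test_that("curve CSV schema round-trips", {
  cv <- simulate_learning_curves(curve_family_spec(), ratio_ladder(0.5, 1, 0.5),
                                 c(3, 4), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(cv, f)
  back <- read_curves_csv(f)
  expect_equal(back$dsc, cv$dsc)
  expect_equal(back$param_count, cv$param_count)
  writeLines("a,b\n1,2", f)
  expect_error(read_curves_csv(f), "lacks columns")
})
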