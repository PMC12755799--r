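test_that("parameter counts match an independent closed-form tally", {
  # depth-2 2D model, base width w, stem s, in 3 channels, written out by hand:
  # stem 3x3 conv + BN; one strided residual transition (s -> 2w) with
  # projection; mirrored transposed-conv (3x3) + residual decoder block on
  # the 2s concat; 1x1 head with bias.
  by_hand <- function(w, s) {
    stem <- 9 * 3 * s + 2 * s
    enc <- 9 * s * (2 * w) + 2 * (2 * w) + 9 * (2 * w)^2 + 2 * (2 * w) +
      s * (2 * w) + 2 * (2 * w)
    up <- 9 * (2 * w) * s + 2 * s
    dec <- 9 * (2 * s) * s + 2 * s + 9 * s^2 + 2 * s + (2 * s) * s + 2 * s
    head <- s + 1
    stem + enc + up + dec + head
  }
  for (ws in list(c(2, 2), c(4, 3), c(8, 7))) {
    spec <- unet_spec(2, dims = 2, base_width = ws[1], stem_width = ws[2])
    expect_equal(unet_param_count(spec), by_hand(ws[1], ws[2]))
    expect_equal(count_parameters(build_unet(spec, seed = 1)), by_hand(ws[1], ws[2]))
  }
  # a single 3x3 conv, 3 -> 8 channels with bias, would have 3*3*3*8 + 8 = 224
  # scalars; our convs are bias-free (BN follows), so the conv weight alone is 216
  spec <- unet_spec(2, dims = 2, base_width = 4, stem_width = 8)
  m <- build_unet(spec, seed = 1)
  expect_equal(length(m$params$stem.w), 3 * 3 * 3 * 8)
  expect_equal(3 * 3 * 3 * 8 + 8, 224)
})

test_that("forward pass preserves spatial shape and emits probabilities", {
  spec <- unet_spec(3, dims = 2, base_width = 2, stem_width = 2)
  m <- build_unet(spec, seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- unet_forward(m, x)
  expect_equal(dim(out$probs), c(64, 64, 1, 1))
  expect_true(all(out$probs > 0 & out$probs < 1))
  # depth-4 on 256x256 keeps the input spatial shape
  spec4 <- unet_spec(4, dims = 2, base_width = 2, stem_width = 2)
  m4 <- build_unet(spec4, seed = 2)
  out4 <- unet_forward(m4, array(runif(256 * 256 * 3), c(256, 256, 3)))
  expect_equal(dim(out4$probs)[1:2], c(256, 256))
})

test_that("indivisible input sizes fail with an explanatory message", {
  m <- build_unet(unet_spec(4, dims = 2, base_width = 2, stem_width = 2), seed = 1)
  expect_error(unet_forward(m, array(0.5, c(60, 60, 3))),
               "divisible by 2\\^\\(depth-1\\) = 8")
  expect_error(unet_forward(m, array(0.5, c(64, 64, 5))), "input channels")
})

test_that("weight initialization is seed-deterministic", {
  spec <- unet_spec(3, dims = 2, base_width = 3, stem_width = 3)
  expect_identical(build_unet(spec, seed = 9)$params, build_unet(spec, seed = 9)$params)
  expect_false(identical(build_unet(spec, seed = 9)$params,
                         build_unet(spec, seed = 10)$params))
})

test_that("3D variant mirrors the 2D one at the same channel schedule", {
  spec <- unet_spec(3, dims = 3, base_width = 2, stem_width = 2)
  m <- build_unet(spec, seed = 1)
  x <- array(runif(16^3 * 4), c(16, 16, 16, 4))
  out <- unet_forward(m, x)
  expect_equal(dim(out$probs), c(16, 16, 16, 1, 1))
  expect_true(all(out$probs > 0 & out$probs < 1))
  # same layer names as 2D, kernels are k^3 instead of k^2
  s2 <- unet_spec(3, dims = 2, base_width = 2, stem_width = 2)
  expect_identical(names(build_unet(s2, 1)$params), names(m$params))
})

test_that("calibrated family prints the documented widths", {
  spec <- unet_spec(3)
  expect_equal(spec$base_width, 109L)
  expect_equal(spec$stem_width, 97L)
  out <- capture.output(print(build_unet(unet_spec(3, base_width = 2, stem_width = 2),
                                         seed = 1)))
  expect_match(out[1], "depth 3")
})
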