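test_that("a segmenter overfits a single sample (training smoke test)", {
  s <- synth_seg_2d(1, size = 32, difficulty = 0.3, seed = 7)
  model <- build_unet(unet_spec(3, base_width = 4, stem_width = 4), seed = 1)
  tr <- train_segmenter(model, s, hyper = tiny_hyper(base_width = 4, max_epochs = 120,
                                                     lr = 1e-2), seed = 1)
  expect_false(tr$record$failed)
  expect_gte(evaluate_segmenter(tr$model, s)$dsc, 0.95)
})

test_that("training is deterministic for a fixed seed and rejects empty subsets", {
  s <- synth_seg_2d(4, size = 16, seed = 3)
  model <- build_unet(unet_spec(3, base_width = 2, stem_width = 2), seed = 5)
  t1 <- train_segmenter(model, s, hyper = tiny_hyper(), seed = 11)
  t2 <- train_segmenter(model, s, hyper = tiny_hyper(), seed = 11)
  expect_identical(t1$record$final_train_loss, t2$record$final_train_loss)
  expect_identical(t1$model$params, t2$model$params)
  expect_error(train_segmenter(model, list(), hyper = tiny_hyper()), "empty")
})

test_that("evaluation equals the pooled-pixel oracle and honors conventions", {
  s <- synth_seg_2d(2, size = 16, seed = 13)
  # a mock model that returns the ground truth exactly -> all metrics 1
  truth_fun <- function(x) {
    n <- dim(x)[4]
    out <- array(0, c(16, 16, 1, n))
    for (j in seq_len(n)) out[, , 1, j] <- s[[j]]$mask
    out
  }
  m <- evaluate_segmenter(truth_fun, s)
  expect_equal(c(m$iou, m$dsc, m$recall, m$precision), rep(1, 4))
  # all-zero predictions against nonempty truths -> recall 0
  zero_fun <- function(x) array(0, c(16, 16, 1, dim(x)[4]))
  expect_equal(evaluate_segmenter(zero_fun, s)$recall, 0)
  # hand-built oracle: pooled counts by direct tally over both images
  half_fun <- function(x) {
    out <- truth_fun(x)
    out[1:8, , , ] <- 0  # drop the top half of each prediction
    out
  }
  m2 <- evaluate_segmenter(half_fun, s)
  tp <- fp <- fn <- 0
  for (j in 1:2) {
    pr <- s[[j]]$mask; pr[1:8, ] <- 0
    tp <- tp + sum(pr & s[[j]]$mask)
    fp <- fp + sum(pr & !s[[j]]$mask)
    fn <- fn + sum(!pr & s[[j]]$mask)
  }
  expect_equal(m2$dsc, 2 * tp / (2 * tp + fp + fn))
  expect_equal(m2$precision, ifelse(tp + fp == 0, 0, tp / (tp + fp)))
  # pooled metrics satisfy the dsc/iou identity exactly
  expect_equal(m2$dsc, 2 * m2$iou / (1 + m2$iou), tolerance = 1e-12)
})

test_that("per-image aggregation averages per-sample metrics", {
  s <- synth_seg_2d(3, size = 16, seed = 17)
  truth_fun <- function(x) {
    n <- dim(x)[4]
    out <- array(0, c(16, 16, 1, n))
    for (j in seq_len(n)) out[, , 1, j] <- s[[j]]$mask
    out
  }
  m <- evaluate_segmenter(truth_fun, s, aggregate = "per_image", batch_size = 3)
  expect_equal(m$dsc, 1)
})

test_that("run_grid yields one record per cell and resumes exactly", {
  samples <- synth_seg_2d(30, size = 16, seed = 23)
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  split <- partition_dataset(names(samples), c(0.6, 0.2, 0.2), seed = 23)
  grid <- training_grid(ratio_ladder(1 / 3, 1, 1 / 3), c(2, 3), base_seed = 23,
                        train_pool_size = length(split$train_ids))
  hy <- tiny_hyper(max_epochs = 1L)
  dir_full <- withr::local_tempdir()
  full <- run_grid(grid, samples, split, hy, out_dir = dir_full)
  expect_equal(nrow(full$curves), 6)
  expect_length(full$records, 6)
  expect_equal(as.vector(table(full$curves$depth)), c(3L, 3L))
  expect_true(all(full$curves$dsc >= 0 & full$curves$dsc <= 1))
  expect_true(all(full$curves$iou >= 0 & full$curves$iou <= 1))
  # dsc/iou identity on every pooled record
  expect_equal(full$curves$dsc, 2 * full$curves$iou / (1 + full$curves$iou),
               tolerance = 1e-9)

  # interrupted after 2 cells, then resumed: records match the single run
  dir_part <- withr::local_tempdir()
  part <- run_grid(grid, samples, split, hy, out_dir = dir_part, max_cells = 2)
  expect_length(part$records, 2)
  resumed <- run_grid(grid, samples, split, hy, out_dir = dir_part)
  expect_equal(resumed$curves, full$curves)

  # resuming against a different grid is refused
  other <- training_grid(ratio_ladder(0.5, 1, 0.5), c(2, 3), base_seed = 99,
                         train_pool_size = length(split$train_ids))
  expect_error(run_grid(other, samples, split, hy, out_dir = dir_part),
               "hash mismatch")
})

test_that("a 3D grid cell trains end to end", {
  samples <- synth_seg_3d(8, size = 16, seed = 29)
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  split <- partition_dataset(names(samples), c(0.5, 0.25, 0.25), seed = 29)
  grid <- training_grid(ratio_ladder(1, 1, 1), 2, base_seed = 29,
                        train_pool_size = length(split$train_ids))
  hy <- tiny_hyper(max_epochs = 1L, batch_size = 2L)
  res <- run_grid(grid, samples, split, hy)
  expect_equal(nrow(res$curves), 1)
  expect_false(res$records[[1]]$failed)
  expect_true(res$curves$dsc >= 0 && res$curves$dsc <= 1)
})
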