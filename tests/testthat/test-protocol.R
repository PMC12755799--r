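test_that("ratio ladders have the documented length, endpoints and errors", {
  lad <- ratio_ladder(0.02, 1, 0.02)
  expect_length(lad, 50)
  expect_equal(lad[1], 0.02)
  expect_equal(lad[50], 1)
  expect_true(all(diff(lad) > 0))

  expect_length(ratio_ladder(0.05, 1, 0.05), 20)
  expect_equal(as.numeric(ratio_ladder(1, 1, 0.05)), 1)  # degenerate single point

  expect_error(ratio_ladder(0.03, 1, 0.02), "not an integer multiple")
  expect_error(ratio_ladder(0, 1, 0.02), "0 < start")
  expect_error(ratio_ladder(0.5, 1.2, 0.1), "stop <= 1")
})

test_that("grid cardinality is |depths| x |ratios| and ordering is depth-major", {
  g <- training_grid(ratio_ladder(0.02, 1, 0.02), 3:6, train_pool_size = 700)
  expect_equal(nrow(g), 200)
  expect_equal(nrow(training_grid(ratio_ladder(0.05, 1, 0.05), c(3, 5))), 40)
  expect_equal(nrow(training_grid(ratio_ladder(1, 1, 0.1), 3)), 1)
  # depth-major, ratio-ascending
  expect_equal(g$depth, rep(3:6, each = 50))
  expect_true(all(tapply(g$data_ratio, g$depth, function(r) all(diff(r) > 0))))
  # per-cell seeds are deterministic and within integer range
  g2 <- training_grid(ratio_ladder(0.02, 1, 0.02), 3:6, train_pool_size = 700)
  expect_identical(g, g2)
  expect_true(all(g$seed >= 0 & g$seed < 2^31))
  expect_error(training_grid(ratio_ladder(0.1, 1, 0.1), integer(0)), "empty")
})

test_that("largest-remainder partition reproduces the reference split sizes", {
  s <- partition_dataset(seq_len(1000), c(0.70, 0.10, 0.20), seed = 1)
  expect_equal(lengths(s), c(train_ids = 700, val_ids = 100, test_ids = 200))
  s2 <- partition_dataset(seq_len(369), c(0.70, 0.10, 0.20), seed = 1)
  expect_equal(lengths(s2), c(train_ids = 258, val_ids = 37, test_ids = 74))
  s3 <- partition_dataset(seq_len(10), c(1, 0, 0), seed = 1)
  expect_equal(lengths(s3), c(train_ids = 10, val_ids = 0, test_ids = 0))
})

test_that("partitions are disjoint, exhaustive and seed-reproducible", {
  for (n in c(37, 100, 369)) {
    s <- partition_dataset(seq_len(n), c(0.6, 0.15, 0.25), seed = n)
    all_ids <- c(s$train_ids, s$val_ids, s$test_ids)
    expect_equal(sort(all_ids), seq_len(n))
    expect_equal(anyDuplicated(all_ids), 0)
    expect_identical(s, partition_dataset(seq_len(n), c(0.6, 0.15, 0.25), seed = n))
  }
  expect_error(partition_dataset(1:2, c(0.4, 0.3, 0.3), 1), "cannot fill")
  expect_error(partition_dataset(1:10, c(0.5, 0.2, 0.2), 1), "sum to")
})

test_that("subsets are nested prefixes with round-half-up sizes", {
  ids <- sprintf("s%03d", 1:700)
  expect_identical(subset_indices(ids, 1, seed = 5), ids)
  expect_length(subset_indices(ids, 0.02, seed = 5), 14)
  expect_length(subset_indices(1:3, 0.01, seed = 5), 1)  # floor of one sample
  for (seed in c(1, 99, 12345)) {
    s10 <- subset_indices(ids, 0.10, seed = seed)
    s50 <- subset_indices(ids, 0.50, seed = seed)
    s100 <- subset_indices(ids, 1.00, seed = seed)
    expect_true(all(s10 %in% s50))
    expect_true(all(s50 %in% s100))
  }
  expect_error(subset_indices(character(0), 0.5, 1), "empty")
  expect_error(subset_indices(ids, 0, 1), "in \\(0, 1\\]")
})

test_that("grids round-trip through JSON with their hash", {
  g <- training_grid(ratio_ladder(0.25, 1, 0.25), c(3, 4), train_pool_size = 20)
  split <- partition_dataset(sprintf("id%02d", 1:20), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_grid_json(g, f, split = split)
  back <- read_grid_json(f)
  expect_equal(back$grid$depth, g$depth)
  expect_equal(back$grid$data_ratio, g$data_ratio)
  expect_setequal(back$split$train_ids, split$train_ids)
})
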