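#' Build a ladder of training-data ratios
#'
#' The experiment grid samples the training pool at a regular ladder of
#' data ratios, e.g. from 2% to 100% at 2% intervals (50 ratios) for a 2D
#' task, or 5% to 100% at 5% intervals (20 ratios) for a heavier 3D task.
#'
#' @param start,stop,step Fractions in (0, 1]; `stop - start` must be an
#'   integer multiple of `step` (tolerance 1e-9).
#' @return Numeric vector of class `ratio_ladder`, strictly increasing,
#'   ending at `stop`.
#' @examples
#' length(ratio_ladder(0.02, 1, 0.02))  # 50
#' @export
ratio_ladder <- function(start, stop = 1, step = start) {
  if (!is_scalar_number(start) || !is_scalar_number(stop) || !is_scalar_number(step))
    stop_config("ratio_ladder: start, stop, step must be finite scalars")
  if (start <= 0 || stop > 1 || start > stop)
    stop_config("ratio_ladder: need 0 < start <= stop <= 1, got (%g, %g)", start, stop)
  if (step <= 0) stop_config("ratio_ladder: step must be positive, got %g", step)
  span <- (stop - start) / step
  if (abs(span - round(span)) > 1e-9)
    stop_config("ratio_ladder: span of (%g, %g, %g) is not an integer multiple of step",
                start, stop, step)
  n <- as.integer(round(span)) + 1L
  r <- start + step * (seq_len(n) - 1L)
  r[n] <- stop  # exact endpoint, no accumulated float error
  structure(r, class = "ratio_ladder")
}

#' Enumerate the training-configuration grid
#'
#' One configuration per (depth, data ratio) cell, ordered depth-major then
#' ratio-ascending. Each cell gets its own reproducible seed derived from
#' `base_seed`. Subset sizes use round-half-up with a floor of one sample.
#'
#' @param ladder A [ratio_ladder()].
#' @param depths Integer vector of U-Net depths (all >= 1, nonempty).
#' @param task_id Character label for the task.
#' @param base_seed Integer base seed.
#' @param train_pool_size Optional training-pool size used to fill in
#'   `subset_size`; `NA` sizes if omitted.
#' @return A data.frame with columns task_id, depth, data_ratio,
#'   ratio_index, subset_size, seed.
#' @examples
#' nrow(training_grid(ratio_ladder(0.02, 1, 0.02), depths = 3:6))  # 200
#' @export
training_grid <- function(ladder, depths, task_id = "task", base_seed = 0L,
                          train_pool_size = NULL) {
  stopifnot(inherits(ladder, "ratio_ladder") || is.numeric(ladder))
  if (length(depths) == 0L) stop_config("training_grid: depth list is empty")
  if (any(depths < 1)) stop_config("training_grid: depths must all be >= 1")
  cells <- expand.grid(ratio_index = seq_along(ladder), depth = as.integer(depths),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$depth, cells$ratio_index), , drop = FALSE]
  n_pool <- if (is.null(train_pool_size)) NA_integer_ else as.integer(train_pool_size)
  data.frame(
    task_id = task_id,
    depth = cells$depth,
    data_ratio = as.numeric(ladder)[cells$ratio_index],
    ratio_index = cells$ratio_index,
    subset_size = if (is.na(n_pool)) NA_integer_ else
      pmax(1L, as.integer(round_half_up(as.numeric(ladder)[cells$ratio_index] * n_pool))),
    seed = vapply(seq_len(nrow(cells)), function(i)
      cell_seed(base_seed, cells$depth[i], cells$ratio_index[i]), numeric(1)),
    row.names = NULL
  )
}

#' Partition sample ids into train / validation / test splits
#'
#' Sizes follow largest-remainder apportionment of `fractions`, so e.g.
#' 1000 ids at (0.70, 0.10, 0.20) give (700, 100, 200) and 369 ids give
#' (258, 37, 74). Assignment is a seeded shuffle and fully reproducible.
#'
#' @param ids Vector of sample identifiers.
#' @param fractions Length-3 nonnegative vector (train, val, test) summing
#'   to 1 within 1e-9.
#' @param seed Integer seed driving the shuffle.
#' @return List with elements `train_ids`, `val_ids`, `test_ids`.
#' @export
partition_dataset <- function(ids, fractions = c(0.70, 0.10, 0.20), seed = 0L) {
  if (length(fractions) != 3L || any(fractions < 0))
    stop_config("partition_dataset: fractions must be 3 nonnegative numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_config("partition_dataset: fractions sum to %g, not 1", sum(fractions))
  n <- length(ids)
  if (n < sum(fractions > 0))
    stop_config("partition_dataset: %d ids cannot fill %d nonzero groups",
                n, sum(fractions > 0))
  sizes <- largest_remainder(n, fractions)
  perm <- with_seed(seed, sample.int(n))
  shuffled <- ids[perm]
  bounds <- cumsum(sizes)
  list(
    train_ids = shuffled[seq_len(sizes[1])],
    val_ids = if (sizes[2] > 0) shuffled[(bounds[1] + 1):bounds[2]] else ids[0],
    test_ids = if (sizes[3] > 0) shuffled[(bounds[2] + 1):bounds[3]] else ids[0]
  )
}

# Largest-remainder apportionment of n into groups proportional to fractions.
# Ties in remainders are broken by group order (earlier group first).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    rem <- exact - base
    take <- order(-rem, seq_along(fractions))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Nested training subsets at a given data ratio
#'
#' A single seeded permutation of the training pool is drawn and subsets are
#' taken as prefixes of it, so `subset_indices(ids, r1, s)` is always
#' contained in `subset_indices(ids, r2, s)` for `r1 <= r2`. Nesting makes
#' learning curves comparable across ratios: a larger subset strictly adds
#' samples rather than resampling.
#'
#' @param train_ids Nonempty vector of pool identifiers.
#' @param data_ratio Fraction in (0, 1].
#' @param seed Integer seed for the pool permutation.
#' @return Subset of `train_ids` of size `max(1, round_half_up(ratio * n))`.
#' @export
subset_indices <- function(train_ids, data_ratio, seed = 0L) {
  n <- length(train_ids)
  if (n == 0L) stop_config("subset_indices: empty training pool")
  if (!is_scalar_number(data_ratio) || data_ratio <= 0 || data_ratio > 1)
    stop_config("subset_indices: data_ratio must be in (0, 1], got %g", data_ratio)
  if (data_ratio == 1) return(train_ids)
  m <- max(1L, as.integer(round_half_up(data_ratio * n)))
  perm <- with_seed(seed, sample.int(n))
  train_ids[perm[seq_len(m)]]
}

#' Serialize a training grid (with split) to JSON
#'
#' @param grid A data.frame from [training_grid()].
#' @param split Optional list from [partition_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grid, path, split = NULL) {
  obj <- list(grid = grid, grid_hash = hash_object(grid))
  if (!is.null(split)) obj$split <- split
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$grid <- as.data.frame(obj$grid)
  obj
}
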