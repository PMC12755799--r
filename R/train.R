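# Training engine: pixel-wise binary cross-entropy, Adam, early stopping on
# validation Dice, and the grid runner that assembles learning curves.

#' Default training hyperparameters
#'
#' @param dims Spatial rank of the task (2 or 3).
#' @return List with `lr`, `batch_size`, `max_epochs`, `patience`,
#'   `base_width`, `stem_width`, `threshold`.
#' @export
default_hyper <- function(dims = 2) {
  list(lr = 1e-3, batch_size = if (dims == 2) 8L else 2L,
       max_epochs = 30L, patience = 10L,
       base_width = 4L, stem_width = 4L, threshold = 0.5)
}

# stack a list of samples into (spatial..., C, N) and (spatial..., 1, N)
batch_pixels <- function(samples) {
  d <- dim(samples[[1]]$pixels)
  out <- array(0, c(d, length(samples)))
  for (i in seq_along(samples)) {
    out[seq_len(prod(d)) + (i - 1) * prod(d)] <- samples[[i]]$pixels
  }
  out
}

batch_masks <- function(samples) {
  d <- dim(samples[[1]]$mask)
  out <- array(0, c(d, 1L, length(samples)))
  for (i in seq_along(samples)) {
    out[seq_len(prod(d)) + (i - 1) * prod(d)] <- samples[[i]]$mask
  }
  out
}

# numerically stable mean BCE from logits, and its gradient
bce_with_logits <- function(logits, y) {
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  mean(sp - y * logits)
}

bce_grad <- function(logits, y) (sigmoid(logits) - y) / length(y)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a segmenter on a training subset
#'
#' Minimizes mean pixel-wise binary cross-entropy with Adam. After every
#' epoch the validation Dice (pooled, threshold 0.5) is computed; training
#' stops early when it has not improved for `patience` epochs and the
#' best-validation weights are returned. A non-finite loss aborts the run
#' and flags the record as failed rather than raising.
#'
#' @param model A built [build_unet()] model.
#' @param samples Nonempty list of training samples.
#' @param val_samples Validation samples (may be empty; then the final
#'   epoch's weights are returned).
#' @param hyper Hyperparameter list, see [default_hyper()].
#' @param seed Integer seed for shuffling.
#' @return List with `model` (trained) and `record` (epochs_run,
#'   final_train_loss, best_val_dsc, failed, wall_seconds).
#' @export
train_segmenter <- function(model, samples, val_samples = list(),
                            hyper = default_hyper(model$spec$dims), seed = 0L) {
  if (length(samples) == 0L) stop_config("train_segmenter: empty training subset")
  t0 <- proc.time()[["elapsed"]]
  n <- length(samples)
  bs <- min(hyper$batch_size, n)
  dims <- model$spec$dims
  xall <- batch_pixels(samples)   # stacked once; batches are slices
  yall <- batch_masks(samples)
  state <- adam_init(model$params)
  best <- list(dsc = -Inf, params = model$params, bn = model$bn, epoch = 0L)
  wait <- 0L; failed <- FALSE; last_loss <- NA_real_; epochs_run <- 0L
  with_seed(seed, {
    for (epoch in seq_len(hyper$max_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1, n)]
        x <- slice_batch(xall, idx, dims)
        y <- slice_batch(yall, idx, dims)
        fwd <- unet_forward(model, x, train = TRUE, cache = TRUE)
        model$bn <- fwd$bn
        loss <- bce_with_logits(fwd$logits, y)
        if (!is.finite(loss)) { failed <- TRUE; break }
        grads <- unet_backward(model, fwd$cache, bce_grad(fwd$logits, y))
        upd <- adam_step(model$params, grads, state, hyper$lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      if (failed) break
      epochs_run <- epoch
      last_loss <- ep_loss / nb
      if (length(val_samples) > 0) {
        vm <- evaluate_segmenter(model, val_samples, threshold = hyper$threshold,
                                 batch_size = bs)
        if (vm$dsc > best$dsc + 1e-9) {
          best <- list(dsc = vm$dsc, params = model$params, bn = model$bn,
                       epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= hyper$patience) break
        }
      }
    }
  })
  if (length(val_samples) > 0 && is.finite(best$dsc)) {
    model$params <- best$params; model$bn <- best$bn
  }
  list(model = model,
       record = list(epochs_run = epochs_run, final_train_loss = last_loss,
                     best_val_dsc = if (is.finite(best$dsc)) best$dsc else NA_real_,
                     failed = failed,
                     wall_seconds = proc.time()[["elapsed"]] - t0))
}

#' Evaluate a segmenter on a test set
#'
#' Sigmoid outputs are binarized at `threshold` and compared to the ground
#' truth. By default the confusion counts are pooled over all test voxels
#' (micro-average), which makes the identity dsc = 2 iou / (1 + iou) exact;
#' `aggregate = "per_image"` instead averages per-image metrics.
#'
#' @param model A `dicecast_unet`, or a function mapping a pixel batch
#'   (spatial..., C, N) to probabilities (spatial..., 1, N).
#' @param test_samples Nonempty list of samples.
#' @param threshold Binarization threshold for the probabilities.
#' @param aggregate "pooled" (default) or "per_image".
#' @param batch_size Forward-pass batch size.
#' @return List with iou, dsc, recall, precision (and pooled counts).
#' @export
evaluate_segmenter <- function(model, test_samples, threshold = 0.5,
                               aggregate = c("pooled", "per_image"),
                               batch_size = 8L) {
  aggregate <- match.arg(aggregate)
  if (length(test_samples) == 0L) stop_config("evaluate_segmenter: empty test set")
  fwd_fun <- if (is.function(model)) model else
    function(x) unet_forward(model, x, train = FALSE)$probs
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  per <- list()
  n <- length(test_samples)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    probs <- fwd_fun(batch_pixels(test_samples[idx]))
    pred <- (probs >= threshold) * 1
    y <- batch_masks(test_samples[idx])
    if (aggregate == "pooled") {
      counts <- counts + confusion_counts(pred, y)
    } else {
      nd <- length(dim(pred))
      for (j in seq_along(idx)) {
        pj <- index_last(pred, j); yj <- index_last(y, j)
        per[[length(per) + 1]] <- metrics_from_counts(confusion_counts(pj, yj))
      }
    }
  }
  if (aggregate == "pooled") {
    metrics_from_counts(counts)
  } else {
    list(iou = mean(vapply(per, `[[`, numeric(1), "iou")),
         dsc = mean(vapply(per, `[[`, numeric(1), "dsc")),
         recall = mean(vapply(per, `[[`, numeric(1), "recall")),
         precision = mean(vapply(per, `[[`, numeric(1), "precision")))
  }
}

index_last <- function(x, j) {
  d <- dim(x)
  if (length(d) == 4) x[, , , j, drop = FALSE] else x[, , , , j, drop = FALSE]
}

slice_batch <- function(x, idx, dims) {
  if (dims == 2) x[, , , idx, drop = FALSE] else x[, , , , idx, drop = FALSE]
}

#' Run the full training grid and assemble learning curves
#'
#' Trains one segmenter per grid configuration (nested subset of the train
#' pool, seeded per cell), evaluates it on the test split, and appends each
#' record to `out_dir/records.jsonl` as it completes, so an interrupted
#' grid resumes from the last finished cell. Resuming against a different
#' grid is refused via a stored grid hash.
#'
#' @param grid Data.frame from [training_grid()].
#' @param samples Named list of samples (names = sample ids) covering the
#'   split.
#' @param split List from [partition_dataset()].
#' @param hyper See [default_hyper()].
#' @param out_dir Directory for incremental records (NULL = in-memory only).
#' @param max_cells Run at most this many new cells (useful for batched or
#'   interrupted runs); remaining cells are left for a later resume.
#' @return List with `curves` (a `learning_curves` data.frame carrying all
#'   four metrics) and `records` (one list per configuration).
#' @export
run_grid <- function(grid, samples, split, hyper = default_hyper(),
                     out_dir = NULL, max_cells = Inf) {
  if (nrow(grid) == 0L) stop_config("run_grid: empty grid")
  missing_ids <- setdiff(c(split$train_ids, split$val_ids, split$test_ids),
                         names(samples))
  if (length(missing_ids))
    stop_config("run_grid: %d split ids missing from samples (first: %s)",
                length(missing_ids), missing_ids[1])
  ghash <- hash_object(grid[, c("task_id", "depth", "data_ratio", "seed")])
  done <- list()
  rec_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hash_path <- file.path(out_dir, "grid_hash.txt")
    rec_path <- file.path(out_dir, "records.jsonl")
    if (file.exists(hash_path)) {
      if (!identical(readLines(hash_path)[1], unname(ghash)))
        stop_config(paste0("run_grid: %s holds records for a different grid ",
                           "(hash mismatch); refusing to resume"), out_dir)
      if (file.exists(rec_path)) {
        done <- lapply(readLines(rec_path), jsonlite::fromJSON)
      }
    } else writeLines(unname(ghash), hash_path)
  }
  done_keys <- vapply(done, function(r) paste(r$depth, r$ratio_index), character(1))
  records <- done
  dims <- length(dim(samples[[split$train_ids[1]]]$mask))
  val <- samples[split$val_ids]
  test <- samples[split$test_ids]
  new_cells <- 0L
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$depth[i], grid$ratio_index[i])
    if (key %in% done_keys) next
    if (new_cells >= max_cells) break
    cfg_seed <- grid$seed[i]
    ids <- subset_indices(split$train_ids, grid$data_ratio[i], seed = cfg_seed)
    spec <- unet_spec(grid$depth[i], dims = dims,
                      in_channels = dim(samples[[ids[1]]]$pixels)[dims + 1],
                      base_width = hyper$base_width, stem_width = hyper$stem_width)
    model <- build_unet(spec, seed = cfg_seed)
    tr <- train_segmenter(model, samples[ids], val, hyper, seed = cfg_seed)
    met <- if (tr$record$failed) list(iou = NA, dsc = NA, recall = NA, precision = NA)
      else evaluate_segmenter(tr$model, test, threshold = hyper$threshold,
                              batch_size = hyper$batch_size)
    rec <- list(task_id = grid$task_id[i], depth = grid$depth[i],
                data_ratio = grid$data_ratio[i], ratio_index = grid$ratio_index[i],
                subset_size = length(ids), seed = cfg_seed,
                param_count = unet_param_count(spec),
                epochs_run = tr$record$epochs_run,
                final_train_loss = tr$record$final_train_loss,
                iou = met$iou, dsc = met$dsc, recall = met$recall,
                precision = met$precision,
                failed = tr$record$failed,
                wall_seconds = tr$record$wall_seconds)
    records[[length(records) + 1]] <- rec
    new_cells <- new_cells + 1L
    if (!is.null(rec_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = rec_path, sep = "", append = TRUE)
  }
  curves <- do.call(rbind, lapply(records, function(r)
    data.frame(task_id = r$task_id, depth = r$depth, param_count = r$param_count,
               data_ratio = r$data_ratio, subset_size = r$subset_size,
               iou = null_na(r$iou), dsc = null_na(r$dsc),
               recall = null_na(r$recall), precision = null_na(r$precision),
               seed = r$seed)))
  curves <- curves[order(curves$depth, curves$data_ratio), , drop = FALSE]
  rownames(curves) <- NULL
  class(curves) <- c("learning_curves", "data.frame")
  list(curves = curves, records = records)
}

null_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
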