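#' Synthetic 2D segmentation task
#'
#' Generates endoscopy-like RGB images: a textured, noisy background with a
#' single bright, irregularly deformed elliptical blob, plus the matching
#' binary mask. Contrast and boundary sharpness decrease with `difficulty`.
#' Blob radii are drawn so that the foreground fraction of every mask stays
#' within roughly \[0.03, 0.39\] of the frame.
#'
#' @param n Number of samples (>= 0).
#' @param size Image side length in pixels (>= 16).
#' @param difficulty Level in \[0, 1\]; higher is lower contrast, softer
#'   boundaries and more noise.
#' @param seed Integer seed; output is bit-reproducible.
#' @return List of samples; each has `pixels` (size x size x 3, in \[0,1\]),
#'   `mask` (size x size, 0/1) and `sample_id`.
#' @export
synth_seg_2d <- function(n, size = 64, difficulty = 0.5, seed = 0L) {
  check_gen_args(n, size, difficulty)
  with_seed(seed, lapply(seq_len(n), function(i) {
    blob <- random_blob_2d(size, difficulty)
    bg <- texture_2d(size)
    contrast <- (0.65 - 0.35 * difficulty) * runif(1, 0.85, 1.15)
    chan_mult <- c(1, runif(1, 0.55, 0.8), runif(1, 0.35, 0.6)) # reddish blob
    soft <- blob$soft  # in [0,1], ~1 inside the blob
    px <- vapply(1:3, function(ch) {
      base <- 0.25 + 0.35 * bg * runif(1, 0.8, 1.2)
      noise <- matrix(rnorm(size^2, sd = 0.02 + 0.08 * difficulty), size, size)
      pmin(pmax(base + contrast * chan_mult[ch] * soft + noise, 0), 1)
    }, matrix(0, size, size))
    list(pixels = px, mask = blob$mask, sample_id = sprintf("s2d_%04d", i))
  }))
}

#' Synthetic 3D multi-channel segmentation task
#'
#' Generates 4-channel volumes mimicking multimodal MRI: a compact deformed
#' ellipsoidal lesion over textured background, with per-channel lesion
#' contrast of differing sign and magnitude. Every mask is nonempty.
#'
#' @inheritParams synth_seg_2d
#' @param size Volume side length in voxels (>= 16).
#' @return List of samples with `pixels` (size^3 x 4) and `mask` (size^3).
#' @export
synth_seg_3d <- function(n, size = 32, difficulty = 0.5, seed = 0L) {
  check_gen_args(n, size, difficulty)
  with_seed(seed, lapply(seq_len(n), function(i) {
    blob <- random_blob_3d(size, difficulty)
    atten <- 1 - 0.5 * difficulty
    contrasts <- c(0.45, 0.3, -0.3, 0.55) * atten *
      runif(4, 0.85, 1.15)  # lesion visibility differs per channel
    px <- vapply(1:4, function(ch) {
      base <- 0.35 + 0.1 * array(rnorm(size^3), rep(size, 3))
      base <- base + 0.15 * texture_3d(size)
      v <- base + contrasts[ch] * blob$soft +
        array(rnorm(size^3, sd = 0.02 + 0.06 * difficulty), rep(size, 3))
      pmin(pmax(v, 0), 1)
    }, array(0, rep(size, 3)))
    list(pixels = px, mask = blob$mask, sample_id = sprintf("s3d_%04d", i))
  }))
}

check_gen_args <- function(n, size, difficulty) {
  if (n < 0) stop_config("generator: n must be >= 0")
  if (size < 16) stop_config("generator: size %d too small to host the minimum blob (need >= 16)", size)
  if (difficulty < 0 || difficulty > 1) stop_config("generator: difficulty must be in [0, 1]")
}

# Deformed ellipse: polar radius r(theta) = r0 * (1 + sum a_k cos(k theta + phi_k)),
# axis-scaled. Returns binary mask and a soft (sigmoid-edged) indicator.
random_blob_2d <- function(size, difficulty) {
  r0 <- runif(1, 0.13, 0.27) * size
  ecc <- runif(1, 0.75, 1.3)
  cx <- runif(1, 0.38, 0.62) * size
  cy <- runif(1, 0.38, 0.62) * size
  amp <- runif(3, 0, 0.075 * (1 + difficulty))     # harmonics 2..4
  phi <- runif(3, 0, 2 * pi)
  xs <- matrix(seq_len(size) - cx, size, size)
  ys <- matrix(seq_len(size) - cy, size, size, byrow = TRUE)
  theta <- atan2(ys / ecc, xs * ecc)
  rr <- sqrt((xs * ecc)^2 + (ys / ecc)^2)
  rb <- r0 * (1 + amp[1] * cos(2 * theta + phi[1]) +
                amp[2] * cos(3 * theta + phi[2]) + amp[3] * cos(4 * theta + phi[3]))
  rho <- rr / rb
  width <- 0.03 + 0.12 * difficulty
  list(mask = (rho <= 1) * 1, soft = 1 / (1 + exp((rho - 1) / width)))
}

random_blob_3d <- function(size, difficulty) {
  r0 <- runif(1, 0.16, 0.3) * size
  cx <- runif(3, 0.4, 0.6) * size
  ax <- runif(3, 0.8, 1.25)
  ax <- ax / prod(ax)^(1 / 3)                       # volume-preserving axes
  amp <- runif(2, 0, 0.06 * (1 + difficulty))
  phi <- runif(2, 0, 2 * pi)
  g <- seq_len(size)
  xs <- array(rep(g - cx[1], times = size^2), rep(size, 3)) / ax[1]
  ys <- aperm(array(rep(g - cx[2], times = size^2), rep(size, 3)), c(2, 1, 3)) / ax[2]
  zs <- aperm(array(rep(g - cx[3], times = size^2), rep(size, 3)), c(3, 2, 1)) / ax[3]
  rr <- sqrt(xs^2 + ys^2 + zs^2)
  theta <- atan2(ys, xs)
  rb <- r0 * (1 + amp[1] * cos(2 * theta + phi[1]) + amp[2] * cos(3 * theta + phi[2]))
  rho <- rr / rb
  width <- 0.04 + 0.1 * difficulty
  list(mask = (rho <= 1) * 1, soft = 1 / (1 + exp((rho - 1) / width)))
}

# Smooth low-frequency texture in [0, 1] from a few random sinusoids.
texture_2d <- function(size) {
  g <- seq_len(size) / size
  tex <- matrix(0, size, size)
  for (k in 1:3) {
    f <- runif(2, 1, 4); ph <- runif(2, 0, 2 * pi)
    tex <- tex + outer(sin(2 * pi * f[1] * g + ph[1]), sin(2 * pi * f[2] * g + ph[2]))
  }
  (tex - min(tex)) / (max(tex) - min(tex) + 1e-12)
}

texture_3d <- function(size) {
  g <- seq_len(size) / size
  f <- runif(3, 1, 3); ph <- runif(3, 0, 2 * pi)
  sx <- sin(2 * pi * f[1] * g + ph[1]); sy <- sin(2 * pi * f[2] * g + ph[2])
  sz <- sin(2 * pi * f[3] * g + ph[3])
  outer(outer(sx, sy), sz)
}

#' Curve family for the learning-curve simulator
#'
#' Exponential-saturation family on the data-ratio axis: the noiseless Dice
#' value at ratio r and depth d is
#' `d_inf + depth_effect * (d - min depth) - (d_inf - d0) * exp(-r / tau)`,
#' clamped to \[0, 1\]. Ratios live in (0, 1], and empirical segmentation
#' curves visibly saturate, which this family reproduces; it is a test
#' fixture for the forecasting stage, not a scientific claim about real
#' learning curves.
#'
#' @param d_inf Asymptotic Dice in (0, 1].
#' @param d0 Small-data Dice, `0 <= d0 <= d_inf`.
#' @param tau Saturation scale in ratio units (> 0).
#' @param noise_sd Gaussian observation noise per point (>= 0).
#' @param depth_effect Additive Dice shift per depth step (applied as
#'   `depth - min(depths)`).
#' @return Object of class `curve_family_spec`.
#' @export
curve_family_spec <- function(d_inf = 0.87, d0 = 0.4, tau = 0.18,
                              noise_sd = 0.01, depth_effect = 0.02) {
  if (!(d0 >= 0 && d0 <= d_inf && d_inf <= 1))
    stop_config("curve_family_spec: need 0 <= d0 <= d_inf <= 1")
  if (tau <= 0) stop_config("curve_family_spec: tau must be > 0")
  if (noise_sd < 0) stop_config("curve_family_spec: noise_sd must be >= 0")
  structure(list(d_inf = d_inf, d0 = d0, tau = tau, noise_sd = noise_sd,
                 depth_effect = depth_effect), class = "curve_family_spec")
}

# Noiseless closed form of the family (exported for test oracles and the
# analytic plateau inversion).
#' @rdname curve_family_spec
#' @param spec A `curve_family_spec`.
#' @param r Data ratio(s).
#' @param depth,depth_min Depth of the curve and smallest depth in the family.
#' @export
curve_family_value <- function(spec, r, depth = 1, depth_min = 1) {
  v <- spec$d_inf + spec$depth_effect * (depth - depth_min) -
    (spec$d_inf - spec$d0) * exp(-r / spec$tau)
  pmin(pmax(v, 0), 1)
}

#' Simulate a family of learning curves
#'
#' Evaluates the saturating closed form of `spec` on a ratio ladder for each
#' depth and adds seeded Gaussian observation noise. Parameter counts are
#' taken from the calibrated 2D U-Net family so that downstream forecasters
#' see realistic parameter-count covariates.
#'
#' @inheritParams training_grid
#' @param spec A [curve_family_spec()].
#' @return A `learning_curves` data.frame with columns task_id, depth,
#'   param_count, data_ratio, dsc.
#' @export
simulate_learning_curves <- function(spec, ladder, depths, seed = 0L,
                                     task_id = "simulated") {
  stopifnot(inherits(spec, "curve_family_spec"))
  depths <- as.integer(depths)
  out <- with_seed(seed, do.call(rbind, lapply(depths, function(d) {
    v <- curve_family_value(spec, as.numeric(ladder), d, min(depths))
    noisy <- pmin(pmax(v + rnorm(length(v), sd = spec$noise_sd), 0), 1)
    data.frame(task_id = task_id, depth = d,
               param_count = unet_param_count(unet_spec(depth = d, dims = 2)),
               data_ratio = as.numeric(ladder), dsc = noisy)
  })))
  class(out) <- c("learning_curves", "data.frame")
  out
}

#' Read and write learning-curve tables
#'
#' CSV schema: task_id, depth, param_count, data_ratio, dsc (extra metric
#' columns from grid runs are preserved).
#'
#' @param curves A `learning_curves` data.frame.
#' @param path CSV file path.
#' @export
write_curves_csv <- function(curves, path) {
  write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("task_id", "depth", "param_count", "data_ratio", "dsc")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop_config("curves CSV %s lacks columns: %s", path,
                                paste(miss, collapse = ", "))
  class(out) <- c("learning_curves", "data.frame")
  out
}

#' Write a synthetic dataset to disk
#'
#' 2D samples become paired PNG files (image, mask) plus a JSON manifest;
#' 3D samples become one NIfTI file per channel plus a mask NIfTI.
#'
#' @param samples Output of [synth_seg_2d()] or [synth_seg_3d()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(samples, function(s) {
    nd <- length(dim(s$mask))
    if (nd == 2) {
      img <- file.path(dir, paste0(s$sample_id, "_img.png"))
      msk <- file.path(dir, paste0(s$sample_id, "_mask.png"))
      png::writePNG(aperm(s$pixels, c(1, 2, 3)), img)
      png::writePNG(s$mask, msk)
      list(sample_id = s$sample_id, dims = 2, image = basename(img), mask = basename(msk))
    } else {
      chans <- vapply(seq_len(dim(s$pixels)[4]), function(ch) {
        f <- file.path(dir, sprintf("%s_ch%d.nii.gz", s$sample_id, ch))
        RNifti::writeNifti(s$pixels[, , , ch], f)
        basename(f)
      }, character(1))
      msk <- file.path(dir, paste0(s$sample_id, "_mask.nii.gz"))
      RNifti::writeNifti(s$mask, msk)
      list(sample_id = s$sample_id, dims = 3, channels = as.list(chans),
           mask = basename(msk))
    }
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n = length(samples), samples = records), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param manifest Path to a manifest written by [write_dataset()].
#' @export
read_dataset <- function(manifest) {
  dir <- dirname(manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(m$samples, function(rec) {
    if (rec$dims == 2) {
      px <- png::readPNG(file.path(dir, rec$image))
      mk <- round(png::readPNG(file.path(dir, rec$mask)))
    } else {
      plain <- function(f) {
        a <- as.array(RNifti::readNifti(file.path(dir, f)))
        array(as.numeric(a), dim(a))  # drop NIfTI header attributes
      }
      ch <- lapply(rec$channels, plain)
      px <- array(unlist(ch), c(dim(ch[[1]]), length(ch)))
      mk <- round(plain(rec$mask))
    }
    list(pixels = px, mask = mk, sample_id = rec$sample_id)
  })
}
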