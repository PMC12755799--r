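#' Specify a residual U-Net segmenter
#'
#' The family is parameterized by `depth`, the number of encoder resolution
#' levels. A stem convolution maps the input to `stem_width` channels at
#' full resolution (level 0); each of the `depth - 1` transitions is a
#' strided residual block (two 3x3 convolutions with the stride fused into
#' the first, plus a strided 1x1 projection shortcut) that halves the
#' spatial size and moves to `base_width * 2^level` channels. The decoder
#' mirrors the encoder with 3x3 transposed convolutions and residual blocks
#' on the concatenated skip features; a 1x1 head produces per-voxel
#' foreground logits.
#'
#' The default widths (`base_width = 109`, `stem_width = 97`) are the
#' calibrated values at which the 2D family's trainable-parameter counts
#' are 6.0M, 25.6M, 103.9M and 417.2M at depths 3-6. Desk-scale experiments
#' override them (e.g. `base_width = 4`).
#'
#' @param depth Number of resolution levels (>= 2).
#' @param dims Spatial rank, 2 or 3.
#' @param in_channels Input channels (defaults: 3 for 2D, 4 for 3D).
#' @param out_channels Output channels (1 for binary masks).
#' @param base_width Channel count scale; level `i >= 1` has
#'   `base_width * 2^i` channels.
#' @param stem_width Channels at level 0; defaults to
#'   `round(0.89 * base_width)` (calibrated ratio).
#' @return Object of class `unet_spec`.
#' @export
unet_spec <- function(depth, dims = 2, in_channels = if (dims == 2) 3L else 4L,
                      out_channels = 1L, base_width = 109L, stem_width = NULL) {
  if (depth < 2) stop_config("unet_spec: depth must be >= 2, got %d", depth)
  if (!dims %in% c(2, 3)) stop_config("unet_spec: dims must be 2 or 3")
  if (base_width < 1) stop_config("unet_spec: base_width must be >= 1")
  if (is.null(stem_width)) stem_width <- max(1L, as.integer(round(0.89 * base_width)))
  structure(list(depth = as.integer(depth), dims = as.integer(dims),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 stem_width = as.integer(stem_width)),
            class = "unet_spec")
}

# channels at level j (0-based)
level_width <- function(spec, j) {
  if (j == 0) spec$stem_width else spec$base_width * 2L^j
}

# Flat list of layer descriptors; single source of truth for parameter
# shapes, initialization and counting.
unet_layer_table <- function(spec) {
  k <- 3L; dims <- spec$dims; D <- spec$depth
  out <- list()
  add_conv <- function(name, k, cin, cout) {
    out[[length(out) + 1L]] <<- list(name = name, type = "conv", k = k,
                                     cin = cin, cout = cout,
                                     shape = c(rep(k, dims), cin, cout))
  }
  add_bn <- function(name, c) {
    out[[length(out) + 1L]] <<- list(name = name, type = "bn", c = c)
  }
  add_conv("stem.w", k, spec$in_channels, spec$stem_width)
  add_bn("stem.bn", spec$stem_width)
  for (t in seq_len(D - 1)) {
    a <- level_width(spec, t - 1); b <- level_width(spec, t)
    add_conv(sprintf("enc%d.w1", t), k, a, b); add_bn(sprintf("enc%d.bn1", t), b)
    add_conv(sprintf("enc%d.w2", t), k, b, b); add_bn(sprintf("enc%d.bn2", t), b)
    add_conv(sprintf("enc%d.wp", t), 1L, a, b); add_bn(sprintf("enc%d.bnp", t), b)
  }
  for (t in seq(D - 1, 1)) {
    a <- level_width(spec, t - 1); b <- level_width(spec, t)
    add_conv(sprintf("dec%d.wu", t), k, a, b)  # transposed: maps b -> a
    add_bn(sprintf("dec%d.bnu", t), a)
    add_conv(sprintf("dec%d.w1", t), k, 2L * a, a); add_bn(sprintf("dec%d.bn1", t), a)
    add_conv(sprintf("dec%d.w2", t), k, a, a); add_bn(sprintf("dec%d.bn2", t), a)
    add_conv(sprintf("dec%d.wp", t), 1L, 2L * a, a); add_bn(sprintf("dec%d.bnp", t), a)
  }
  add_conv("head.w", 1L, spec$stem_width, spec$out_channels)
  out[[length(out) + 1L]] <- list(name = "head.b", type = "bias", c = spec$out_channels)
  out
}

#' Trainable-parameter count of a U-Net spec
#'
#' Computed from layer shapes without allocating the model; convolutions
#' carry no bias (batch norm follows each one), batch-norm scale and shift
#' are counted, and the 1x1 head has a bias.
#'
#' @param spec A [unet_spec()].
#' @return Integer-valued parameter count.
#' @export
unet_param_count <- function(spec) {
  sum(vapply(unet_layer_table(spec), function(l) switch(l$type,
    conv = prod(l$shape),
    bn = 2 * l$c,
    bias = l$c), numeric(1)))
}

#' Build (initialize) a residual U-Net
#'
#' Weights use He-normal initialization (sd = sqrt(2 / fan_in)), batch-norm
#' scale 1 / shift 0; all randomness comes from `seed`, so the same spec
#' and seed reproduce identical initial weights.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `dicecast_unet` holding parameters, batch-norm
#'   running statistics and the spec.
#' @export
build_unet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  layers <- unet_layer_table(spec)
  params <- list(); bn <- list()
  with_seed(seed, for (l in layers) {
    if (l$type == "conv") {
      fan_in <- l$k^spec$dims * l$cin
      params[[l$name]] <- array(rnorm(prod(l$shape), sd = sqrt(2 / fan_in)), l$shape)
    } else if (l$type == "bn") {
      params[[paste0(l$name, ".g")]] <- rep(1, l$c)
      params[[paste0(l$name, ".b")]] <- rep(0, l$c)
      bn[[l$name]] <- list(running_mean = rep(0, l$c), running_var = rep(1, l$c))
    } else {
      # head bias starts at the logit of a typical foreground prior (~0.1)
      # so early training works on localization instead of recalibrating
      # the base rate (standard trick for class-imbalanced dense prediction)
      params[[l$name]] <- rep(stats::qlogis(0.1), l$c)
    }
  })
  structure(list(spec = spec, params = params, bn = bn), class = "dicecast_unet")
}

#' @export
print.dicecast_unet <- function(x, ...) {
  sp <- x$spec
  widths <- vapply(0:(sp$depth - 1), function(j) level_width(sp, j), numeric(1))
  cat(sprintf("Residual U-Net (%dD), depth %d\n", sp$dims, sp$depth))
  cat(sprintf("  level widths: %s\n", paste(widths, collapse = " ")))
  cat(sprintf("  parameters: %s (%.1f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' @param model A `dicecast_unet`.
#' @return Exact number of trainable scalars (batch-norm running statistics
#'   are not trainable and are excluded).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dicecast_unet"))
  sum(vapply(model$params, length, numeric(1)))
}

check_input_shape <- function(spec, d) {
  sp <- d[seq_len(spec$dims)]
  div <- 2L^(spec$depth - 1L)
  if (any(sp %% div != 0))
    stop_config(paste0("unet forward: spatial size (%s) must be divisible by ",
                       "2^(depth-1) = %d for a depth-%d model"),
                paste(sp, collapse = "x"), div, spec$depth)
  if (d[spec$dims + 1] != spec$in_channels)
    stop_config("unet forward: expected %d input channels, got %d",
                spec$in_channels, d[spec$dims + 1])
}

#' Forward pass of a residual U-Net
#'
#' @param model A [build_unet()] model.
#' @param x Array `(spatial..., C)` for one sample or `(spatial..., C, N)`
#'   for a batch; every spatial extent must be divisible by
#'   `2^(depth - 1)`.
#' @param train Use batch statistics (and update running statistics) in the
#'   normalization layers instead of the stored running averages.
#' @param cache Keep the intermediate activations required for the
#'   backward pass (training engine internals).
#' @return List with `probs` (sigmoid probabilities, same spatial shape as
#'   the input) and `logits`; with `cache = TRUE` also the layer caches and
#'   updated batch-norm state.
#' @export
unet_forward <- function(model, x, train = FALSE, cache = FALSE) {
  sp <- model$spec; dims <- sp$dims; D <- sp$depth; p <- model$params
  if (length(dim(x)) == dims + 1) dim(x) <- c(dim(x), 1L)
  check_input_shape(sp, dim(x))
  bnst <- model$bn
  ca <- list(enc = vector("list", D - 1), dec = vector("list", D - 1))

  bn_apply <- function(h, name) {
    r <- bn_fw(h, p[[paste0(name, ".g")]], p[[paste0(name, ".b")]], bnst[[name]], train)
    bnst[[name]] <<- r$stats
    list(y = r$y, cache = r$cache)
  }

  c0 <- conv_fw(x, p$stem.w, 1L, 1L, dims)
  b0 <- bn_apply(c0, "stem.bn")
  h <- relu_fw(b0$y)
  if (cache) ca$stem <- list(x = x, c = c0, bn = b0$cache, pre = b0$y)
  skips <- vector("list", D); skips[[1]] <- h

  for (t in seq_len(D - 1)) {
    nm <- sprintf("enc%d", t)
    c1 <- conv_fw(h, p[[paste0(nm, ".w1")]], 2L, 1L, dims)
    b1 <- bn_apply(c1, paste0(nm, ".bn1")); r1 <- relu_fw(b1$y)
    c2 <- conv_fw(r1, p[[paste0(nm, ".w2")]], 1L, 1L, dims)
    b2 <- bn_apply(c2, paste0(nm, ".bn2"))
    pr <- conv_fw(h, p[[paste0(nm, ".wp")]], 2L, 0L, dims)
    bp <- bn_apply(pr, paste0(nm, ".bnp"))
    s <- b2$y + bp$y
    if (cache) ca$enc[[t]] <- list(x = h, bn1 = b1$cache, pre1 = b1$y, r1 = r1,
                                   bn2 = b2$cache, bnp = bp$cache, s = s)
    h <- relu_fw(s)
    skips[[t + 1]] <- h
  }

  for (t in seq(D - 1, 1)) {
    nm <- sprintf("dec%d", t)
    u <- convT_fw(h, p[[paste0(nm, ".wu")]], dims)
    bu <- bn_apply(u, paste0(nm, ".bnu")); ru <- relu_fw(bu$y)
    cc <- cat_channels(ru, skips[[t]], dims)
    c1 <- conv_fw(cc, p[[paste0(nm, ".w1")]], 1L, 1L, dims)
    b1 <- bn_apply(c1, paste0(nm, ".bn1")); r1 <- relu_fw(b1$y)
    c2 <- conv_fw(r1, p[[paste0(nm, ".w2")]], 1L, 1L, dims)
    b2 <- bn_apply(c2, paste0(nm, ".bn2"))
    pr <- conv_fw(cc, p[[paste0(nm, ".wp")]], 1L, 0L, dims)
    bp <- bn_apply(pr, paste0(nm, ".bnp"))
    s <- b2$y + bp$y
    if (cache) ca$dec[[t]] <- list(x = h, bnu = bu$cache, preu = bu$y, ru = ru,
                                   cc = cc, bn1 = b1$cache, pre1 = b1$y, r1 = r1,
                                   bn2 = b2$cache, bnp = bp$cache, s = s)
    h <- relu_fw(s)
  }

  logits <- conv_fw(h, p$head.w, 1L, 0L, dims)
  logits <- logits + rep(p$head.b, each = prod(dim(logits)[seq_len(dims)]))
  if (cache) ca$head <- list(x = h)
  out <- list(probs = sigmoid(logits), logits = logits)
  if (cache) { out$cache <- ca; out$bn <- bnst }
  out
}

# Backward pass from d(loss)/d(logits); returns gradient list keyed like
# model$params.
unet_backward <- function(model, cache, dlogits) {
  sp <- model$spec; dims <- sp$dims; D <- sp$depth; p <- model$params
  g <- list()

  bn_back <- function(gy, name, bncache) {
    r <- bn_bw(gy, p[[paste0(name, ".g")]], bncache)
    g[[paste0(name, ".g")]] <<- r$dgamma
    g[[paste0(name, ".b")]] <<- r$dbeta
    r$gx
  }

  nd <- length(dim(dlogits))
  g$head.b <- vapply(seq_len(sp$out_channels), function(c) {
    idx <- slice.index(dlogits, nd - 1) == c
    sum(dlogits[idx])
  }, numeric(1))
  hx <- cache$head$x
  g$head.w <- conv_bw_weight(hx, dlogits, 1L, 1L, 0L, dims)
  gh <- conv_bw_input(dlogits, p$head.w, 1L, 0L, dim(hx)[seq_len(dims)], dims)

  for (t in seq_len(D - 1)) {  # decoder blocks, shallowest first
    nm <- sprintf("dec%d", t)
    cb <- cache$dec[[t]]
    gs <- relu_bw(gh, cb$s)
    # projection branch
    gpr <- bn_back(gs, paste0(nm, ".bnp"), cb$bnp)
    g[[paste0(nm, ".wp")]] <- conv_bw_weight(cb$cc, gpr, 1L, 1L, 0L, dims)
    gcc <- conv_bw_input(gpr, p[[paste0(nm, ".wp")]], 1L, 0L,
                         dim(cb$cc)[seq_len(dims)], dims)
    # main branch
    gc2 <- bn_back(gs, paste0(nm, ".bn2"), cb$bn2)
    g[[paste0(nm, ".w2")]] <- conv_bw_weight(cb$r1, gc2, 3L, 1L, 1L, dims)
    gr1 <- conv_bw_input(gc2, p[[paste0(nm, ".w2")]], 1L, 1L,
                         dim(cb$r1)[seq_len(dims)], dims)
    gb1 <- relu_bw(gr1, cb$pre1)
    gc1 <- bn_back(gb1, paste0(nm, ".bn1"), cb$bn1)
    g[[paste0(nm, ".w1")]] <- conv_bw_weight(cb$cc, gc1, 3L, 1L, 1L, dims)
    gcc <- gcc + conv_bw_input(gc1, p[[paste0(nm, ".w1")]], 1L, 1L,
                               dim(cb$cc)[seq_len(dims)], dims)
    # split concat into upsample branch and skip
    a <- dim(cb$ru)[dims + 1]
    parts <- split_channels(gcc, a, dims)
    gskip <- parts[[2]]
    gru <- parts[[1]]
    gbu <- relu_bw(gru, cb$preu)
    gu <- bn_back(gbu, paste0(nm, ".bnu"), cb$bnu)
    g[[paste0(nm, ".wu")]] <- convT_bw_weight(cb$x, gu, dims)
    gdeep <- convT_bw_input(gu, p[[paste0(nm, ".wu")]], dims)
    # propagate to the next deeper decoder block (or bottleneck) and stash
    # the skip gradient for the encoder sweep
    cache$dec[[t]]$gskip <- gskip
    gh <- gdeep
  }

  # gh now sits at the deepest encoder output (bottleneck). Encoder blocks
  # deepest-first; the output of encoder t (skips[[t+1]]) also feeds the
  # concat of decoder t+1, whose gradient was stashed above.
  for (t in seq(D - 1, 1)) {
    nm <- sprintf("enc%d", t)
    cb <- cache$enc[[t]]
    if (t + 1 <= D - 1) gh <- gh + cache$dec[[t + 1]]$gskip
    gs <- relu_bw(gh, cb$s)
    gpr <- bn_back(gs, paste0(nm, ".bnp"), cb$bnp)
    g[[paste0(nm, ".wp")]] <- conv_bw_weight(cb$x, gpr, 1L, 2L, 0L, dims)
    gx <- conv_bw_input(gpr, p[[paste0(nm, ".wp")]], 2L, 0L,
                        dim(cb$x)[seq_len(dims)], dims)
    gc2 <- bn_back(gs, paste0(nm, ".bn2"), cb$bn2)
    g[[paste0(nm, ".w2")]] <- conv_bw_weight(cb$r1, gc2, 3L, 1L, 1L, dims)
    gr1 <- conv_bw_input(gc2, p[[paste0(nm, ".w2")]], 1L, 1L,
                         dim(cb$r1)[seq_len(dims)], dims)
    gb1 <- relu_bw(gr1, cb$pre1)
    gc1 <- bn_back(gb1, paste0(nm, ".bn1"), cb$bn1)
    g[[paste0(nm, ".w1")]] <- conv_bw_weight(cb$x, gc1, 3L, 2L, 1L, dims)
    gx <- gx + conv_bw_input(gc1, p[[paste0(nm, ".w1")]], 2L, 1L,
                             dim(cb$x)[seq_len(dims)], dims)
    gh <- gx
  }
  # the stem output (skips[[1]]) feeds both encoder 1 and decoder 1's concat
  gh <- gh + cache$dec[[1]]$gskip

  gstem <- relu_bw(gh, cache$stem$pre)
  gc0 <- bn_back(gstem, "stem.bn", cache$stem$bn)
  g$stem.w <- conv_bw_weight(cache$stem$x, gc0, 3L, 1L, 1L, dims)
  g
}
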