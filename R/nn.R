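# Dimension-generic wrappers around the compiled convolution kernels plus
# batch-norm / activation primitives with manual backward passes.
# Activation layout: (spatial..., C, N); conv weights (k..., Cin, Cout);
# transposed-conv weights are stored as the underlying strided conv weight
# (k..., Cout_T, Cin_T).

conv_fw <- function(x, w, stride, pad, dims) {
  if (dims == 2) .conv2d_fw(x, w, stride, pad) else .conv3d_fw(x, w, stride, pad)
}

conv_bw_input <- function(gy, w, stride, pad, in_spatial, dims) {
  if (dims == 2) .conv2d_bw_input(gy, w, stride, pad, in_spatial[1], in_spatial[2])
  else .conv3d_bw_input(gy, w, stride, pad, in_spatial[1], in_spatial[2], in_spatial[3])
}

conv_bw_weight <- function(x, gy, k, stride, pad, dims) {
  if (dims == 2) .conv2d_bw_weight(x, gy, k, stride, pad)
  else .conv3d_bw_weight(x, gy, k, stride, pad)
}

# transposed conv, kernel 3, stride 2, pad 1, output padding 1: doubles the
# spatial size; implemented as the input-gradient of the matching strided conv
convT_fw <- function(x, w, dims) {
  sp <- dim(x)[seq_len(dims)]
  conv_bw_input(x, w, stride = 2L, pad = 1L, in_spatial = 2L * sp, dims = dims)
}

convT_bw_input <- function(gy, w, dims) conv_fw(gy, w, stride = 2L, pad = 1L, dims = dims)

convT_bw_weight <- function(x, gy, dims) {
  conv_bw_weight(gy, x, k = 3L, stride = 2L, pad = 1L, dims = dims)
}

# ---- batch normalization over (spatial..., N) per channel -------------------
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fw <- function(x, gamma, beta, stats, train) {
  C <- length(gamma)
  r <- .bn_fw(x, gamma, beta, stats$running_mean, stats$running_var,
              train, BN_MOMENTUM, BN_EPS, C)
  list(y = r$y,
       cache = if (train) list(xhat = r$xhat, inv_std = r$inv_std) else NULL,
       stats = if (train) list(running_mean = r$running_mean,
                               running_var = r$running_var) else stats)
}

bn_bw <- function(gy, gamma, cache) {
  .bn_bw(gy, gamma, cache$xhat, cache$inv_std, length(gamma))
}

RELU_SLOPE <- 0.1  # leaky slope; narrow desk-scale nets must not lose channels

relu_fw <- function(x) .relu_fw(x, RELU_SLOPE)
relu_bw <- function(gy, x) .relu_bw(gy, x, RELU_SLOPE)

sigmoid <- function(x) 1 / (1 + exp(-x))

# channel concatenation / split, dimension-generic
cat_channels <- function(x1, x2, dims) {
  d1 <- dim(x1); d2 <- dim(x2)
  out <- array(0, c(d1[seq_len(dims)], d1[dims + 1] + d2[dims + 1], d1[dims + 2]))
  if (dims == 2) {
    out[, , seq_len(d1[3]), ] <- x1
    out[, , d1[3] + seq_len(d2[3]), ] <- x2
  } else {
    out[, , , seq_len(d1[4]), ] <- x1
    out[, , , d1[4] + seq_len(d2[4]), ] <- x2
  }
  out
}

split_channels <- function(x, n1, dims) {
  if (dims == 2) list(x[, , seq_len(n1), , drop = FALSE],
                      x[, , -seq_len(n1), , drop = FALSE])
  else list(x[, , , seq_len(n1), , drop = FALSE],
            x[, , , -seq_len(n1), , drop = FALSE])
}
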