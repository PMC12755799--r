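#' @useDynLib dicecast, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd predict lm coef median setNames
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-cell seed: base_seed XOR a small integer hash of
# (depth, ratio index), kept in [0, 2^31).
cell_seed <- function(base_seed, depth, ratio_index) {
  h <- (as.integer(depth) * 100003L + as.integer(ratio_index) * 10007L) %% .Machine$integer.max
  bitwXor(as.integer(base_seed) %% .Machine$integer.max, h) %% .Machine$integer.max
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# md5 of an object via its canonical JSON serialization (file-based,
# so only base tools is needed)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
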