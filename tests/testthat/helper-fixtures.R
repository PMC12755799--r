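# Shared fixtures: everything is generated in code at test time.

tiny_hyper <- function(...) {
  h <- default_hyper(2)
  h$base_width <- 2L; h$stem_width <- 2L
  h$batch_size <- 8L; h$max_epochs <- 2L; h$patience <- 2L; h$lr <- 1e-2
  utils::modifyList(h, list(...))
}

# a hand-buildable curve table on an arbitrary dsc sequence
make_curve <- function(dsc, ratios = seq_along(dsc) / length(dsc),
                       depth = 3L, task_id = "t") {
  out <- data.frame(task_id = task_id, depth = depth, param_count = 1e6,
                    data_ratio = ratios, dsc = dsc)
  class(out) <- c("learning_curves", "data.frame")
  out
}

# random binary mask pair of given shape
random_masks <- function(shape, p = 0.4) {
  list(pred = array(rbinom(prod(shape), 1, p), shape),
       gt = array(rbinom(prod(shape), 1, p), shape))
}
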