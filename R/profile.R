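#' Count trainable parameters
#'
#' For an instantiated model the count is the exact number of scalars across
#' all parameter arrays; for a configuration it is computed in closed form
#' from the layer dimensions (convolution weights, batch-norm scale/shift
#' pairs, fully connected weights and biases). Both routes agree exactly.
#'
#' @param x a `tf_model` or `tf_model_config`.
#' @return integer parameter count.
#' @export
count_params <- function(x) {
  if (inherits(x, "tf_model"))
    return(sum(vapply(x$params, length, 0L)))
  stopifnot(inherits(x, "tf_model_config"))
  cfg <- x
  total <- 0
  if (cfg$use_image) {
    bb <- cfg$backbone
    total <- total + 27 * bb$stem_ch + 2 * bb$stem_ch
    for (b in backbone_blocks(bb)) {
      if (b$expand > 1) total <- total + b$cin * b$cmid + 2 * b$cmid
      total <- total + b$k^2 * b$cmid + 2 * b$cmid
      if (bb$use_se)
        total <- total + b$cmid * b$sq + b$sq + b$sq * b$cmid + b$cmid
      total <- total + b$cmid * b$cout + 2 * b$cout
    }
    last <- utils::tail(bb$stages$out_ch, 1)
    total <- total + last * bb$head_ch + 2 * bb$head_ch
  }
  if (cfg$use_sensor) {
    total <- total + cfg$sensor_dim * cfg$sensor_hidden + cfg$sensor_hidden +
      cfg$sensor_hidden * cfg$sensor_embed + cfg$sensor_embed
  }
  out_dim <- c(cls = cfg$n_classes, o2 = 1, co2 = 1)
  for (hd in cfg$heads) {
    total <- total + cfg$fusion_dim * cfg$head_hidden + cfg$head_hidden +
      cfg$head_hidden * out_dim[[hd]] + out_dim[[hd]]
  }
  as.integer(total)
}

#' Count multiply-accumulate operations of one inference pass
#'
#' Static shape walk: every convolution contributes
#' `Kh*Kw*Cin/groups * Cout * Hout * Wout` multiply-accumulates, every fully
#' connected layer `in * out` (squeeze-and-excitation gating layers and the
#' task heads included; pooling, normalization and activations are not
#' counted, following the usual convention for conv-net profiling).
#'
#' @param x a `tf_model` or `tf_model_config`.
#' @param resolution input side length; defaults to the configured backbone
#'   resolution.
#' @return numeric MAC count for a single image/record.
#' @export
count_macs <- function(x, resolution = NULL) {
  cfg <- if (inherits(x, "tf_model")) x$cfg else x
  stopifnot(inherits(cfg, "tf_model_config"))
  total <- 0
  if (cfg$use_image) {
    bb <- cfg$backbone
    res <- resolution %||% bb$resolution
    h <- conv_out_size(res, 3, 2, 1)
    total <- total + 27 * bb$stem_ch * h * h
    for (b in backbone_blocks(bb)) {
      if (b$expand > 1) total <- total + b$cin * b$cmid * h * h
      ho <- conv_out_size(h, b$k, b$stride, b$k %/% 2)
      total <- total + b$k^2 * b$cmid * ho * ho        # depthwise: Cin/groups = 1
      if (bb$use_se) total <- total + 2 * b$cmid * b$sq
      total <- total + b$cmid * b$cout * ho * ho
      h <- ho
    }
    last <- utils::tail(bb$stages$out_ch, 1)
    total <- total + last * bb$head_ch * h * h
  }
  if (cfg$use_sensor) {
    total <- total + cfg$sensor_dim * cfg$sensor_hidden +
      cfg$sensor_hidden * cfg$sensor_embed
  }
  out_dim <- c(cls = cfg$n_classes, o2 = 1, co2 = 1)
  for (hd in cfg$heads)
    total <- total + cfg$fusion_dim * cfg$head_hidden +
      cfg$head_hidden * out_dim[[hd]]
  total
}

#' Profile a model: parameters, MACs, and forward latency
#'
#' Latency is the median of repeated single-image forward passes on random
#' input; it is hardware-dependent and reported for information only.
#'
#' @param model a `tf_model`.
#' @param n_runs number of timed forward passes (>= 30 recommended).
#' @return list with `params`, `macs`, `latency_ms`.
#' @export
profile_model <- function(model, n_runs = 30) {
  cfg <- model$cfg
  res <- cfg$backbone$resolution
  img <- if (cfg$use_image)
    list(with_seed(1, array(runif(res * res * 3), dim = c(res, res, 3))))
  sens <- if (cfg$use_sensor)
    with_seed(2, matrix(rnorm(cfg$sensor_dim), 1))
  times <- vapply(seq_len(n_runs), function(i) {
    t0 <- proc.time()[["elapsed"]]
    model_forward(model, img, sens, training = FALSE)
    proc.time()[["elapsed"]] - t0
  }, 0)
  list(params = count_params(model), macs = count_macs(model),
       latency_ms = stats::median(times) * 1000)
}
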