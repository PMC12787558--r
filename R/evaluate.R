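#' Classification metrics: accuracy, per-class F1, macro-F1
#'
#' Macro-F1 is the unweighted mean of the per-class F1 scores over the four
#' health classes; a class with no true or predicted samples contributes an
#' F1 of 0.
#'
#' @param truth,pred integer class vectors (0-3).
#' @param classes class universe.
#' @return list with `accuracy`, `f1` (named per-class vector), `macro_f1`,
#'   and the `confusion` matrix (rows = truth).
#' @export
classification_metrics <- function(truth, pred, classes = 0:3) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  f1 <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    prec_den <- sum(cm[, i]); rec_den <- sum(cm[i, ])
    if (tp == 0) return(0)
    p <- tp / prec_den; r <- tp / rec_den
    2 * p * r / (p + r)
  }, 0)
  names(f1) <- paste0("class", classes)
  list(accuracy = sum(diag(cm)) / length(truth), f1 = f1,
       macro_f1 = mean(f1), confusion = cm)
}

#' Regression metrics: MAE and RMSE
#'
#' @param truth,pred numeric vectors in original units.
#' @return list with `mae` and `rmse` (always `rmse >= mae`).
#' @export
regression_metrics <- function(truth, pred) {
  e <- pred - truth
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Run a model on a test set and compute the full metrics report
#'
#' Class predictions are the arg-max of the softmax head; gas predictions
#' are made on the standardized scale and mapped back to original units
#' with the training-fit target statistics before computing MAE/RMSE.
#'
#' @param model a trained `tf_model`.
#' @param test list with `images`, `x`, `labels`, `targets` (original
#'   units), and `image_stats`.
#' @param pipeline the fitted [fit_sensor_pipeline()] (for target
#'   unstandardization).
#' @param batch_size evaluation batch size.
#' @return object of class `tf_metrics`.
#' @export
evaluate_model <- function(model, test, pipeline, batch_size = 64) {
  cfg <- model$cfg
  n <- length(test$labels)
  if (n == 0) stopf("empty test set")
  probs <- NULL; o2p <- NULL; co2p <- NULL
  nb <- ceiling(n / batch_size)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    fm <- if (cfg$use_image)
      make_image_batch(test$images, idx, test$image_stats, FALSE, 0)
    xs <- if (cfg$use_sensor) test$x[idx, , drop = FALSE]
    fwd <- model_forward(model, fm, xs, training = FALSE)
    if (!is.null(fwd$outputs$probs)) probs <- rbind(probs, fwd$outputs$probs)
    if (!is.null(fwd$outputs$o2)) o2p <- c(o2p, fwd$outputs$o2)
    if (!is.null(fwd$outputs$co2)) co2p <- c(co2p, fwd$outputs$co2)
  }
  out <- list(n = n)
  if (!is.null(probs)) {
    pred <- max.col(probs) - 1L
    out <- c(out, classification_metrics(test$labels, pred))
    out$pred_class <- pred
  }
  stats <- pipeline$standardization
  if (!is.null(o2p)) {
    pred_o2 <- unstandardize_targets(o2p, stats, "o2")
    out$o2 <- c(regression_metrics(test$targets[, "o2"], pred_o2), list(pred = pred_o2))
  }
  if (!is.null(co2p)) {
    pred_co2 <- unstandardize_targets(co2p, stats, "co2")
    out$co2 <- c(regression_metrics(test$targets[, "co2"], pred_co2), list(pred = pred_co2))
  }
  structure(out, class = "tf_metrics")
}

#' @export
print.tf_metrics <- function(x, ...) {
  cat(sprintf("Test metrics (n = %d)\n", x$n))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy  : %.4f\n  macro-F1  : %.4f\n", x$accuracy, x$macro_f1))
    cat(sprintf("  per-class F1: %s\n",
                paste(sprintf("%.3f", x$f1), collapse = " ")))
  }
  if (!is.null(x$o2))
    cat(sprintf("  O2  MAE %.3f  RMSE %.3f\n", x$o2$mae, x$o2$rmse))
  if (!is.null(x$co2))
    cat(sprintf("  CO2 MAE %.3f  RMSE %.3f\n", x$co2$mae, x$co2$rmse))
  invisible(x)
}

#' Generate, split, and encode a complete synthetic experiment
#'
#' Convenience wrapper chaining the generator and the preprocessing
#' pipeline: samples a population, renders the images, extracts the raw
#' sensor table, performs the stratified 80/20 split, fits the tabular
#' pipeline and image normalization on the training split only, and
#' returns model-ready train/test sets.
#'
#' @param cfg a [generator_config()].
#' @param split_seed seed of the stratified split.
#' @param test_fraction held-out fraction.
#' @return list with `train`, `test` (each: `images`, `x`, `labels`,
#'   `targets_std`, `targets`, `image_stats`), `pipeline`, `pop`, and the
#'   configs.
#' @export
prepare_experiment <- function(cfg, split_seed = cfg$seed, test_fraction = 0.2) {
  schema <- default_sensor_schema()
  pop <- sample_population(cfg)
  sensors <- population_sensors(pop, cfg)
  images <- render_population(pop, cfg)
  sp <- stratified_split(sensors$health_class, test_fraction, split_seed)
  pipeline <- fit_sensor_pipeline(sensors[sp$train, ], schema)
  image_stats <- image_channel_stats(images[sp$train])
  encode <- function(idx) {
    tr <- transform_sensors(pipeline, sensors[idx, ])
    list(images = images[idx], x = tr$x, labels = tr$labels,
         targets_std = tr$targets_std, targets = tr$targets,
         image_stats = image_stats)
  }
  list(train = encode(sp$train), test = encode(sp$test),
       split = sp, pipeline = pipeline, pop = pop, generator = cfg)
}
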