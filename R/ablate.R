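#' Build a model configuration for an ablation variant
#'
#' Variants: `"full"` (reference), `"no_se"` (squeeze-and-excitation gates
#' removed), `"image_only"` (sensor MLP removed; the fusion vector is the
#' image embedding), `"sensor_only"` (backbone removed), and the three
#' `"single_task_*"` variants keeping one head.
#'
#' @param variant variant name.
#' @param profile backbone profile forwarded to [backbone_config()].
#' @param sensor_dim encoded sensor width.
#' @param seed initialization seed.
#' @param ... further arguments to [model_config()].
#' @return a [model_config()].
#' @export
variant_config <- function(variant = c("full", "no_se", "image_only",
                                       "sensor_only", "single_task_cls",
                                       "single_task_o2", "single_task_co2"),
                           profile = "tiny", sensor_dim, seed = 1, ...) {
  variant <- match.arg(variant)
  use_se <- variant != "no_se"
  use_image <- variant != "sensor_only"
  use_sensor <- variant != "image_only"
  heads <- switch(variant,
                  single_task_cls = "cls",
                  single_task_o2 = "o2",
                  single_task_co2 = "co2",
                  c("cls", "o2", "co2"))
  weights <- c(cls = 0.4, o2 = 0.3, co2 = 0.3)
  if (length(heads) == 1) {
    weights[] <- 0; weights[heads] <- 1
  }
  model_config(backbone = backbone_config(profile, use_se = use_se),
               sensor_dim = sensor_dim, use_image = use_image,
               use_sensor = use_sensor, heads = heads,
               loss_weights = weights, seed = seed, ...)
}

#' Ablation harness: train and evaluate architecture variants
#'
#' For each seed, the dataset is re-split identically for every variant,
#' and each variant is trained with the same schedule and evaluated on the
#' same held-out set, so differences reflect the architecture alone.
#'
#' @param exp a [prepare_experiment()] result (shared across variants).
#' @param trainer a [train_config()]; its seed is replaced per run.
#' @param variants character vector of [variant_config()] names.
#' @param seeds integer vector; one full comparison per seed.
#' @return data.frame with one row per (variant, seed): accuracy, macro-F1,
#'   gas MAE/RMSE, parameter count.
#' @export
ablate <- function(exp, trainer = train_config(max_epochs = 10, patience = 9),
                   variants = c("full", "no_se", "image_only", "sensor_only"),
                   seeds = c(1, 2, 3)) {
  sensor_dim <- ncol(exp$train$x)
  out <- NULL
  for (seed in seeds) {
    for (v in variants) {
      cfg <- variant_config(v, sensor_dim = sensor_dim, seed = seed)
      model <- build_model(cfg)
      tr <- trainer; tr$seed <- as.integer(seed)
      fit <- train_model(model, exp$train, tr)
      met <- evaluate_model(fit$model, exp$test, exp$pipeline)
      out <- rbind(out, data.frame(
        variant = v, seed = seed,
        accuracy = met$accuracy %||% NA_real_,
        macro_f1 = met$macro_f1 %||% NA_real_,
        o2_mae = if (is.null(met$o2)) NA_real_ else met$o2$mae,
        co2_mae = if (is.null(met$co2)) NA_real_ else met$co2$mae,
        params = count_params(fit$model),
        best_epoch = fit$best_epoch))
    }
  }
  out
}
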