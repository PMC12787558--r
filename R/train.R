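#' Training configuration
#'
#' Reference recipe: Adam at an initial learning rate of 1e-3 annealed to 0
#' on a cosine schedule, weight decay 1e-5, gradient-norm clipping at 5.0,
#' batch size 32, up to 120 epochs with early stopping at patience 12 on
#' the validation multi-task loss, loss weights 0.4/0.3/0.3.
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 penalty added to the gradients.
#' @param clip_norm global gradient-norm ceiling.
#' @param batch_size minibatch size.
#' @param max_epochs cosine-schedule period and epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param loss_weights named multi-task weights (`cls`, `o2`, `co2`).
#' @param val_fraction fraction of the training split carved out
#'   (stratified) as the early-stopping validation set.
#' @param seed integer seed controlling shuffling, augmentation and the
#'   validation carve-out.
#' @param verbose print a line per epoch.
#' @return object of class `tf_train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-5, clip_norm = 5,
                         batch_size = 32, max_epochs = 120, patience = 12,
                         loss_weights = c(cls = 0.4, o2 = 0.3, co2 = 0.3),
                         val_fraction = 0.1, seed = 1, verbose = FALSE) {
  stopifnot(lr > 0, weight_decay >= 0, clip_norm > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, patience < max_epochs)
  structure(list(lr = lr, weight_decay = weight_decay, clip_norm = clip_norm,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 loss_weights = loss_weights, val_fraction = val_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "tf_train_config")
}

#' Cosine-annealed learning rate at a given epoch
#'
#' Starts at the configured rate at epoch 1 and anneals to 0 at
#' `max_epochs`.
#'
#' @param epoch 1-based epoch index.
#' @param lr initial rate.
#' @param max_epochs schedule period.
#' @export
cosine_lr <- function(epoch, lr, max_epochs) {
  if (max_epochs == 1) return(lr)
  lr * 0.5 * (1 + cos(pi * (epoch - 1) / (max_epochs - 1)))
}

# Assemble, augment, normalize and stack one image minibatch.
make_image_batch <- function(images, idx, image_stats, augment, seed) {
  imgs <- images[idx]
  if (augment) {
    imgs <- with_seed(seed, lapply(imgs, function(im) augment_image(im)))
  }
  imgs <- lapply(imgs, normalize_image, stats = image_stats)
  images_to_fmap(imgs)
}

global_norm <- function(grads) sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))

#' Train a multimodal multi-task model
#'
#' Minibatch Adam with cosine learning-rate annealing, global gradient-norm
#' clipping, per-epoch validation, and early stopping on the validation
#' multi-task loss; the best-validation parameter snapshot is returned.
#' Fully deterministic for fixed seeds: two runs with the same inputs yield
#' identical histories and parameters.
#'
#' @param model a [build_model()] result.
#' @param data list with elements `images` (list of raw `[H, W, 3]` arrays
#'   in `[0, 1]`; may be `NULL` for sensor-only models), `x` (encoded
#'   standardized sensor matrix), `labels` (integer 0-3), `targets_std`
#'   (N x 2 standardized gas targets), and `image_stats` (per-channel
#'   normalization, required when images are used).
#' @param trainer a [train_config()].
#' @param val optional validation list with the same fields; when `NULL`, a
#'   stratified `val_fraction` of `data` is carved out.
#' @return object of class `tf_fit`: the best `model`, the per-epoch
#'   `history` data.frame, `best_epoch`, and the configs.
#' @export
train_model <- function(model, data, trainer = train_config(), val = NULL) {
  cfg <- model$cfg
  use_img <- cfg$use_image
  n <- length(data$labels)
  if (use_img && is.null(data$image_stats))
    stopf("image_stats required when the model has an image branch")

  if (is.null(val)) {
    sp <- stratified_split(data$labels, trainer$val_fraction,
                           derive_seed(trainer$seed, "val"))
    pick <- function(d, idx) list(
      images = if (use_img) d$images[idx],
      x = d$x[idx, , drop = FALSE],
      labels = d$labels[idx],
      targets_std = d$targets_std[idx, , drop = FALSE],
      image_stats = d$image_stats)
    val <- pick(data, sp$test)
    data <- pick(data, sp$train)
    n <- length(data$labels)
  }

  # The model configuration owns its objective (single-task variants set
  # their own weight vector); the trainer's weights are the fallback.
  weights <- model$cfg$loss_weights %||% trainer$loss_weights

  params <- model$params
  buffers <- model$buffers
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0

  history <- NULL
  best <- list(loss = Inf, epoch = 0, params = params, buffers = buffers)
  nb <- ceiling(n / trainer$batch_size)

  for (epoch in seq_len(trainer$max_epochs)) {
    lr <- cosine_lr(epoch, trainer$lr, trainer$max_epochs)
    ord <- with_seed(derive_seed(trainer$seed, "shuffle", epoch), sample.int(n))
    ep_loss <- c(L_cls = 0, L_o2 = 0, L_co2 = 0, L_T = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * trainer$batch_size + 1):min(b * trainer$batch_size, n)]
      fm <- if (use_img)
        make_image_batch(data$images, idx, data$image_stats, TRUE,
                         derive_seed(trainer$seed, "aug", epoch, b))
      xs <- if (cfg$use_sensor) data$x[idx, , drop = FALSE]
      m <- structure(list(cfg = cfg, params = params, buffers = buffers),
                     class = "tf_model")
      fwd <- model_forward(m, fm, xs, training = TRUE)
      buffers[names(fwd$buffers)] <- fwd$buffers
      L <- total_loss(fwd$outputs, data$labels[idx],
                      data$targets_std[idx, , drop = FALSE],
                      weights)
      if (!is.finite(L$L_T))
        stopf("non-finite loss at epoch %d, batch %d (samples %s)",
              epoch, b, paste(head(idx), collapse = ","))
      grads <- model_backward(m, fwd$cache, L$dhead)
      if (trainer$weight_decay > 0) {
        for (k in names(grads))
          grads[[k]] <- grads[[k]] + trainer$weight_decay * params[[k]]
      }
      gn <- global_norm(grads)
      if (gn > trainer$clip_norm) {
        sc <- trainer$clip_norm / gn
        for (k in names(grads)) grads[[k]] <- grads[[k]] * sc
      }
      t_step <- t_step + 1
      bc1 <- 1 - beta1^t_step; bc2 <- 1 - beta2^t_step
      for (k in names(grads)) {
        adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * grads[[k]]
        adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * grads[[k]]^2
        params[[k]] <- params[[k]] -
          lr * (adam_m[[k]] / bc1) / (sqrt(adam_v[[k]] / bc2) + adam_eps)
      }
      ep_loss <- ep_loss + c(L$L_cls, L$L_o2, L$L_co2, L$L_T) / nb
    }

    vm <- structure(list(cfg = cfg, params = params, buffers = buffers),
                    class = "tf_model")
    vloss <- validation_loss(vm, val, weights)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      train_L_cls = ep_loss[["L_cls"]], train_L_o2 = ep_loss[["L_o2"]],
      train_L_co2 = ep_loss[["L_co2"]], train_L_T = ep_loss[["L_T"]],
      val_L_T = vloss$L_T, val_accuracy = vloss$accuracy))
    if (trainer$verbose)
      message(sprintf("epoch %3d  lr %.2e  train L_T %.4f  val L_T %.4f  val acc %.3f",
                      epoch, lr, ep_loss[["L_T"]], vloss$L_T, vloss$accuracy))
    if (vloss$L_T < best$loss) {
      best <- list(loss = vloss$L_T, epoch = epoch,
                   params = params, buffers = buffers)
    } else if (epoch - best$epoch >= trainer$patience) break
  }

  structure(list(
    model = structure(list(cfg = cfg, params = best$params,
                           buffers = best$buffers), class = "tf_model"),
    history = history, best_epoch = best$epoch, trainer = trainer),
    class = "tf_fit")
}

# Validation multi-task loss and accuracy, computed in evaluation mode.
validation_loss <- function(model, val, weights, batch_size = 64) {
  cfg <- model$cfg
  n <- length(val$labels)
  tot <- c(L_cls = 0, L_o2 = 0, L_co2 = 0, L_T = 0)
  correct <- 0
  nb <- ceiling(n / batch_size)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    fm <- if (cfg$use_image)
      make_image_batch(val$images, idx, val$image_stats, FALSE, 0)
    xs <- if (cfg$use_sensor) val$x[idx, , drop = FALSE]
    fwd <- model_forward(model, fm, xs, training = FALSE)
    L <- total_loss(fwd$outputs, val$labels[idx],
                    val$targets_std[idx, , drop = FALSE], weights)
    wgt <- length(idx) / n
    tot <- tot + c(L$L_cls, L$L_o2, L$L_co2, L$L_T) * wgt
    if (!is.null(fwd$outputs$probs))
      correct <- correct + sum(max.col(fwd$outputs$probs) - 1 == val$labels[idx])
  }
  list(L_cls = tot[["L_cls"]], L_o2 = tot[["L_o2"]], L_co2 = tot[["L_co2"]],
       L_T = tot[["L_T"]], accuracy = correct / n)
}

#' @export
print.tf_fit <- function(x, ...) {
  cat(sprintf("Training run: %d epochs (best validation L_T %.4f at epoch %d)\n",
              nrow(x$history), min(x$history$val_L_T), x$best_epoch))
  invisible(x)
}
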