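#' Instantiate a multimodal multi-task model
#'
#' Allocates and initializes every trainable tensor of the configured
#' architecture. Convolutions are bias-free (batch normalization supplies
#' the affine terms) and initialized with truncated-normal fan-out scaling;
#' fully connected layers use uniform fan-in initialization. Batch-norm
#' scale/shift start at 1/0 with running statistics 0/1.
#'
#' @param cfg a [model_config()].
#' @return object of class `tf_model` with elements `cfg`, `params`
#'   (named list of weight arrays) and `buffers` (batch-norm running stats).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "tf_model_config"))
  params <- list(); buffers <- list()
  tnorm <- function(n, sd) {
    v <- rnorm(n, 0, sd)
    clamp(v, -2 * sd, 2 * sd)
  }
  conv_init <- function(cout, cin_kk, fan_out)
    matrix(tnorm(cout * cin_kk, sqrt(2 / fan_out)), cout, cin_kk)
  fc_init <- function(cout, cin) {
    b <- 1 / sqrt(cin)
    matrix(runif(cout * cin, -b, b), cout, cin)
  }
  fc_bias <- function(cout, cin) runif(cout, -1 / sqrt(cin), 1 / sqrt(cin))
  add_bn <- function(name, ch) {
    params[[paste0(name, ".g")]] <<- rep(1, ch)
    params[[paste0(name, ".b")]] <<- rep(0, ch)
    buffers[[paste0(name, ".rm")]] <<- rep(0, ch)
    buffers[[paste0(name, ".rv")]] <<- rep(1, ch)
  }

  with_seed(cfg$seed, {
    if (cfg$use_image) {
      bb <- cfg$backbone
      params[["stem.W"]] <- conv_init(bb$stem_ch, 3 * 9, 9 * bb$stem_ch)
      add_bn("stem", bb$stem_ch)
      blocks <- backbone_blocks(bb)
      for (i in seq_along(blocks)) {
        b <- blocks[[i]]; p <- sprintf("b%02d", i)
        if (b$expand > 1) {
          params[[paste0(p, ".exp.W")]] <- conv_init(b$cmid, b$cin, b$cmid)
          add_bn(paste0(p, ".bn1"), b$cmid)
        }
        params[[paste0(p, ".dw.W")]] <-
          matrix(tnorm(b$k^2 * b$cmid, sqrt(2 / b$k^2)), b$k^2, b$cmid)
        add_bn(paste0(p, ".bn2"), b$cmid)
        if (bb$use_se) {
          params[[paste0(p, ".se.W1")]] <- fc_init(b$sq, b$cmid)
          params[[paste0(p, ".se.b1")]] <- fc_bias(b$sq, b$cmid)
          params[[paste0(p, ".se.W2")]] <- fc_init(b$cmid, b$sq)
          params[[paste0(p, ".se.b2")]] <- fc_bias(b$cmid, b$sq)
        }
        params[[paste0(p, ".proj.W")]] <- conv_init(b$cout, b$cmid, b$cout)
        add_bn(paste0(p, ".bn3"), b$cout)
      }
      last <- blocks[[length(blocks)]]$cout
      params[["head.W"]] <- conv_init(bb$head_ch, last, bb$head_ch)
      add_bn("head", bb$head_ch)
    }
    if (cfg$use_sensor) {
      params[["sens.fc1.W"]] <- fc_init(cfg$sensor_hidden, cfg$sensor_dim)
      params[["sens.fc1.b"]] <- fc_bias(cfg$sensor_hidden, cfg$sensor_dim)
      params[["sens.fc2.W"]] <- fc_init(cfg$sensor_embed, cfg$sensor_hidden)
      params[["sens.fc2.b"]] <- fc_bias(cfg$sensor_embed, cfg$sensor_hidden)
    }
    out_dim <- c(cls = cfg$n_classes, o2 = 1L, co2 = 1L)
    for (hd in cfg$heads) {
      p <- paste0("hd.", hd)
      params[[paste0(p, ".W1")]] <- fc_init(cfg$head_hidden, cfg$fusion_dim)
      params[[paste0(p, ".b1")]] <- fc_bias(cfg$head_hidden, cfg$fusion_dim)
      params[[paste0(p, ".W2")]] <- fc_init(out_dim[[hd]], cfg$head_hidden)
      params[[paste0(p, ".b2")]] <- fc_bias(out_dim[[hd]], cfg$head_hidden)
    }
  })
  structure(list(cfg = cfg, params = params, buffers = buffers),
            class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Multimodal multi-task tree model\n")
  cat(sprintf("  backbone : %s%s (%dpx, embedding %d)\n",
              if (cfg$use_image) cfg$backbone$profile else "none",
              if (cfg$use_image && !cfg$backbone$use_se) ", no SE" else "",
              cfg$backbone$resolution, cfg$backbone$head_ch))
  cat(sprintf("  sensors  : %s\n",
              if (cfg$use_sensor)
                sprintf("%d -> %d -> %d MLP", cfg$sensor_dim,
                        cfg$sensor_hidden, cfg$sensor_embed) else "none"))
  cat(sprintf("  fusion   : %d-wide, heads [%s], hidden %d\n",
              cfg$fusion_dim, paste(cfg$heads, collapse = ", "), cfg$head_hidden))
  cat(sprintf("  params   : %s trainable\n",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# ---- forward ---------------------------------------------------------------

mbconv_fwd <- function(params, buffers, bb, b, prefix, fm, training) {
  cache <- list(residual = b$residual, x_in = if (b$residual) fm$a)
  upd <- list()
  bn <- function(name, x) {
    r <- bn_fwd(x, params[[paste0(name, ".g")]], params[[paste0(name, ".b")]],
                buffers[[paste0(name, ".rm")]], buffers[[paste0(name, ".rv")]],
                training, bb$bn_momentum, bb$bn_eps)
    if (training) {
      upd[[paste0(name, ".rm")]] <<- r$rmean
      upd[[paste0(name, ".rv")]] <<- r$rvar
    }
    r
  }
  bns <- function(name, x) {
    r <- bn_silu_fwd(x, params[[paste0(name, ".g")]], params[[paste0(name, ".b")]],
                     buffers[[paste0(name, ".rm")]], buffers[[paste0(name, ".rv")]],
                     training, bb$bn_momentum, bb$bn_eps)
    if (training) {
      upd[[paste0(name, ".rm")]] <<- r$rmean
      upd[[paste0(name, ".rv")]] <<- r$rvar
    }
    r
  }
  a <- fm$a
  if (b$expand > 1) {
    r <- pw_conv_fwd(a, params[[paste0(prefix, ".exp.W")]])
    cache$exp <- r$cache
    r2 <- bns(paste0(prefix, ".bn1"), r$out); cache$bns1 <- r2$cache
    a <- r2$out
  }
  r <- dw_conv_fwd(fmap(a, fm$h, fm$w, fm$n),
                   params[[paste0(prefix, ".dw.W")]], b$k, b$stride, b$k %/% 2)
  cache$dw <- r$cache
  fmo <- r$out
  r2 <- bns(paste0(prefix, ".bn2"), fmo$a); cache$bns2 <- r2$cache
  a <- r2$out
  if (bb$use_se) {
    r <- se_fwd(fmap(a, fmo$h, fmo$w, fmo$n),
                params[[paste0(prefix, ".se.W1")]], params[[paste0(prefix, ".se.b1")]],
                params[[paste0(prefix, ".se.W2")]], params[[paste0(prefix, ".se.b2")]])
    cache$se <- r$cache
    a <- r$out$a
  }
  r <- pw_conv_fwd(a, params[[paste0(prefix, ".proj.W")]])
  cache$proj <- r$cache
  r2 <- bn(paste0(prefix, ".bn3"), r$out); cache$bn3 <- r2$cache
  a <- r2$out
  if (b$residual) a <- a + cache$x_in
  list(out = fmap(a, fmo$h, fmo$w, fmo$n), cache = cache, buffers = upd)
}

mbconv_bwd <- function(params, bb, b, prefix, cache, dout) {
  grads <- list()
  da <- dout
  dres <- if (b$residual) dout else NULL
  r <- bn_bwd(cache$bn3, da)
  grads[[paste0(prefix, ".bn3.g")]] <- r$dgamma
  grads[[paste0(prefix, ".bn3.b")]] <- r$dbeta
  r2 <- pw_conv_bwd(cache$proj, r$dx, params[[paste0(prefix, ".proj.W")]])
  grads[[paste0(prefix, ".proj.W")]] <- r2$dW
  da <- r2$dx
  if (bb$use_se) {
    r <- se_bwd(cache$se, da,
                params[[paste0(prefix, ".se.W1")]], params[[paste0(prefix, ".se.W2")]])
    grads[[paste0(prefix, ".se.W1")]] <- r$dW1
    grads[[paste0(prefix, ".se.b1")]] <- r$db1
    grads[[paste0(prefix, ".se.W2")]] <- r$dW2
    grads[[paste0(prefix, ".se.b2")]] <- r$db2
    da <- r$dx
  }
  r <- bn_silu_bwd(cache$bns2, da)
  grads[[paste0(prefix, ".bn2.g")]] <- r$dgamma
  grads[[paste0(prefix, ".bn2.b")]] <- r$dbeta
  r2 <- dw_conv_bwd(cache$dw, r$dx, params[[paste0(prefix, ".dw.W")]])
  grads[[paste0(prefix, ".dw.W")]] <- r2$dW
  da <- r2$dx
  if (b$expand > 1) {
    r <- bn_silu_bwd(cache$bns1, da)
    grads[[paste0(prefix, ".bn1.g")]] <- r$dgamma
    grads[[paste0(prefix, ".bn1.b")]] <- r$dbeta
    r2 <- pw_conv_bwd(cache$exp, r$dx, params[[paste0(prefix, ".exp.W")]])
    grads[[paste0(prefix, ".exp.W")]] <- r2$dW
    da <- r2$dx
  }
  if (b$residual) da <- da + dres
  list(dx = da, grads = grads)
}

#' Run the image backbone on a batch of images
#'
#' Stem convolution, the MBConv stage stack, the 1x1 head convolution, and
#' global average pooling to a fixed-length embedding.
#'
#' @param model a [build_model()] object (with an image branch).
#' @param fm feature map from `images_to_fmap()` (internal) or a batch
#'   assembled by [predict.tf_model()].
#' @param training batch-statistics mode for batch normalization.
#' @return list with `emb` (N x head_ch matrix), `cache`, `buffers`.
#' @keywords internal
forward_backbone <- function(model, fm, training = FALSE) {
  cfg <- model$cfg; bb <- cfg$backbone
  params <- model$params; buffers <- model$buffers
  if (fm$h != bb$resolution || fm$w != bb$resolution)
    stopf("input resolution %dx%d does not match configured %d",
          fm$h, fm$w, bb$resolution)
  upd <- list(); caches <- list()
  r <- dense_conv_fwd(fm, params[["stem.W"]], 3, 2, 1)
  caches$stem_conv <- r$cache
  fmx <- r$out
  rb <- bn_silu_fwd(fmx$a, params[["stem.g"]], params[["stem.b"]],
                    buffers[["stem.rm"]], buffers[["stem.rv"]],
                    training, bb$bn_momentum, bb$bn_eps)
  if (training) { upd[["stem.rm"]] <- rb$rmean; upd[["stem.rv"]] <- rb$rvar }
  caches$stem_bns <- rb$cache
  fmx <- fmap(rb$out, fmx$h, fmx$w, fmx$n)
  blocks <- backbone_blocks(bb)
  caches$blocks <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- mbconv_fwd(params, buffers, bb, blocks[[i]], sprintf("b%02d", i),
                    fmx, training)
    caches$blocks[[i]] <- r$cache
    upd[names(r$buffers)] <- r$buffers
    fmx <- r$out
  }
  r <- pw_conv_fwd(fmx$a, params[["head.W"]])
  caches$head_conv <- r$cache
  rb <- bn_silu_fwd(r$out, params[["head.g"]], params[["head.b"]],
                    buffers[["head.rm"]], buffers[["head.rv"]],
                    training, bb$bn_momentum, bb$bn_eps)
  if (training) { upd[["head.rm"]] <- rb$rmean; upd[["head.rv"]] <- rb$rvar }
  caches$head_bns <- rb$cache
  rg <- gap_fwd(fmap(rb$out, fmx$h, fmx$w, fmx$n))
  caches$gap <- rg$cache
  caches$pre_pool <- c(h = fmx$h, w = fmx$w, n = fmx$n)
  list(emb = rg$out, cache = caches, buffers = upd)
}

backward_backbone <- function(model, cache, demb) {
  cfg <- model$cfg; bb <- cfg$backbone; params <- model$params
  grads <- list()
  da <- gap_bwd(cache$gap, demb)
  r <- bn_silu_bwd(cache$head_bns, da)
  grads[["head.g"]] <- r$dgamma; grads[["head.b"]] <- r$dbeta
  r2 <- pw_conv_bwd(cache$head_conv, r$dx, params[["head.W"]])
  grads[["head.W"]] <- r2$dW
  da <- r2$dx
  blocks <- backbone_blocks(bb)
  for (i in rev(seq_along(blocks))) {
    r <- mbconv_bwd(params, bb, blocks[[i]], sprintf("b%02d", i),
                    cache$blocks[[i]], da)
    grads[names(r$grads)] <- r$grads
    da <- r$dx
  }
  r <- bn_silu_bwd(cache$stem_bns, da)
  grads[["stem.g"]] <- r$dgamma; grads[["stem.b"]] <- r$dbeta
  r2 <- dense_conv_bwd(cache$stem_conv, r$dx)
  grads[["stem.W"]] <- r2$dW
  grads
}

#' Forward pass of the full multimodal model
#'
#' @param model a `tf_model`.
#' @param images list of `[H, W, 3]` arrays (already normalized), or `NULL`
#'   for sensor-only variants.
#' @param sensors N x d matrix of encoded standardized sensor vectors, or
#'   `NULL` for image-only variants.
#' @param training use batch statistics and record caches for backprop.
#' @return list with `outputs` (logits, probs, o2, co2, embeddings, fusion),
#'   `cache` (when `training`), and `buffers` (updated running statistics).
#' @export
model_forward <- function(model, images = NULL, sensors = NULL, training = FALSE) {
  cfg <- model$cfg; params <- model$params
  cache <- list(); upd <- list()
  img_emb <- sens_emb <- NULL
  n <- NULL
  if (cfg$use_image) {
    if (is.null(images)) stopf("model has an image branch but no images given")
    fm <- if (is.list(images) && !is.null(images$a)) images else images_to_fmap(images)
    r <- forward_backbone(model, fm, training)
    img_emb <- r$emb; cache$backbone <- r$cache; upd[names(r$buffers)] <- r$buffers
    n <- nrow(img_emb)
  }
  if (cfg$use_sensor) {
    if (is.null(sensors)) stopf("model has a sensor branch but no sensors given")
    sensors <- as.matrix(sensors)
    if (ncol(sensors) != cfg$sensor_dim)
      stopf("sensor width %d does not match fitted width %d",
            ncol(sensors), cfg$sensor_dim)
    r1 <- fc_fwd(sensors, params[["sens.fc1.W"]], params[["sens.fc1.b"]])
    ra <- silu_fwd(r1$out)
    r2 <- fc_fwd(ra$out, params[["sens.fc2.W"]], params[["sens.fc2.b"]])
    sens_emb <- r2$out
    cache$sens <- list(fc1 = r1$cache, act = ra$cache, fc2 = r2$cache)
    if (!is.null(n) && nrow(sens_emb) != n)
      stopf("image batch (%d) and sensor batch (%d) sizes differ", n, nrow(sens_emb))
    n <- nrow(sens_emb)
  }
  fusion <- fuse(sens_emb, img_emb)
  outputs <- list(sensor_emb = sens_emb, image_emb = img_emb, fusion = fusion)
  cache$heads <- list()
  for (hd in cfg$heads) {
    p <- paste0("hd.", hd)
    r1 <- fc_fwd(fusion, params[[paste0(p, ".W1")]], params[[paste0(p, ".b1")]])
    ra <- relu_fwd(r1$out)
    r2 <- fc_fwd(ra$out, params[[paste0(p, ".W2")]], params[[paste0(p, ".b2")]])
    cache$heads[[hd]] <- list(fc1 = r1$cache, act = ra$cache, fc2 = r2$cache)
    if (hd == "cls") {
      outputs$logits <- r2$out
      outputs$probs <- softmax(r2$out)
    } else {
      outputs[[hd]] <- as.numeric(r2$out)
    }
  }
  list(outputs = outputs, cache = if (training) cache else NULL, buffers = upd)
}

#' Fuse sensor and image embeddings by concatenation
#'
#' Exact concatenation with the sensor block first; no learned parameters.
#' Either argument may be `NULL` (single-modality variants), but not both.
#'
#' @param sensor_emb N x d_s matrix or `NULL`.
#' @param image_emb N x d_i matrix or `NULL`.
#' @return N x (d_s + d_i) fusion matrix.
#' @export
fuse <- function(sensor_emb, image_emb) {
  if (is.null(sensor_emb) && is.null(image_emb))
    stopf("at least one modality embedding is required")
  if (is.null(sensor_emb)) return(image_emb)
  if (is.null(image_emb)) return(sensor_emb)
  if (nrow(sensor_emb) != nrow(image_emb))
    stopf("embeddings have different batch sizes")
  cbind(sensor_emb, image_emb)
}

# Backward pass from head-output gradients to all parameter gradients.
model_backward <- function(model, cache, dhead_out) {
  cfg <- model$cfg; params <- model$params
  grads <- list()
  dfusion <- 0
  for (hd in names(dhead_out)) {
    p <- paste0("hd.", hd)
    dout <- dhead_out[[hd]]
    if (is.null(dim(dout))) dout <- matrix(dout, ncol = 1)
    r2 <- fc_bwd(cache$heads[[hd]]$fc2, dout, params[[paste0(p, ".W2")]])
    grads[[paste0(p, ".W2")]] <- r2$dW; grads[[paste0(p, ".b2")]] <- r2$db
    da <- relu_bwd(cache$heads[[hd]]$act, r2$dx)
    r1 <- fc_bwd(cache$heads[[hd]]$fc1, da, params[[paste0(p, ".W1")]])
    grads[[paste0(p, ".W1")]] <- r1$dW; grads[[paste0(p, ".b1")]] <- r1$db
    dfusion <- dfusion + r1$dx
  }
  ds <- di <- NULL
  if (cfg$use_sensor && cfg$use_image) {
    ds <- dfusion[, seq_len(cfg$sensor_embed), drop = FALSE]
    di <- dfusion[, cfg$sensor_embed + seq_len(cfg$backbone$head_ch), drop = FALSE]
  } else if (cfg$use_sensor) ds <- dfusion else di <- dfusion
  if (cfg$use_sensor) {
    r2 <- fc_bwd(cache$sens$fc2, ds, params[["sens.fc2.W"]])
    grads[["sens.fc2.W"]] <- r2$dW; grads[["sens.fc2.b"]] <- r2$db
    da <- silu_bwd(cache$sens$act, r2$dx)
    r1 <- fc_bwd(cache$sens$fc1, da, params[["sens.fc1.W"]])
    grads[["sens.fc1.W"]] <- r1$dW; grads[["sens.fc1.b"]] <- r1$db
  }
  if (cfg$use_image) {
    gb <- backward_backbone(model, cache$backbone, di)
    grads[names(gb)] <- gb
  }
  grads
}

#' Weighted multi-task loss
#'
#' Cross-entropy (nats, from logits via log-sum-exp) for the health
#' classifier plus mean-absolute-error terms for the two standardized gas
#' targets, combined as `L_T = w_cls*L_cls + w_o2*L_o2 + w_co2*L_co2`.
#' Heads absent from the model contribute zero.
#'
#' @param outputs `outputs` element of [model_forward()].
#' @param labels integer health labels in 0..3 (required when the model has
#'   a classification head).
#' @param targets N x 2 matrix of standardized o2/co2 targets.
#' @param weights named loss weights (`cls`, `o2`, `co2`).
#' @return list with `L_cls`, `L_o2`, `L_co2`, `L_T` and head-output
#'   gradients `dhead` (already scaled by the weights).
#' @export
total_loss <- function(outputs, labels = NULL, targets = NULL,
                       weights = c(cls = 0.4, o2 = 0.3, co2 = 0.3)) {
  L <- list(L_cls = 0, L_o2 = 0, L_co2 = 0)
  dhead <- list()
  if (!is.null(outputs$logits)) {
    if (is.null(labels)) stopf("labels required for the classification head")
    if (any(!labels %in% 0:3)) stopf("health labels must be in {0,1,2,3}")
    r <- cross_entropy_fwd(outputs$logits, labels)
    L$L_cls <- r$loss
    dhead$cls <- r$dlogits * weights[["cls"]]
  }
  if (!is.null(outputs$o2)) {
    r <- mae_fwd(outputs$o2, targets[, "o2"])
    L$L_o2 <- r$loss
    dhead$o2 <- r$dpred * weights[["o2"]]
  }
  if (!is.null(outputs$co2)) {
    r <- mae_fwd(outputs$co2, targets[, "co2"])
    L$L_co2 <- r$loss
    dhead$co2 <- r$dpred * weights[["co2"]]
  }
  L$L_T <- weights[["cls"]] * L$L_cls + weights[["o2"]] * L$L_o2 +
    weights[["co2"]] * L$L_co2
  L$dhead <- dhead
  L
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the architecture
#' configuration, all parameters and batch-norm buffers, the fitted sensor
#' pipeline, and the per-channel image normalization statistics, so that
#' inference is reproducible from the file alone.
#'
#' @param model a `tf_model`.
#' @param path checkpoint file path.
#' @param pipeline optional fitted [fit_sensor_pipeline()].
#' @param image_stats optional per-channel image mean/sd.
#' @param history optional training history to embed.
#' @export
save_checkpoint <- function(model, path, pipeline = NULL, image_stats = NULL,
                            history = NULL) {
  saveRDS(list(cfg = model$cfg, params = model$params, buffers = model$buffers,
               pipeline = pipeline, image_stats = image_stats,
               history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- structure(list(cfg = obj$cfg, params = obj$params,
                          buffers = obj$buffers), class = "tf_model")
  list(model = model, pipeline = obj$pipeline, image_stats = obj$image_stats,
       history = obj$history)
}
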