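test_that("augmentation: identity under pinned factors, seeded determinism", {
  img <- random_images(1, 32, seed = 14)[[1]]
  ident <- augment_image(img, seed = 1, crop_scale = c(1, 1), flip_prob = 0,
                         brightness = 0, contrast = 0)
  expect_equal(ident, img, tolerance = 1e-12)
  a1 <- augment_image(img, seed = 99)
  expect_identical(a1, augment_image(img, seed = 99))
  expect_false(identical(a1, augment_image(img, seed = 100)))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # evaluation batches bypass augmentation entirely
  stats <- list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  fm <- treefusion:::make_image_batch(list(img), 1, stats, FALSE, 0)
  expect_equal(array(fm$a, dim = c(32, 32, 3)), img, tolerance = 1e-12)
})

test_that("cosine schedule spans lr0 down to 0 across the configured epochs", {
  expect_equal(cosine_lr(1, 1e-3, 120), 1e-3)
  expect_lte(cosine_lr(120, 1e-3, 120), 1e-6)
  expect_equal(cosine_lr(61, 1e-3, 121), 5e-4)      # midpoint at half amplitude
  lrs <- vapply(1:120, cosine_lr, 0, lr = 1e-3, max_epochs = 120)
  expect_true(all(diff(lrs) < 0))                    # monotone decay
})

test_that("metric arithmetic matches hand counts", {
  # confusion diagonal (3,4,5,8) over 25 samples
  truth <- rep(0:3, times = c(5, 5, 6, 9))
  pred <- truth
  pred[c(1, 2, 6, 11, 20)] <- c(1, 1, 2, 3, 0)       # 5 mistakes
  cm <- classification_metrics(truth, pred)
  expect_equal(as.numeric(diag(cm$confusion)), c(3, 4, 5, 8))
  expect_equal(cm$accuracy, 0.80)
  # perfect predictions
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$macro_f1, 1.0)
  expect_equal(perfect$accuracy, 1.0)
  rm0 <- regression_metrics(c(1, 2), c(1, 2))
  expect_equal(rm0$mae, 0); expect_equal(rm0$rmse, 0)
  # predictions [1,2] against targets [2,4]
  rm <- regression_metrics(c(2, 4), c(1, 2))
  expect_equal(rm$mae, 1.5)
  expect_equal(rm$rmse, sqrt(2.5))
  # Jensen: RMSE >= MAE on random data
  for (i in 1:10) {
    e <- with_seed_local(i, list(t = rnorm(30), p = rnorm(30)))
    r <- regression_metrics(e$t, e$p)
    expect_gte(r$rmse, r$mae)
  }
})

test_that("training config validates the recipe and early stopping trips at patience", {
  expect_error(train_config(patience = 10, max_epochs = 10), "patience")
  expect_error(train_config(lr = -1))
  tc <- train_config()
  expect_equal(tc$lr, 1e-3); expect_equal(tc$clip_norm, 5)
  expect_equal(tc$batch_size, 32L); expect_equal(tc$max_epochs, 120L)
  expect_equal(tc$patience, 12L)
  expect_equal(unname(tc$loss_weights), c(0.4, 0.3, 0.3))

  # divergent learning rate: validation worsens immediately, run stops at
  # best_epoch + patience, and the retained snapshot is the history minimum
  cfg <- generator_config(n_trees = 80, seed = 11)
  pop <- sample_population(cfg)
  sens <- population_sensors(pop, cfg)
  pipe <- fit_sensor_pipeline(sens, default_sensor_schema())
  tr <- transform_sensors(pipe, sens)
  data <- list(images = NULL, x = tr$x, labels = tr$labels,
               targets_std = tr$targets_std, image_stats = NULL)
  mc <- model_config(backbone = backbone_config("tiny"), use_image = FALSE,
                     sensor_dim = ncol(tr$x), seed = 1)
  fit <- train_model(build_model(mc), data,
                     train_config(lr = 5, max_epochs = 40, patience = 3,
                                  seed = 2, batch_size = 16))
  expect_lt(nrow(fit$history), 40)
  expect_equal(nrow(fit$history), fit$best_epoch + 3)
  expect_equal(min(fit$history$val_L_T), fit$history$val_L_T[fit$best_epoch])
})

test_that("a short sensor-only run learns and reproduces bit-identically", {
  cfg <- generator_config(n_trees = 120, seed = 19)
  pop <- sample_population(cfg)
  sens <- population_sensors(pop, cfg)
  sp <- stratified_split(sens$health_class, 0.2, 19)
  pipe <- fit_sensor_pipeline(sens[sp$train, ], default_sensor_schema())
  trn <- transform_sensors(pipe, sens[sp$train, ])
  tst <- transform_sensors(pipe, sens[sp$test, ])
  data <- list(images = NULL, x = trn$x, labels = trn$labels,
               targets_std = trn$targets_std, image_stats = NULL)
  mc <- model_config(backbone = backbone_config("tiny"), use_image = FALSE,
                     sensor_dim = ncol(trn$x), seed = 3)
  tc <- train_config(max_epochs = 15, patience = 14, seed = 3, batch_size = 16)
  fit1 <- train_model(build_model(mc), data, tc)
  fit2 <- train_model(build_model(mc), data, tc)
  expect_identical(fit1$history, fit2$history)       # end-to-end determinism
  expect_identical(fit1$model$params, fit2$model$params)
  # the loss must actually go down over training
  expect_lt(utils::tail(fit1$history$train_L_T, 1), fit1$history$train_L_T[1])

  test_set <- list(images = NULL, x = tst$x, labels = tst$labels,
                   targets = tst$targets, image_stats = NULL)
  met <- evaluate_model(fit1$model, test_set, pipe)
  expect_identical(evaluate_model(fit1$model, test_set, pipe)[], met[])
  expect_gt(met$accuracy, 0.25)                      # clearly above chance
  expect_gte(met$o2$rmse, met$o2$mae)
  expect_gte(met$co2$rmse, met$co2$mae)
  expect_error(evaluate_model(fit1$model, list(labels = integer(0)), pipe),
               "empty test set")
})

test_that("variant configurations change exactly what they claim", {
  full <- variant_config("full", sensor_dim = 30)
  no_se <- variant_config("no_se", sensor_dim = 30)
  img <- variant_config("image_only", sensor_dim = 30)
  sens <- variant_config("sensor_only", sensor_dim = 30)
  st <- variant_config("single_task_o2", sensor_dim = 30)
  expect_lt(count_params(no_se), count_params(full))  # SE layers removed
  expect_equal(img$fusion_dim, img$backbone$head_ch)  # image-only fusion width
  expect_false(sens$use_image)
  expect_equal(st$heads, "o2")
  expect_equal(unname(st$loss_weights), c(0, 1, 0))
  b <- build_model(no_se)
  expect_false(any(grepl("\\.se\\.", names(b$params))))
})

test_that("checkpoints round-trip the model, pipeline and image statistics", {
  m <- micro_model(seed = 13)
  pipe <- fit_sensor_pipeline(toy_table(), toy_schema())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, pipeline = pipe, image_stats = list(mean = 1:3, sd = 4:6))
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, m$params)
  imgs <- random_images(2, 16, seed = 4)
  xs <- with_seed_local(5, matrix(rnorm(10), 2))
  expect_identical(model_forward(ck$model, imgs, xs)$outputs,
                   model_forward(m, imgs, xs)$outputs)
  expect_equal(ck$image_stats$mean, 1:3)
})

test_that("profiling reports params, MACs and a latency figure", {
  m <- micro_model(seed = 2)
  pr <- profile_model(m, n_runs = 3)
  expect_equal(pr$params, count_params(m))
  expect_equal(pr$macs, count_macs(m))
  expect_true(is.finite(pr$latency_ms) && pr$latency_ms >= 0)
  # tiny profile is far below the full profile
  expect_lt(count_params(model_config(backbone = backbone_config("tiny"),
                                      sensor_dim = 30)),
            count_params(model_config(backbone = backbone_config("full"))))
})
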