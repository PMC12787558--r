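#' Species table of the emulated urban-tree survey
#'
#' Twelve species: four dominant ones at 27/18/14/12% of the population and
#' eight rare species at (1 - 0.71)/8 = 3.625% each. Base height and canopy
#' aspect ratio drive the biometric simulation.
#'
#' @return data.frame with `species`, `prop`, `base_height`, `aspect`.
#' @export
tree_species_table <- function() {
  data.frame(
    species = c("Platanus orientalis", "Acer negundo", "Fraxinus pennsylvanica",
                "Morus alba", "Tilia cordata", "Betula pendula", "Quercus robur",
                "Ulmus pumila", "Populus alba", "Robinia pseudoacacia",
                "Salix babylonica", "Aesculus hippocastanum"),
    prop = c(0.27, 0.18, 0.14, 0.12, rep((1 - 0.71) / 8, 8)),
    base_height = c(14, 12, 13, 9, 11, 10, 15, 9, 16, 12, 10, 13),
    aspect = c(0.55, 0.60, 0.50, 0.65, 0.60, 0.45, 0.65, 0.55, 0.40, 0.50, 0.70, 0.60))
}

#' Configure the synthetic urban-tree generator
#'
#' A latent health score `u ~ Beta(2, 2)` is discretized at the quartiles of
#' its distribution into the four ordinal classes (0 = very poor ... 3 =
#' good/healthy). Each modality observes a blurred copy of `u`:
#' `u_vis = u + N(0, s_v)` drives the rendered appearance and
#' `u_sens = u + N(0, s_s)` drives the sensor/biometric channels, so part of
#' the class signal is visual and part tabular and an oracle with both
#' modalities beats either alone. Gas targets follow
#' `O2 = a * canopy_width^2 * crown_density * (0.5 + 0.5 u) + N(0, sigma_gas)`
#' and `CO2 = 1.375 * O2 * (1 + U(-jitter, +jitter))` (44/32 molar-mass
#' stand-in coupling), in arbitrary "daily rate" units.
#'
#' @param n_trees number of trees to generate.
#' @param seed integer master seed; the full dataset is a deterministic
#'   function of (config, seed).
#' @param resolution rendered image side, 96 or 224.
#' @param species_props 12 species proportions summing to 1.
#' @param sigma_latent per-modality blur of the health latent (default
#'   0.015, giving a fused-oracle class-recovery ceiling of about 0.96 and
#'   single-modality ceilings of about 0.95).
#' @param modality_split fraction of the health signal expressed visually
#'   (0.5 splits the blur evenly; values toward 1 sharpen the visual channel
#'   by `s_m = sigma_latent / sqrt(2 * fraction_m)`).
#' @param noise_scale master multiplier on every sensor/biometric
#'   measurement noise (0 gives the noise-free limit).
#' @param sigma_gas standard deviation of the additive O2 noise, daily-rate
#'   units.
#' @param gas_coef coefficient `a` of the O2 law.
#' @param co2_jitter half-width of the uniform relative perturbation of the
#'   CO2/O2 coupling.
#' @param render_jitter pixel/texture noise scale of the renderer.
#' @param missing_rate fraction of continuous sensor cells blanked at
#'   random (emulating sensor dropouts; exercised by the imputation step).
#' @param health_shape1,health_shape2 Beta parameters of the latent prior.
#' @return object of class `tf_generator_config`.
#' @export
generator_config <- function(n_trees = 800, seed = 7, resolution = 96,
                             species_props = tree_species_table()$prop,
                             sigma_latent = 0.015, modality_split = 0.5,
                             noise_scale = 1, sigma_gas = 0.5, gas_coef = 0.4,
                             co2_jitter = 0.05, render_jitter = 0.02,
                             missing_rate = 0.02,
                             health_shape1 = 2, health_shape2 = 2) {
  stopifnot(resolution %in% c(96, 224))
  stopifnot(length(species_props) == 12, abs(sum(species_props) - 1) < 1e-8,
            all(species_props > 0))
  stopifnot(sigma_latent >= 0, noise_scale >= 0, sigma_gas >= 0,
            modality_split > 0, modality_split < 1)
  thr <- qbeta(c(0.25, 0.5, 0.75), health_shape1, health_shape2)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                 resolution = as.integer(resolution),
                 species_props = species_props,
                 sigma_latent = sigma_latent, modality_split = modality_split,
                 sigma_vis = sigma_latent / sqrt(2 * modality_split),
                 sigma_sens = sigma_latent / sqrt(2 * (1 - modality_split)),
                 noise_scale = noise_scale, sigma_gas = sigma_gas,
                 gas_coef = gas_coef, co2_jitter = co2_jitter,
                 render_jitter = render_jitter, missing_rate = missing_rate,
                 health_shape1 = health_shape1, health_shape2 = health_shape2,
                 class_thresholds = thr),
            class = "tf_generator_config")
}

# Linear links from the sensor-side health latent to the Table-1 channels:
# intercept, slope in u_sens, and measurement noise sd (scaled by
# cfg$noise_scale). Documented in the methods vignette.
sensor_channel_links <- function() {
  data.frame(
    channel = c("Soil_Moisture_pct", "Ambient_Temperature_C", "Humidity_pct",
                "CO2_ppm", "PM2.5_ug_m3", "NO2_ppb", "O3_ppb"),
    intercept = c(18, 27, 42, 470, 38, 44, 62),
    slope = c(22, -5, 18, -70, -20, -22, -16),
    sigma = c(1.5, 0.8, 2.0, 8.0, 2.5, 3.0, 4.0))
}

zone_table <- function() {
  data.frame(zone = c("park", "residential", "roadside", "industrial"),
             prob = c(0.25, 0.35, 0.25, 0.15),
             d_pm = c(-4, 0, 5, 8), d_no2 = c(-5, 0, 6, 9),
             d_o3 = c(2, 0, -2, -3), d_co2 = c(-15, 0, 20, 30))
}

#' Sample a synthetic tree population (ground-truth latent records)
#'
#' Draws species, urban zone, the health latent and its two modality views,
#' biometrics as monotone functions of (species, latent) plus measurement
#' noise, the environmental channels through the documented linear link
#' table, the gas targets, and the render parameters. Deterministic given
#' the config seed.
#'
#' @param cfg a [generator_config()].
#' @return data.frame of class `tf_population`, one row per tree.
#' @export
sample_population <- function(cfg) {
  stopifnot(inherits(cfg, "tf_generator_config"))
  n <- cfg$n_trees
  if (n < 4) stopf("need at least as many trees as health classes (4)")
  sp <- tree_species_table()
  zt <- zone_table()
  ns <- cfg$noise_scale
  pop <- with_seed(derive_seed(cfg$seed, 1), {
    species_idx <- sample.int(12, n, replace = TRUE, prob = cfg$species_props)
    zone_idx <- sample.int(4, n, replace = TRUE, prob = zt$prob)
    u <- rbeta(n, cfg$health_shape1, cfg$health_shape2)
    u_vis <- clamp(u + rnorm(n, 0, cfg$sigma_vis), 0, 1)
    u_sens <- clamp(u + rnorm(n, 0, cfg$sigma_sens), 0, 1)
    cls <- findInterval(u, cfg$class_thresholds)

    height <- clamp(sp$base_height[species_idx] * 0.85 + rnorm(n, 0, 2.0 * ns), 3, 25)
    canopy <- clamp(height * sp$aspect[species_idx] * (0.7 + 0.3 * u) +
                      rnorm(n, 0, 0.15 * ns), 0.5, 12)
    crown <- clamp(0.15 + 0.75 * u_sens + rnorm(n, 0, 0.015 * ns), 0.02, 0.98)
    bark <- clamp(5 * (1 - u_sens) + rnorm(n, 0, 0.10 * ns), 0, 5)
    leaf <- clamp(5 * (1 - u_sens) + rnorm(n, 0, 0.12 * ns), 0, 5)
    root <- clamp(3 * (1 - u_sens) + rnorm(n, 0, 0.20 * ns), 0, 3)

    links <- sensor_channel_links()
    env <- sapply(seq_len(nrow(links)), function(i)
      links$intercept[i] + links$slope[i] * u_sens + rnorm(n, 0, links$sigma[i] * ns))
    colnames(env) <- links$channel
    env[, "PM2.5_ug_m3"] <- env[, "PM2.5_ug_m3"] + zt$d_pm[zone_idx]
    env[, "NO2_ppb"] <- env[, "NO2_ppb"] + zt$d_no2[zone_idx]
    env[, "O3_ppb"] <- env[, "O3_ppb"] + zt$d_o3[zone_idx]
    env[, "CO2_ppm"] <- env[, "CO2_ppm"] + zt$d_co2[zone_idx]
    aqi <- 0.5 * env[, "PM2.5_ug_m3"] + 0.3 * env[, "NO2_ppb"] +
      0.2 * env[, "O3_ppb"] + rnorm(n, 0, 1.0 * ns)

    cd_vis <- clamp(0.15 + 0.75 * u_vis, 0.02, 0.98)
    data.frame(
      tree_id = sprintf("T%05d", seq_len(n)),
      Species = sp$species[species_idx],
      Urban_Zone = zt$zone[zone_idx],
      u = u, u_vis = u_vis, u_sens = u_sens,
      health_class = cls,
      Height_m = height, Canopy_Width_m = canopy, Crown_Density = crown,
      Bark_Damage_Score = bark, Leaf_Color_Deviation = leaf,
      Root_Exposure_Score = root,
      env, Air_Quality_Index = aqi,
      fill_frac = 0.25 + 0.65 * cd_vis,
      hue_mix = 1 - u_vis,
      damage_n = round(8 * (1 - u_vis)),
      trunk_w = 0.018 + 0.012 * height / 20,
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  pop <- derive_targets(pop, cfg)
  class(pop) <- c("tf_population", "data.frame")
  pop
}

#' Derive gas-exchange targets for a population
#'
#' `O2 = a * canopy_width^2 * crown_density * (0.5 + 0.5 u) + eps`,
#' `eps ~ N(0, sigma_gas)`; `CO2 = 1.375 * O2 * (1 + delta)`,
#' `delta ~ U(-jitter, +jitter)`. Noise-free values (`o2_clean`,
#' `co2_clean`) are kept so the injected noise level is known exactly.
#' The functional form is a documented stand-in for the physiological
#' estimation model that produced the real labels.
#'
#' @param pop population data.frame with biometrics and latent `u`.
#' @param cfg a [generator_config()].
#' @return the population with columns `o2_clean`, `O2_rate`, `co2_clean`,
#'   `CO2_rate` added.
#' @export
derive_targets <- function(pop, cfg) {
  n <- nrow(pop)
  with_seed(derive_seed(cfg$seed, 2), {
    o2_clean <- cfg$gas_coef * pop$Canopy_Width_m^2 * pop$Crown_Density *
      (0.5 + 0.5 * pop$u)
    o2 <- o2_clean + rnorm(n, 0, cfg$sigma_gas)
    delta <- runif(n, -cfg$co2_jitter, cfg$co2_jitter)
    co2 <- 1.375 * o2 * (1 + delta)
    pop$o2_clean <- o2_clean
    pop$O2_rate <- o2
    pop$co2_clean <- 1.375 * o2_clean
    pop$CO2_rate <- co2
  })
  pop
}

#' Extract the raw sensor table (the "measured" CSV view of a population)
#'
#' Keeps the schema columns plus supervision, and blanks a random fraction
#' of continuous cells to emulate sensor dropouts (imputed downstream).
#'
#' @param pop a [sample_population()] result.
#' @param cfg the generator config used.
#' @return data.frame matching [default_sensor_schema()].
#' @export
population_sensors <- function(pop, cfg) {
  schema <- default_sensor_schema()
  cols <- c(schema$id_column, schema$continuous, names(schema$categorical),
            schema$label_column, unname(schema$target_columns))
  tab <- pop[, cols]
  if (cfg$missing_rate > 0) {
    with_seed(derive_seed(cfg$seed, 3), {
      for (col in schema$continuous) {
        hit <- runif(nrow(tab)) < cfg$missing_rate
        tab[[col]][hit] <- NA
      }
    })
  }
  rownames(tab) <- NULL
  tab
}

#' Classify a (possibly blurred) health latent at the configured thresholds
#'
#' @param u numeric latent values in `[0, 1]`.
#' @param thresholds the three class boundaries (see
#'   [generator_config()]`$class_thresholds`).
#' @return integer classes 0-3.
#' @export
oracle_classify <- function(u, thresholds) findInterval(u, thresholds)

#' Class-recovery ceiling of each modality, from the generative rule itself
#'
#' The image carries the latent `u_vis`, the sensor record `u_sens`; a
#' training-free oracle thresholds the modality latent (or their mean, for
#' the fused oracle) and is scored against the true class. This bounds what
#' any model trained on one or both modalities can achieve.
#'
#' @param pop a [sample_population()] result.
#' @param modality `"fused"`, `"image"`, or `"sensor"`.
#' @param cfg the generator config (for its class thresholds).
#' @return accuracy in `[0, 1]`.
#' @export
oracle_accuracy <- function(pop, modality = c("fused", "image", "sensor"),
                            cfg = generator_config()) {
  modality <- match.arg(modality)
  u_obs <- switch(modality,
                  fused = (pop$u_vis + pop$u_sens) / 2,
                  image = pop$u_vis,
                  sensor = pop$u_sens)
  mean(oracle_classify(u_obs, cfg$class_thresholds) == pop$health_class)
}

#' Generate a complete dataset on disk
#'
#' Layout: `images/<tree_id>.png` (rendered, background-suppressed),
#' `sensors.csv` (raw sensor table with missing cells empty),
#' `truth.csv` (latents, clean gas values, class — for evaluation only),
#' `manifest.csv` (tree_id, image path) and `generator.json` (config echo).
#'
#' @param cfg a [generator_config()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the population data.frame.
#' @export
generate_dataset <- function(cfg, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stopf("output directory '%s' is not empty (use overwrite = TRUE)", dir)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  pop <- sample_population(cfg)
  sensors <- population_sensors(pop, cfg)
  images <- render_population(pop, cfg)
  paths <- file.path("images", paste0(pop$tree_id, ".png"))
  for (i in seq_len(nrow(pop)))
    png::writePNG(images[[i]], file.path(dir, paths[i]))
  write.csv(sensors, file.path(dir, "sensors.csv"), row.names = FALSE, na = "")
  truth_cols <- c("tree_id", "u", "u_vis", "u_sens", "health_class",
                  "o2_clean", "O2_rate", "co2_clean", "CO2_rate")
  write.csv(pop[, truth_cols], file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(data.frame(tree_id = pop$tree_id, path = paths),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pop)
}

#' Load a generated dataset from disk
#'
#' @param dir a directory written by [generate_dataset()].
#' @return list with `sensors`, `truth`, `manifest` data.frames and
#'   `images` (named list of `[H, W, 3]` arrays).
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  sensors <- read.csv(file.path(dir, "sensors.csv"), stringsAsFactors = FALSE,
                      check.names = FALSE)
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) load_image(file.path(dir, p)))
  names(images) <- manifest$tree_id
  list(sensors = sensors, truth = truth, manifest = manifest, images = images)
}
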