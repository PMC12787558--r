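test_that("species sampling matches the configured mix within multinomial tolerance", {
  cfg <- generator_config(n_trees = 1000, seed = 21)
  pop <- sample_population(cfg)
  counts <- table(factor(pop$Species, levels = tree_species_table()$species))
  expected <- 1000 * tree_species_table()$prop          # 270/180/140/120 + rare
  tol <- 3 * sqrt(1000 * tree_species_table()$prop * (1 - tree_species_table()$prop))
  expect_true(all(abs(as.numeric(counts) - expected) <= tol))
  # rare species proportion: (1 - 0.71) / 8 each
  expect_equal(tree_species_table()$prop[5], 0.03625)
  expect_equal(sum(tree_species_table()$prop), 1)
})

test_that("population sampling is bit-identical under one seed and differs across seeds", {
  cfg <- generator_config(n_trees = 60, seed = 5)
  expect_identical(sample_population(cfg), sample_population(cfg))
  cfg2 <- generator_config(n_trees = 60, seed = 6)
  expect_false(identical(sample_population(cfg)$u, sample_population(cfg2)$u))
})

test_that("noise-free limit: biometrics are exact functions of (species, latent)", {
  cfg <- generator_config(n_trees = 120, seed = 9, noise_scale = 0,
                          sigma_latent = 0, sigma_gas = 0, co2_jitter = 0,
                          missing_rate = 0)
  pop <- sample_population(cfg)
  sp <- tree_species_table()
  base <- sp$base_height[match(pop$Species, sp$species)]
  aspect <- sp$aspect[match(pop$Species, sp$species)]
  expect_equal(pop$Height_m, pmin(pmax(base * 0.85, 3), 25))
  expect_equal(pop$Canopy_Width_m,
               pmin(pmax(pop$Height_m * aspect * (0.7 + 0.3 * pop$u), 0.5), 12))
  expect_equal(pop$Crown_Density, pmin(pmax(0.15 + 0.75 * pop$u, 0.02), 0.98))
  expect_equal(pop$u_vis, pop$u)
  expect_equal(pop$u_sens, pop$u)
})

test_that("gas law: square growth in canopy width, zero at zero density, exact 1.375 coupling", {
  cfg <- generator_config(n_trees = 10, seed = 2, sigma_gas = 0, co2_jitter = 0)
  base <- data.frame(Canopy_Width_m = c(2, 4, 3, 3), Crown_Density = c(0.5, 0.5, 0, 0.8),
                     u = c(1, 1, 0.4, 0.6))
  out <- derive_targets(base, cfg)
  # doubling canopy width quadruples the noise-free O2
  expect_equal(out$o2_clean[2], 4 * out$o2_clean[1])
  # zero crown density zeroes the noise-free rate entirely
  expect_equal(out$O2_rate[3], 0)
  # molar-mass stand-in coupling 44/32 = 1.375, exact without jitter
  nz <- out$O2_rate != 0
  expect_equal(out$CO2_rate[nz] / out$O2_rate[nz], rep(1.375, sum(nz)))

  # with default noise the coupling stays near-perfect in correlation
  pop <- sample_population(generator_config(n_trees = 600, seed = 13))
  expect_gte(cor(pop$O2_rate, pop$CO2_rate), 0.95)
})

test_that("health classes are the thresholded latent for every record", {
  cfg <- generator_config(n_trees = 500, seed = 17)
  pop <- sample_population(cfg)
  expect_identical(pop$health_class,
                   oracle_classify(pop$u, cfg$class_thresholds))
  expect_true(all(pop$health_class %in% 0:3))
  # quartile thresholds represent all four classes materially
  expect_true(all(table(pop$health_class) > 0.15 * 500))
})

test_that("modality split: the fused oracle beats either single-modality oracle and clears 0.95", {
  cfg <- generator_config(n_trees = 40000, seed = 29)
  pop <- sample_population(cfg)
  acc_fused <- oracle_accuracy(pop, "fused", cfg)
  acc_img <- oracle_accuracy(pop, "image", cfg)
  acc_sens <- oracle_accuracy(pop, "sensor", cfg)
  expect_gte(acc_fused, 0.95)                 # Bayes-style ceiling of the rule
  expect_gt(acc_fused, acc_img)
  expect_gt(acc_fused, acc_sens)
})

test_that("renderer is deterministic and its health channels behave as documented", {
  cfg <- generator_config(n_trees = 8, seed = 3)
  pop <- sample_population(cfg)
  img1 <- render_tree(pop[1, ], cfg)
  expect_identical(img1, render_tree(pop[1, ], cfg))   # same (tree, seed)
  expect_false(identical(img1, render_tree(pop[2, ], cfg)))
  expect_equal(dim(img1), c(96, 96, 3))
  expect_true(all(img1 >= 0 & img1 <= 1))

  # perfectly healthy tree, zero jitter: canopy pixels sit at the healthy green
  cfg0 <- generator_config(n_trees = 8, seed = 3, render_jitter = 0)
  tr <- pop[1, ]
  tr$u_vis <- 1; tr$hue_mix <- 0; tr$damage_n <- 0
  img <- render_tree(tr, cfg0)
  greens <- img[, , 2]
  expect_equal(max(greens), 0.55)
  hit <- which(greens == 0.55, arr.ind = TRUE)[1, ]
  expect_equal(img[hit[1], hit[2], 1], 0.20)
  expect_equal(img[hit[1], hit[2], 3], 0.16)

  # foreground pixel fraction increases strictly with crown density
  lo <- tr; lo$fill_frac <- 0.25 + 0.65 * 0.2
  hi <- tr; hi$fill_frac <- 0.25 + 0.65 * 0.9
  expect_lt(foreground_fraction(render_tree(lo, cfg0)),
            foreground_fraction(render_tree(hi, cfg0)))
})

test_that("dataset writer produces aligned, reproducible files and refuses to clobber", {
  cfg <- generator_config(n_trees = 12, seed = 31)
  dir1 <- tempfile("ds1_"); dir2 <- tempfile("ds2_")
  pop <- generate_dataset(cfg, dir1)
  expect_length(list.files(file.path(dir1, "images")), 12)
  sens <- read.csv(file.path(dir1, "sensors.csv"), check.names = FALSE)
  man <- read.csv(file.path(dir1, "manifest.csv"))
  expect_equal(nrow(sens), 12)
  expect_identical(sort(man$tree_id), sort(sens$tree_id))
  # regeneration with the same config gives identical checksums
  generate_dataset(cfg, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(dir1, f1))),
                   unname(tools::md5sum(file.path(dir2, f1))))
  # non-empty directory without the overwrite flag is an error
  expect_error(generate_dataset(cfg, dir1), "not empty")
  expect_silent(generate_dataset(cfg, dir1, overwrite = TRUE))

  # round trip through the loader pairs every image with its record
  ds <- load_dataset(dir1)
  al <- align_by_tree_id(ds$manifest, ds$sensors)
  expect_equal(nrow(al$pairs), 12)
  expect_length(ds$images, 12)
  expect_equal(dim(ds$images[[1]]), c(96, 96, 3))
})

test_that("sensor table carries the schema columns and the configured missingness", {
  cfg <- generator_config(n_trees = 400, seed = 37)
  pop <- sample_population(cfg)
  sens <- population_sensors(pop, cfg)
  schema <- default_sensor_schema()
  expect_true(all(c(schema$continuous, names(schema$categorical),
                    "health_class", "O2_rate", "CO2_rate") %in% names(sens)))
  miss <- mean(is.na(as.matrix(sens[, schema$continuous])))
  expect_gt(miss, 0.005); expect_lt(miss, 0.05)       # around the 2% default
  # labels and targets are never blanked
  expect_false(anyNA(sens$health_class))
  expect_false(anyNA(sens$O2_rate))
})
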