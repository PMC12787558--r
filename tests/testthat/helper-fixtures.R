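# Shared fixtures, built in code.

# A small raw sensor table exercising missing values and both categoricals.
toy_schema <- function() {
  sensor_schema(
    continuous = c("soil", "temp"),
    categorical = list(kind = c("a", "b", "c"), zone = c("x", "y")),
    id_column = "tree_id", label_column = "health_class",
    target_columns = c(o2 = "O2_rate", co2 = "CO2_rate"))
}

toy_table <- function() {
  data.frame(
    tree_id = paste0("t", 1:6),
    soil = c(1.0, NA, 3.0, 2.0, 4.0, 2.0),
    temp = c(10, 12, NA, 11, 13, 12),
    kind = c("a", "a", NA, "b", "c", "a"),
    zone = c("x", "y", "x", NA, "y", "x"),
    health_class = c(0, 1, 2, 3, 1, 2),
    O2_rate = c(1.5, 2.0, 2.5, 3.0, 2.2, 1.8),
    CO2_rate = c(2.1, 2.8, 3.4, 4.1, 3.0, 2.5),
    stringsAsFactors = FALSE)
}

# A micro backbone (16px input, two stages, stride product 4 after the stem)
# small enough for finite-difference checks and brute-force oracles.
micro_model <- function(seed = 42, use_se = TRUE, resolution = 16) {
  stages <- data.frame(expand = c(1, 6), kernel = c(3, 5), stride = c(1, 2),
                       out_ch = c(6, 8), repeats = c(1, 2))
  bb <- custom_backbone_config(6, stages, 12, resolution, use_se = use_se)
  cfg <- model_config(backbone = bb, sensor_dim = 5, sensor_hidden = 7,
                      sensor_embed = 4, head_hidden = 6, seed = seed)
  build_model(cfg)
}

random_images <- function(n, res, seed = 1) {
  with_seed_local(seed, lapply(seq_len(n), function(i)
    array(runif(res * res * 3), dim = c(res, res, 3))))
}

# Seed helper that does not disturb the test RNG stream.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Fast generator settings for smoke-scale training tests.
small_generator <- function(n = 80, seed = 11) generator_config(n_trees = n, seed = seed)
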