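#' Impute missing values in a raw sensor table
#'
#' Continuous columns are filled with the column mean of observed values,
#' categorical columns with the most frequent observed category (ties broken
#' by vocabulary order). Observed values are never modified. Statistics can
#' be supplied (fitted on a training split) so that evaluation data are
#' imputed without leakage.
#'
#' @param table data.frame with the schema's columns; missing values as `NA`
#'   (empty cells when read from CSV).
#' @param schema a [sensor_schema()].
#' @param stats optional imputation statistics from [fit_imputation()];
#'   when `NULL`, statistics are computed from `table` itself.
#' @return The table with no missing values in schema columns.
#' @export
impute_missing <- function(table, schema, stats = NULL) {
  check_schema_columns(table, schema)
  if (is.null(stats)) stats <- fit_imputation(table, schema)
  for (col in schema$continuous) {
    v <- table[[col]]
    v[is.na(v)] <- stats$means[[col]]
    table[[col]] <- v
  }
  for (col in names(schema$categorical)) {
    v <- as.character(table[[col]])
    v[is.na(v)] <- stats$modes[[col]]
    table[[col]] <- v
  }
  table
}

#' Fit imputation statistics (column means and modes)
#'
#' @inheritParams impute_missing
#' @return list with `means` (per continuous column) and `modes`
#'   (per categorical column). A column with no observed value is an error.
#' @export
fit_imputation <- function(table, schema) {
  check_schema_columns(table, schema)
  means <- list(); modes <- list()
  for (col in schema$continuous) {
    v <- table[[col]]
    if (!is.numeric(v)) stopf("continuous column '%s' is not numeric", col)
    if (all(is.na(v))) stopf("column '%s' has no observed values", col)
    means[[col]] <- mean(v, na.rm = TRUE)
  }
  for (col in names(schema$categorical)) {
    v <- as.character(table[[col]])
    v <- v[!is.na(v)]
    if (length(v) == 0) stopf("column '%s' has no observed values", col)
    vocab <- schema$categorical[[col]]
    counts <- table(factor(v, levels = vocab))
    modes[[col]] <- vocab[which.max(counts)]
  }
  list(means = means, modes = modes)
}

#' One-hot encode the categorical columns of records
#'
#' Each categorical column expands to an indicator block of the size of its
#' vocabulary with exactly one 1 per record.
#'
#' @param records data.frame of one or more raw records (no missing values in
#'   categorical columns).
#' @param schema a [sensor_schema()].
#' @param unknown policy for out-of-vocabulary values: `"error"` (default,
#'   strict) or `"zero"` (emit an all-zero block).
#' @return numeric matrix, rows = records, columns = concatenated indicator
#'   blocks in schema order.
#' @export
one_hot_encode <- function(records, schema, unknown = c("error", "zero")) {
  unknown <- match.arg(unknown)
  blocks <- lapply(names(schema$categorical), function(col) {
    vocab <- schema$categorical[[col]]
    v <- as.character(records[[col]])
    idx <- match(v, vocab)
    if (anyNA(idx) && unknown == "error") {
      bad <- unique(v[is.na(idx)])
      stopf("unknown categor%s in '%s': %s",
            if (length(bad) > 1) "ies" else "y", col, paste(bad, collapse = ", "))
    }
    m <- matrix(0, nrow = length(v), ncol = length(vocab),
                dimnames = list(NULL, paste(col, vocab, sep = ".")))
    ok <- !is.na(idx)
    m[cbind(which(ok), idx[ok])] <- 1
    m
  })
  do.call(cbind, blocks)
}

#' Fit z-score standardization statistics on the training split
#'
#' Means and standard deviations of every continuous column and of the two
#' gas-regression targets, using the population convention (divide by n) so
#' the fit set has unit variance exactly. Must be called on the training
#' split only; evaluation data are transformed with these statistics.
#'
#' @param train data.frame of training records (already imputed).
#' @param schema a [sensor_schema()].
#' @param on_constant what to do with a zero-variance column: `"error"`
#'   (default) or `"drop"` (exclude it from the feature set with a warning).
#' @return list of class `tf_standardization` with `mean`, `sd`, `columns`,
#'   and `targets` (per-target mean/sd) entries.
#' @export
fit_standardization <- function(train, schema, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  check_schema_columns(train, schema)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  cols <- schema$continuous
  mu <- vapply(cols, function(cl) mean(train[[cl]]), 0)
  sg <- vapply(cols, function(cl) pop_sd(train[[cl]]), 0)
  if (any(sg <= 0)) {
    bad <- cols[sg <= 0]
    if (on_constant == "error")
      stopf("zero-variance continuous column(s): %s", paste(bad, collapse = ", "))
    warning(sprintf("dropping zero-variance column(s): %s", paste(bad, collapse = ", ")))
    keep <- sg > 0
    cols <- cols[keep]; mu <- mu[keep]; sg <- sg[keep]
  }
  targets <- NULL
  if (!is.null(schema$target_columns) &&
      all(schema$target_columns %in% names(train))) {
    targets <- lapply(schema$target_columns, function(cl) {
      s <- pop_sd(train[[cl]])
      if (s <= 0) stopf("zero-variance target column '%s'", cl)
      list(mean = mean(train[[cl]]), sd = s)
    })
    names(targets) <- names(schema$target_columns)
  }
  structure(list(columns = cols, mean = mu, sd = sg, targets = targets),
            class = "tf_standardization")
}

#' Apply (or invert) fitted z-score standardization
#'
#' @param records data.frame with the fitted continuous columns.
#' @param stats a `tf_standardization` from [fit_standardization()].
#' @return `apply_standardization`: the records with continuous columns
#'   transformed to `(x - mean)/sd`.
#' @export
apply_standardization <- function(records, stats) {
  for (i in seq_along(stats$columns)) {
    cl <- stats$columns[i]
    records[[cl]] <- (records[[cl]] - stats$mean[i]) / stats$sd[i]
  }
  records
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(records, stats) {
  for (i in seq_along(stats$columns)) {
    cl <- stats$columns[i]
    records[[cl]] <- records[[cl]] * stats$sd[i] + stats$mean[i]
  }
  records
}

#' Standardize / unstandardize gas-regression targets
#'
#' @param x numeric vector of target values (`standardize_targets`) or of
#'   standardized values (`unstandardize_targets`).
#' @param stats a `tf_standardization`.
#' @param which `"o2"` or `"co2"`.
#' @export
standardize_targets <- function(x, stats, which = c("o2", "co2")) {
  which <- match.arg(which)
  t <- stats$targets[[which]]
  (x - t$mean) / t$sd
}

#' @rdname standardize_targets
#' @export
unstandardize_targets <- function(x, stats, which = c("o2", "co2")) {
  which <- match.arg(which)
  t <- stats$targets[[which]]
  x * t$sd + t$mean
}

#' Pair an image manifest with a sensor table by tree ID
#'
#' Keeps one paired sample per ID present in both sources; IDs present in
#' only one source are reported in the result and excluded. A duplicated ID
#' within either source is a hard error.
#'
#' @param image_manifest data.frame with at least `tree_id` (and typically a
#'   `path` column).
#' @param sensor_table data.frame keyed by the schema's ID column.
#' @param id_column name of the key column in both sources.
#' @return list with `pairs` (merged data.frame), `dropped_images`,
#'   `dropped_records` (character vectors of unmatched IDs).
#' @export
align_by_tree_id <- function(image_manifest, sensor_table, id_column = "tree_id") {
  ids_img <- as.character(image_manifest[[id_column]])
  ids_tab <- as.character(sensor_table[[id_column]])
  if (anyDuplicated(ids_img))
    stopf("duplicated tree ID in image manifest: %s",
          paste(unique(ids_img[duplicated(ids_img)]), collapse = ", "))
  if (anyDuplicated(ids_tab))
    stopf("duplicated tree ID in sensor table: %s",
          paste(unique(ids_tab[duplicated(ids_tab)]), collapse = ", "))
  common <- intersect(ids_img, ids_tab)
  pairs <- merge(image_manifest, sensor_table, by = id_column, sort = TRUE)
  list(pairs = pairs,
       dropped_images = setdiff(ids_img, common),
       dropped_records = setdiff(ids_tab, common))
}

#' Stratified train/test split
#'
#' Samples `round(test_fraction * n_c)` test items per class `c`, so test
#' class proportions track the full-data proportions. Deterministic for a
#' given seed.
#'
#' @param labels vector of class labels (one per sample).
#' @param test_fraction fraction of each class assigned to the test split.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stopf("every class needs >= 2 samples; got: %s",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  test_idx <- integer(0)
  with_seed(derive_seed(seed, 101), {
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      n_test <- max(1L, round(test_fraction * length(idx)))
      test_idx <- c(test_idx, sort(sample(idx, n_test)))
    }
  })
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}

#' Fit the full tabular preprocessing pipeline on a training split
#'
#' Chains imputation (means/modes), one-hot vocabulary binding, and z-score
#' standardization of continuous features and gas targets, all fitted on the
#' training records only.
#'
#' @param train data.frame of raw training records.
#' @param schema a [sensor_schema()].
#' @param on_constant forwarded to [fit_standardization()].
#' @return object of class `tf_pipeline`.
#' @export
fit_sensor_pipeline <- function(train, schema, on_constant = "error") {
  imput <- fit_imputation(train, schema)
  train_imp <- impute_missing(train, schema, imput)
  stand <- fit_standardization(train_imp, schema, on_constant)
  structure(list(schema = schema, imputation = imput, standardization = stand),
            class = "tf_pipeline")
}

#' Transform raw records into model-ready feature vectors
#'
#' @param pipeline a fitted [fit_sensor_pipeline()].
#' @param records data.frame of raw records (training or evaluation).
#' @param unknown out-of-vocabulary policy, see [one_hot_encode()].
#' @return list with `x` (numeric matrix, continuous block then one-hot
#'   blocks), `labels` (integer 0-3 or `NULL`), `targets` (matrix of raw o2 /
#'   co2 or `NULL`) and `targets_std` (standardized targets).
#' @export
transform_sensors <- function(pipeline, records, unknown = "error") {
  schema <- pipeline$schema
  rec <- impute_missing(records, schema, pipeline$imputation)
  rec <- apply_standardization(rec, pipeline$standardization)
  xc <- as.matrix(rec[, pipeline$standardization$columns, drop = FALSE])
  storage.mode(xc) <- "double"
  xk <- one_hot_encode(rec, schema, unknown)
  x <- cbind(xc, xk)
  labels <- NULL
  if (!is.null(schema$label_column) && schema$label_column %in% names(rec)) {
    labels <- as.integer(rec[[schema$label_column]])
    if (any(!labels %in% 0:3))
      stopf("health labels must be in {0,1,2,3}")
  }
  targets <- targets_std <- NULL
  if (!is.null(schema$target_columns) &&
      all(schema$target_columns %in% names(rec)) &&
      !is.null(pipeline$standardization$targets)) {
    targets <- cbind(o2  = rec[[schema$target_columns[["o2"]]]],
                     co2 = rec[[schema$target_columns[["co2"]]]])
    targets_std <- cbind(
      o2  = standardize_targets(targets[, "o2"], pipeline$standardization, "o2"),
      co2 = standardize_targets(targets[, "co2"], pipeline$standardization, "co2"))
  }
  list(x = x, labels = labels, targets = targets, targets_std = targets_std,
       tree_id = as.character(rec[[schema$id_column]]))
}

#' Serialize a fitted pipeline to JSON (and back)
#'
#' The sidecar holds the imputation means/modes, standardization means/sds,
#' target statistics and categorical vocabularies so that inference is
#' reproducible from the file alone.
#'
#' @param pipeline a `tf_pipeline`.
#' @param path file path for the JSON sidecar.
#' @export
pipeline_to_json <- function(pipeline, path) {
  obj <- list(
    schema = list(continuous = pipeline$schema$continuous,
                  categorical = pipeline$schema$categorical,
                  id_column = pipeline$schema$id_column,
                  label_column = pipeline$schema$label_column,
                  target_columns = as.list(pipeline$schema$target_columns)),
    imputation = pipeline$imputation,
    standardization = list(columns = pipeline$standardization$columns,
                           mean = as.list(pipeline$standardization$mean),
                           sd = as.list(pipeline$standardization$sd),
                           targets = pipeline$standardization$targets))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_to_json
#' @export
pipeline_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- sensor_schema(
    continuous = unlist(obj$schema$continuous),
    categorical = lapply(obj$schema$categorical, unlist),
    id_column = obj$schema$id_column,
    label_column = obj$schema$label_column,
    target_columns = unlist(obj$schema$target_columns))
  stand <- structure(list(
    columns = unlist(obj$standardization$columns),
    mean = unlist(obj$standardization$mean),
    sd = unlist(obj$standardization$sd),
    targets = lapply(obj$standardization$targets, function(t)
      list(mean = t$mean, sd = t$sd))), class = "tf_standardization")
  structure(list(schema = schema,
                 imputation = list(means = lapply(obj$imputation$means, as.numeric),
                                   modes = lapply(obj$imputation$modes, as.character)),
                 standardization = stand),
            class = "tf_pipeline")
}
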