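#' Describe the layout of a per-tree sensor/biometric table
#'
#' A schema names the continuous columns (environmental channels and
#' biometrics), the categorical columns with their category vocabularies,
#' the tree-ID key column, and (optionally) the supervision columns
#' (health class label and the two gas-regression targets).
#'
#' @param continuous character vector of continuous column names, in order.
#' @param categorical named list; one entry per categorical column giving its
#'   full category vocabulary (character vector), in order.
#' @param id_column name of the tree-ID key column.
#' @param label_column name of the 4-class health label column (values 0-3),
#'   or `NULL` for unlabelled tables.
#' @param target_columns named character vector with entries `o2` and `co2`
#'   naming the gas-rate target columns, or `NULL`.
#' @return An object of class `tf_schema`.
#' @export
sensor_schema <- function(continuous, categorical, id_column = "tree_id",
                          label_column = "health_class",
                          target_columns = c(o2 = "O2_rate", co2 = "CO2_rate")) {
  stopifnot(is.character(continuous), length(continuous) > 0)
  stopifnot(is.list(categorical), length(names(categorical)) == length(categorical))
  if (length(intersect(continuous, names(categorical))) > 0)
    stopf("continuous and categorical column sets must be disjoint")
  for (nm in names(categorical)) {
    if (length(categorical[[nm]]) < 1)
      stopf("empty category vocabulary for column '%s'", nm)
    if (anyDuplicated(categorical[[nm]]))
      stopf("duplicated categories in vocabulary for column '%s'", nm)
  }
  structure(list(continuous = continuous,
                 categorical = lapply(categorical, as.character),
                 id_column = id_column,
                 label_column = label_column,
                 target_columns = target_columns),
            class = "tf_schema")
}

#' Reference schema of the urban-tree sensor table
#'
#' Eight environmental channels (soil moisture, ambient temperature,
#' humidity, CO2, PM2.5, NO2, O3, and a composite air-quality index), six
#' biometric measurements/scores, plus two categoricals: the 12-species mix
#' and a 4-level urban-zone classification. Width of the encoded feature
#' vector: 14 continuous + 12 + 4 one-hot = 30.
#'
#' @return A `tf_schema`.
#' @export
default_sensor_schema <- function() {
  sensor_schema(
    continuous = c("Soil_Moisture_pct", "Ambient_Temperature_C", "Humidity_pct",
                   "CO2_ppm", "PM2.5_ug_m3", "NO2_ppb", "O3_ppb",
                   "Air_Quality_Index",
                   "Height_m", "Canopy_Width_m", "Crown_Density",
                   "Bark_Damage_Score", "Leaf_Color_Deviation", "Root_Exposure_Score"),
    categorical = list(
      Species = tree_species_table()$species,
      Urban_Zone = c("park", "residential", "roadside", "industrial")
    )
  )
}

#' Width of the encoded feature vector implied by a schema
#'
#' @param schema a `tf_schema`.
#' @return integer: number of continuous columns plus the summed sizes of the
#'   categorical vocabularies.
#' @export
encoded_width <- function(schema) {
  stopifnot(inherits(schema, "tf_schema"))
  length(schema$continuous) + sum(lengths(schema$categorical))
}

#' @export
print.tf_schema <- function(x, ...) {
  cat("Sensor table schema\n")
  cat(sprintf("  id column   : %s\n", x$id_column))
  cat(sprintf("  continuous  : %d columns\n", length(x$continuous)))
  cat(sprintf("  categorical : %s\n",
              paste(sprintf("%s(%d)", names(x$categorical), lengths(x$categorical)),
                    collapse = ", ")))
  cat(sprintf("  encoded width: %d\n", encoded_width(x)))
  invisible(x)
}

check_schema_columns <- function(table, schema, need_targets = FALSE) {
  cols <- c(schema$continuous, names(schema$categorical), schema$id_column)
  if (need_targets) cols <- c(cols, schema$label_column, unname(schema$target_columns))
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0)
    stopf("table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}
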