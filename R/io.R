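#' Read a tabular dataset from CSV or ARFF
#'
#' CSV files are comma-separated UTF-8 with a header row (RFC 4180 quoting,
#' as distributed by the public heart-disease datasets); ARFF files carry
#' their own attribute declarations, which become the schema. Numeric
#' columns are parsed as numbers; empty CSV cells become missing values.
#' Sentinel codes that stand for "not recorded" (for example a cholesterol
#' of 0) can be mapped to missing per feature.
#'
#' @param path file path.
#' @param format `"csv"` or `"arff"`; defaults to the file extension.
#' @param class_name name of the class column.
#' @param positive_label class value meaning risk present (default: `"Yes"`
#'   if present, otherwise the first class value).
#' @param missing_sentinels named list, e.g. `list(Cholesterol = 0)`: values
#'   to recode as missing before the schema is inferred.
#' @param schema optional [feature_schema()] overriding inference.
#' @return an [item_table()].
#' @export
read_table <- function(path, format = c("auto", "csv", "arff"),
                       class_name, positive_label = NULL,
                       missing_sentinels = list(), schema = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "csv") {
    data <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                      check.names = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop("CSV parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  } else {
    data <- tryCatch(
      foreign::read.arff(path),
      error = function(e) stop("ARFF parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    # keep declared nominal levels for the schema
    if (is.null(schema)) {
      feats <- lapply(data, function(col) {
        if (is.numeric(col)) "numeric" else levels(as.factor(col))
      })
      if (!class_name %in% names(feats))
        stop("unknown class name: ", class_name)
      if (is.null(positive_label)) {
        vals <- feats[[class_name]]
        positive_label <- if ("Yes" %in% vals) "Yes" else vals[1L]
      }
      data <- apply_sentinels(data, missing_sentinels)
      schema <- feature_schema(feats, class_name, positive_label)
      return(item_table(data, schema = schema))
    }
  }
  data <- apply_sentinels(data, missing_sentinels)
  item_table(data, schema = schema, class_name = class_name,
             positive_label = positive_label)
}

apply_sentinels <- function(data, missing_sentinels) {
  for (nm in names(missing_sentinels)) {
    if (!nm %in% names(data)) stop("missing-sentinel feature not in data: ", nm)
    data[[nm]][data[[nm]] %in% missing_sentinels[[nm]]] <- NA
  }
  data
}

#' Write an item table to CSV
#'
#' @param table an [item_table()].
#' @param path output path; missing values are written as empty cells.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}

schema_to_list <- function(schema) {
  list(
    features = lapply(seq_along(schema$features), function(i) {
      nm <- names(schema$features)[i]
      if (schema$kinds[[nm]] == "numeric") list(name = nm, kind = "numeric")
      else list(name = nm, kind = "categorical",
                values = as.list(schema$features[[nm]]))
    }),
    class_name = schema$class_name,
    positive_label = schema$positive_label
  )
}

#' Export a schema as JSON
#'
#' @param schema a [feature_schema()].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
schema_to_json <- function(schema, path = NULL) {
  json <- jsonlite::toJSON(schema_to_list(schema), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(path)) }
  json
}

itemset_to_list <- function(s) {
  lapply(unclass(s), function(it) {
    if (it$type == "eq") list(feature = it$feature, value = it$value)
    else list(feature = it$feature, lo = it$lo, hi = it$hi)
  })
}

itemset_from_list <- function(lst) {
  itemset(lapply(lst, function(el) {
    if (!is.null(el$value)) item(el$feature, value = el$value)
    else item(el$feature,
              lo = if (is.null(el$lo)) -Inf else el$lo,
              hi = if (is.null(el$hi)) Inf else el$hi)
  }))
}
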