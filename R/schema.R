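#' Define a feature schema for a tabular dataset
#'
#' A schema records, in order, every feature of a dataset together with its
#' kind (categorical with an enumerated value set, or numeric), and singles
#' out one binary categorical feature as the class, with a designated
#' positive label meaning "disease / risk present".
#'
#' @param features named list, in column order. Each element is either a
#'   character vector (the enumerated value set of a categorical feature) or
#'   the string `"numeric"`.
#' @param class_name name of the class feature; must be categorical with
#'   exactly two values.
#' @param positive_label the class value meaning risk present; must be one of
#'   the class feature's two values.
#' @return an object of class `feature_schema`.
#' @examples
#' feature_schema(
#'   features = list(Age = "numeric", Sex = c("M", "F"), cls = c("Yes", "No")),
#'   class_name = "cls", positive_label = "Yes"
#' )
#' @export
feature_schema <- function(features, class_name, positive_label) {
  if (is.null(names(features)) || anyDuplicated(names(features)))
    stop("feature names must be unique and non-empty")
  kinds <- vapply(features, function(f) {
    if (identical(f, "numeric")) "numeric" else "categorical"
  }, character(1))
  if (!class_name %in% names(features))
    stop("unknown class name: ", class_name)
  cls_values <- features[[class_name]]
  if (kinds[[class_name]] != "categorical" || length(cls_values) != 2L)
    stop("class feature must be categorical with exactly two values")
  if (!positive_label %in% cls_values)
    stop("positive label ", positive_label, " is not a class value")
  structure(
    list(features = features, kinds = kinds,
         class_name = class_name, positive_label = positive_label,
         negative_label = setdiff(cls_values, positive_label)),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$features), "features\n")
  for (nm in names(x$features)) {
    tag <- if (nm == x$class_name) " [class]" else ""
    if (x$kinds[[nm]] == "numeric") {
      cat("  ", nm, ": numeric", tag, "\n", sep = "")
    } else {
      cat("  ", nm, ": {", paste(x$features[[nm]], collapse = ", "), "}",
          tag, "\n", sep = "")
    }
  }
  cat("Positive label:", x$positive_label, "\n")
  invisible(x)
}

predictor_names <- function(schema) {
  setdiff(names(schema$features), schema$class_name)
}

#' Bind a data frame to a schema as an item table
#'
#' @param data a data frame whose columns conform to `schema` (numeric
#'   columns numeric, categorical columns character/factor with values from
#'   the enumerated set or `NA`).
#' @param schema a [feature_schema()]. If `NULL`, it is inferred: numeric
#'   columns become numeric features, everything else categorical with the
#'   observed values as the value set.
#' @param class_name,positive_label used when inferring the schema.
#' @return an object of class `item_table`: the data frame with the schema
#'   attached.
#' @export
item_table <- function(data, schema = NULL, class_name = NULL,
                       positive_label = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 1L) stop("item table must have at least one row")
  if (is.null(schema)) {
    if (is.null(class_name)) stop("class_name needed to infer a schema")
    feats <- lapply(data, function(col) {
      if (is.numeric(col)) "numeric" else sort(unique(as.character(col[!is.na(col)])))
    })
    if (is.null(positive_label)) {
      vals <- feats[[class_name]]
      hit <- intersect(c("Yes", "Y", "yes", "1", "TRUE"), vals)
      positive_label <- if (length(hit)) hit[1L] else vals[1L]
    }
    schema <- feature_schema(feats, class_name, positive_label)
  }
  missing_cols <- setdiff(names(schema$features), names(data))
  if (length(missing_cols))
    stop("data lacks schema feature(s): ", paste(missing_cols, collapse = ", "))
  data <- data[names(schema$features)]
  for (nm in names(schema$features)) {
    if (schema$kinds[[nm]] == "numeric") {
      if (!is.numeric(data[[nm]])) data[[nm]] <- as.numeric(data[[nm]])
    } else {
      data[[nm]] <- as.character(data[[nm]])
      bad <- !is.na(data[[nm]]) & !data[[nm]] %in% schema$features[[nm]]
      if (any(bad))
        stop("feature ", nm, " holds value(s) outside its schema set: ",
             paste(unique(data[[nm]][bad]), collapse = ", "))
    }
  }
  structure(list(schema = schema, data = data), class = "item_table")
}

#' @export
print.item_table <- function(x, ...) {
  cat("Item table:", nrow(x$data), "rows,",
      length(predictor_names(x$schema)), "predictors, class",
      x$schema$class_name, "\n")
  invisible(x)
}

#' @export
dim.item_table <- function(x) dim(x$data)

n_rows <- function(table) nrow(table$data)

class_vector <- function(table) table$data[[table$schema$class_name]]

positive_mask <- function(table) {
  class_vector(table) == table$schema$positive_label
}

subset_table <- function(table, keep) {
  if (!any(keep)) {
    out <- table
    out$data <- table$data[0L, , drop = FALSE]
    return(out)
  }
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Construct a single item (feature predicate)
#'
#' An item is a predicate on one feature: equality to a categorical value,
#' or membership of a half-open numeric interval `(lo, hi]`. Open ends are
#' allowed, rendered `"> lo"` and `"<= hi"`.
#'
#' @param feature feature name.
#' @param value categorical value for an equality item (mutually exclusive
#'   with `lo`/`hi`).
#' @param lo,hi numeric interval bounds, `(lo, hi]`; either may be infinite.
#' @return an object of class `item`.
#' @examples
#' item("Sex", value = "M")
#' item("Oldpeak", lo = 0.85) # renders as {Oldpeak > 0.85}
#' @export
item <- function(feature, value = NULL, lo = -Inf, hi = Inf) {
  stopifnot(is.character(feature), length(feature) == 1L)
  if (!is.null(value)) {
    it <- list(feature = feature, type = "eq", value = as.character(value))
  } else {
    if (!(lo < hi)) stop("numeric item interval must be non-empty (lo < hi)")
    if (is.infinite(lo) && is.infinite(hi))
      stop("numeric item must bound at least one end")
    it <- list(feature = feature, type = "interval", lo = lo, hi = hi)
  }
  structure(it, class = "item")
}

item_key <- function(it) {
  if (it$type == "eq") paste0(it$feature, "=", it$value)
  else paste0(it$feature, ":(", format(it$lo, digits = 12), ",",
              format(it$hi, digits = 12), "]")
}

format_item <- function(it) {
  if (it$type == "eq") return(paste0(it$feature, " = ", it$value))
  if (is.infinite(it$hi)) return(paste0(it$feature, " > ", format(it$lo)))
  if (is.infinite(it$lo)) return(paste0(it$feature, " <= ", format(it$hi)))
  paste0(it$feature, " in (", format(it$lo), ", ", format(it$hi), "]")
}

#' @export
print.item <- function(x, ...) {
  cat("{", format_item(x), "}\n", sep = "")
  invisible(x)
}

#' Construct an itemset
#'
#' A conjunction of [item()]s over pairwise-distinct features. The empty
#' itemset (the domain antecedent) is permitted and matches every instance.
#'
#' @param ... items, or a single list of items.
#' @return an object of class `itemset`, sorted by feature name for a
#'   canonical order.
#' @export
itemset <- function(...) {
  items <- list(...)
  if (length(items) == 1L && !inherits(items[[1L]], "item") && is.list(items[[1L]]))
    items <- items[[1L]]
  if (length(items)) {
    stopifnot(all(vapply(items, inherits, logical(1), "item")))
    feats <- vapply(items, `[[`, character(1), "feature")
    if (anyDuplicated(feats)) stop("itemset items must be on distinct features")
    items <- items[order(feats)]
  }
  structure(items, class = "itemset")
}

itemset_size <- function(s) length(unclass(s))

itemset_key <- function(s) {
  if (!itemset_size(s)) return("{}")
  paste(vapply(unclass(s), item_key, character(1)), collapse = " & ")
}

#' Render an itemset as text
#'
#' @param s an [itemset()].
#' @return a string such as `"{Sex = M, ST_Slope = Flat}"`; the empty
#'   itemset renders as the empty-set symbol.
#' @export
format_itemset <- function(s) {
  if (!itemset_size(s)) return("\u2205")
  paste0("{", paste(vapply(unclass(s), format_item, character(1)),
                    collapse = ", "), "}")
}

#' @export
print.itemset <- function(x, ...) {
  cat(format_itemset(x), "\n")
  invisible(x)
}

items_equal <- function(a, b) {
  if (a$feature != b$feature || a$type != b$type) return(FALSE)
  if (a$type == "eq") return(a$value == b$value)
  isTRUE(all.equal(c(a$lo, a$hi), c(b$lo, b$hi), tolerance = 1e-9))
}

#' Strict / non-strict subset order over itemsets
#'
#' @param a,b itemsets.
#' @return `itemset_subset` tests whether every item of `a` occurs in `b`;
#'   `itemset_strict_subset` additionally requires `b` to be larger.
#' @export
itemset_subset <- function(a, b) {
  all(vapply(unclass(a), function(ia) {
    any(vapply(unclass(b), items_equal, logical(1), a = ia))
  }, logical(1)))
}

#' @rdname itemset_subset
#' @export
itemset_strict_subset <- function(a, b) {
  itemset_size(a) < itemset_size(b) && itemset_subset(a, b)
}

check_itemset_schema <- function(s, schema) {
  for (it in unclass(s)) {
    if (!it$feature %in% names(schema$features))
      stop("item feature not in schema: ", it$feature)
    if (it$type == "interval" && schema$kinds[[it$feature]] != "numeric")
      stop("numeric item on non-numeric feature: ", it$feature)
  }
  invisible(TRUE)
}

item_mask <- function(table, it) {
  col <- table$data[[it$feature]]
  if (it$type == "eq") {
    out <- !is.na(col) & col == it$value
  } else {
    out <- !is.na(col) & col > it$lo & col <= it$hi
  }
  out
}

#' Evaluate itemset membership
#'
#' An instance matches an itemset iff every item's predicate holds on the
#' instance's value at that feature. A missing value at any item's feature
#' fails the match (fail-closed). Every instance matches the empty itemset.
#'
#' @param x an [item_table()] (vectorized over rows) or a single instance as
#'   a named list / one-row data frame.
#' @param s an [itemset()].
#' @param schema required when `x` is a bare instance.
#' @return logical vector (one element per row for a table).
#' @export
matches <- function(x, s, schema = NULL) {
  if (inherits(x, "item_table")) {
    check_itemset_schema(s, x$schema)
    if (!itemset_size(s)) return(rep(TRUE, n_rows(x)))
    Reduce(`&`, lapply(unclass(s), item_mask, table = x))
  } else {
    inst <- as.list(x)
    if (!is.null(schema)) check_itemset_schema(s, schema)
    if (!itemset_size(s)) return(TRUE)
    all(vapply(unclass(s), function(it) {
      v <- inst[[it$feature]]
      if (is.null(v) || is.na(v)) return(FALSE)
      if (it$type == "eq") as.character(v) == it$value
      else { v <- as.numeric(v); v > it$lo & v <= it$hi }
    }, logical(1)))
  }
}

#' Select the rows of a topic's subdataset
#'
#' Keeps the rows matching `topic` while discarding those matching any of
#' the `exclusions` (typically the topic's strict-superset topics, so that a
#' subset-topic tree is trained only on the rows its supersets do not
#' claim). The schema is unchanged; an empty result is permitted and signals
#' a degenerate topic.
#'
#' @param table an [item_table()].
#' @param topic an [itemset()].
#' @param exclusions list of itemsets.
#' @return an `item_table` with the retained rows.
#' @export
filter_by_topic <- function(table, topic, exclusions = list()) {
  check_itemset_schema(topic, table$schema)
  keep <- matches(table, topic)
  for (ex in exclusions) {
    check_itemset_schema(ex, table$schema)
    keep <- keep & !matches(table, ex)
  }
  subset_table(table, keep)
}
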