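# Items available for mining: every observed categorical value, plus one
# interval item per bin of each numeric feature that has cuts in the map.
mining_items <- function(table, map = NULL) {
  schema <- table$schema
  items <- list()
  for (nm in predictor_names(schema)) {
    if (schema$kinds[[nm]] == "categorical") {
      vals <- sort(unique(table$data[[nm]][!is.na(table$data[[nm]])]))
      for (v in vals) items[[length(items) + 1L]] <- item(nm, value = v)
    } else {
      if (is.null(map) || !nm %in% names(map$cuts))
        stop("numeric feature ", nm,
             " needs a discretization map before mining")
      if (nm %in% map$dropped) next
      cuts <- map$cuts[[nm]]
      edges <- c(-Inf, cuts, Inf)
      for (i in seq_len(length(edges) - 1L))
        items[[length(items) + 1L]] <- item(nm, lo = edges[i], hi = edges[i + 1L])
    }
  }
  items
}

#' Support and confidence of a class association rule
#'
#' For an antecedent itemset `A` and the rule `A => {class = positive}`:
#' support is the fraction of rows matching `A` and the positive class;
#' confidence is support divided by the fraction of rows matching `A`. The
#' empty antecedent therefore has support = confidence = the positive-class
#' prevalence. When no row matches the antecedent, confidence is undefined
#' and reported as 0 with `defined = FALSE`.
#'
#' @param antecedent an [itemset()].
#' @param table an [item_table()].
#' @return list with `support`, `confidence`, `defined`, `n_match`.
#' @export
support_confidence <- function(antecedent, table) {
  check_itemset_schema(antecedent, table$schema)
  m <- matches(table, antecedent)
  n <- n_rows(table)
  nm <- sum(m)
  s <- sum(m & positive_mask(table)) / n
  if (nm == 0L) list(support = 0, confidence = 0, defined = FALSE, n_match = 0L)
  else list(support = s, confidence = s * n / nm, defined = TRUE, n_match = nm)
}

new_car_set <- function(antecedents, support, confidence, defined, schema) {
  keys <- vapply(antecedents, itemset_key, character(1))
  labels <- vapply(antecedents, format_itemset, character(1))
  lens <- vapply(antecedents, itemset_size, integer(1))
  ord <- order(lens, keys)
  structure(
    list(antecedent = antecedents[ord],
         key = keys[ord], label = labels[ord], length = lens[ord],
         support = support[ord], confidence = confidence[ord],
         defined = defined[ord],
         positive_label = schema$positive_label),
    class = "car_set"
  )
}

#' @export
print.car_set <- function(x, ...) {
  cat("Class association rules:", length(x$antecedent), "rules, consequent {",
      x$positive_label, "}\n")
  n <- min(length(x$antecedent), 10L)
  for (i in seq_len(n))
    cat(sprintf("  %s  s=%.4f c=%.4f\n", x$label[i], x$support[i],
                x$confidence[i]))
  if (length(x$antecedent) > n) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.car_set <- function(x, ...) {
  data.frame(antecedent = x$label, length = x$length, support = x$support,
             confidence = x$confidence, defined = x$defined,
             stringsAsFactors = FALSE)
}

#' Mine all class association rules with the positive class as consequent
#'
#' Level-wise (Apriori) enumeration of antecedents over the observed item
#' alphabet, restricted to itemsets covering at least one row (coverage is
#' anti-monotone, so uncovered antecedents and all their supersets are
#' skipped). The empty antecedent (domain rule) is always included. Output
#' order is deterministic: by antecedent length, then lexicographically.
#'
#' @param table an [item_table()]. Numeric features require `map`.
#' @param map optional [mdlp_map()] supplying interval items for numeric
#'   features.
#' @param min_support,min_confidence thresholds in `[0, 1]`; the reference
#'   configuration mines at 0 / 0 and lets the rule tree select.
#' @param max_len maximum antecedent length.
#' @return a `car_set` object.
#' @export
mine_cars <- function(table, map = NULL, min_support = 0, min_confidence = 0,
                      max_len = 4L) {
  if (max_len < 0L) stop("max_len must be >= 0")
  items <- mining_items(table, map)
  n <- n_rows(table)
  pos <- positive_mask(table)
  pos[is.na(pos)] <- FALSE

  ants <- list(itemset())
  masks <- list(rep(TRUE, n))
  if (max_len >= 1L && length(items)) {
    item_masks <- lapply(items, item_mask, table = table)
    item_feats <- vapply(items, `[[`, character(1), "feature")
    # frontier of the level-wise search: (item index vector, row mask)
    frontier_idx <- lapply(seq_along(items), function(i) i)
    frontier_mask <- item_masks
    level <- 1L
    while (length(frontier_idx)) {
      keep <- vapply(frontier_mask, any, logical(1))
      frontier_idx <- frontier_idx[keep]
      frontier_mask <- frontier_mask[keep]
      ants <- c(ants, lapply(frontier_idx, function(ix) itemset(items[ix])))
      masks <- c(masks, frontier_mask)
      if (level >= max_len) break
      nxt_idx <- list(); nxt_mask <- list()
      for (j in seq_along(frontier_idx)) {
        ix <- frontier_idx[[j]]
        last <- ix[length(ix)]
        if (last >= length(items)) next
        for (i2 in (last + 1L):length(items)) {
          if (item_feats[i2] %in% item_feats[ix]) next
          m2 <- frontier_mask[[j]] & item_masks[[i2]]
          if (!any(m2)) next
          nxt_idx[[length(nxt_idx) + 1L]] <- c(ix, i2)
          nxt_mask[[length(nxt_mask) + 1L]] <- m2
        }
      }
      frontier_idx <- nxt_idx
      frontier_mask <- nxt_mask
      level <- level + 1L
    }
  }
  n_match <- vapply(masks, sum, numeric(1))
  supp <- vapply(masks, function(m) sum(m & pos), numeric(1)) / n
  conf <- ifelse(n_match > 0, supp * n / n_match, 0)
  defined <- n_match > 0
  keep <- supp >= min_support & conf >= min_confidence
  new_car_set(ants[keep], supp[keep], conf[keep], defined[keep], table$schema)
}

#' Export mined rules to CSV
#'
#' @param cars a `car_set` from [mine_cars()].
#' @param path output CSV path (columns antecedent, length, support,
#'   confidence).
#' @export
write_cars <- function(cars, path) {
  utils::write.csv(as.data.frame(cars), path, row.names = FALSE)
  invisible(path)
}
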