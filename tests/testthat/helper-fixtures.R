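# Shared fixtures: all built in code, no files.

# minimal binary-feature table: A, D in {1, 0}; class cls in {Y, N}
tiny_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(A = r[1], D = r[2], cls = r[3], stringsAsFactors = FALSE)))
  item_table(df, class_name = "cls", positive_label = "Y")
}

# the printed nine-rule fixture: domain rule plus eight antecedents with
# their support/confidence pairs
printed_rule_fixture <- function() {
  ants <- list(
    itemset(),
    itemset(item("Sex", value = "M")),
    itemset(item("Sex", value = "M"), item("ChestPainType", value = "ASY")),
    itemset(item("Sex", value = "M"), item("ExerciseAngina", value = "Y")),
    itemset(item("Sex", value = "M"), item("ST_Slope", value = "Flat")),
    itemset(item("ChestPainType", value = "ASY")),
    itemset(item("ExerciseAngina", value = "Y")),
    itemset(item("Oldpeak", lo = 0.85)),
    itemset(item("ST_Slope", value = "Flat")))
  car_set(ants,
          support    = c(0.55, 0.50, 0.38, 0.31, 0.37, 0.43, 0.34, 0.36, 0.42),
          confidence = c(0.55, 0.63, 0.83, 0.88, 0.89, 0.79, 0.85, 0.78, 0.83))
}

# random small categorical table for oracle comparisons
random_small_table <- function(seed, n_rows = 10L, n_feats = 3L) {
  set.seed(seed)
  cols <- lapply(seq_len(n_feats), function(i)
    sample(c("a", "b"), n_rows, replace = TRUE))
  names(cols) <- paste0("F", seq_len(n_feats))
  cols$cls <- sample(c("Y", "N"), n_rows, replace = TRUE)
  if (length(unique(cols$cls)) == 1L) cols$cls[1L] <- setdiff(c("Y", "N"), cols$cls[1L])
  item_table(as.data.frame(cols, stringsAsFactors = FALSE),
             class_name = "cls", positive_label = "Y")
}

# entropy in bits, written independently of the package internals
oracle_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# brute-force enumeration of every class association rule over the observed
# items of a small categorical table
oracle_mine <- function(table, max_len = 4L) {
  df <- table$data
  cls <- df[[table$schema$class_name]]
  pos <- cls == table$schema$positive_label
  preds <- setdiff(names(df), table$schema$class_name)
  items <- list()
  for (f in preds) for (v in sort(unique(df[[f]][!is.na(df[[f]])])))
    items[[length(items) + 1L]] <- list(feature = f, value = v)
  out <- list(list(key = "{}", s = mean(pos), c = mean(pos)))
  n <- nrow(df)
  if (length(items)) {
    idx_sets <- unlist(lapply(seq_len(min(max_len, length(items))), function(k)
      utils::combn(seq_along(items), k, simplify = FALSE)), recursive = FALSE)
    for (ix in idx_sets) {
      feats <- vapply(ix, function(i) items[[i]]$feature, character(1))
      if (anyDuplicated(feats)) next
      m <- rep(TRUE, n)
      for (i in ix) {
        col <- df[[items[[i]]$feature]]
        m <- m & !is.na(col) & col == items[[i]]$value
      }
      if (!any(m)) next
      key <- paste(sort(vapply(ix, function(i)
        paste0(items[[i]]$feature, "=", items[[i]]$value), character(1))),
        collapse = " & ")
      out[[length(out) + 1L]] <-
        list(key = key, s = sum(m & pos) / n, c = sum(m & pos) / sum(m))
    }
  }
  out
}
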