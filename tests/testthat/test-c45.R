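test_that("gain ratio matches hand entropy arithmetic", {
  # balanced binary feature perfectly predicting a balanced class
  df <- data.frame(f = c("a", "a", "b", "b"), cls = c("Y", "Y", "N", "N"),
                   stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  expect_equal(gain_ratio(tab, "f"), 1.0)
  # class-independent feature
  df2 <- data.frame(f = c("a", "b", "a", "b"), cls = c("Y", "Y", "N", "N"),
                    stringsAsFactors = FALSE)
  tab2 <- item_table(df2, class_name = "cls", positive_label = "Y")
  expect_equal(gain_ratio(tab2, "f"), 0)
  # 6-row table with a 2:1 informative split, checked by hand
  df3 <- data.frame(f = c("a", "a", "a", "a", "b", "b"),
                    cls = c("Y", "Y", "Y", "N", "N", "N"),
                    stringsAsFactors = FALSE)
  tab3 <- item_table(df3, class_name = "cls", positive_label = "Y")
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  gain <- h(0.5) - (4 / 6 * h(3 / 4) + 2 / 6 * h(0))
  si <- h(4 / 6)
  expect_equal(gain_ratio(tab3, "f"), gain / si)
  expect_error(gain_ratio(tab3, "nope"), "unknown")
})

test_that("degenerate inductions make single leaves", {
  sch <- feature_schema(list(f = c("a", "b"), cls = c("Y", "N")),
                        class_name = "cls", positive_label = "Y")
  pure <- item_table(data.frame(f = c("a", "b", "a"), cls = c("Y", "Y", "Y"),
                                stringsAsFactors = FALSE), schema = sch)
  t1 <- induce_tree(pure, min_num_obj = 1L)
  expect_equal(tree_stats(t1), list(n = 1L, m = 1L, depth = 0L))
  mixed <- item_table(data.frame(f = c("a", "a", "b", "b"),
                                 cls = c("Y", "Y", "N", "N"),
                                 stringsAsFactors = FALSE),
                      class_name = "cls", positive_label = "Y")
  t2 <- induce_tree(mixed, min_num_obj = 5L)   # minNumObj exceeds row count
  expect_equal(tree_stats(t2)$m, 1L)
  one_row <- item_table(data.frame(f = "a", cls = "Y",
                                   stringsAsFactors = FALSE), schema = sch)
  expect_error(induce_tree(one_row, min_num_obj = 1L), NA)
})

test_that("the root split matches a brute-force gain-ratio search", {
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  oracle_best <- function(df, min_num_obj) {
    cls <- df$cls
    base <- h(mean(cls == "Y"))
    best <- NULL; best_gr <- -Inf
    for (f in setdiff(names(df), "cls")) {
      col <- df[[f]]
      if (is.numeric(col)) {
        xs <- sort(unique(col))
        if (length(xs) < 2) next
        for (thr in (head(xs, -1) + tail(xs, -1)) / 2) {
          l <- cls[col <= thr]; r <- cls[col > thr]
          if (length(l) < min_num_obj || length(r) < min_num_obj) next
          wl <- length(l) / nrow(df)
          gain <- base - wl * h(mean(l == "Y")) - (1 - wl) * h(mean(r == "Y"))
          si <- h(wl)
          if (gain <= 1e-10 || si <= 0) next
          if (gain / si > best_gr + 1e-10) { best_gr <- gain / si; best <- f }
        }
      } else {
        sizes <- table(col)
        if (sum(sizes >= min_num_obj) < 2) next
        cond <- 0; si <- 0
        for (v in names(sizes)) {
          sel <- cls[col == v]
          w <- length(sel) / nrow(df)
          cond <- cond + w * h(mean(sel == "Y"))
          si <- si - w * log2(w)
        }
        gain <- base - cond
        if (gain <= 1e-10 || si <= 0) next
        if (gain / si > best_gr + 1e-10) { best_gr <- gain / si; best <- f }
      }
    }
    best
  }
  for (s in 1:6) {
    set.seed(s)
    df <- data.frame(u = sample(c("a", "b"), 8L, TRUE),
                     v = round(runif(8L, 0, 4), 1),
                     cls = sample(c("Y", "N"), 8L, TRUE),
                     stringsAsFactors = FALSE)
    if (length(unique(df$cls)) == 1L) df$cls[1] <- setdiff(c("Y", "N"), df$cls[1])
    tab <- item_table(df, class_name = "cls", positive_label = "Y")
    fit <- induce_tree(tab, min_num_obj = 2L, prune = FALSE)
    want <- oracle_best(df, 2L)
    if (is.null(want)) {
      expect_equal(fit$root$type, "leaf", info = paste("seed", s))
    } else {
      expect_equal(fit$root$feature, want, info = paste("seed", s))
    }
  }
})

test_that("prediction explains its path and routes missing values", {
  df <- data.frame(x = c(1, 2, 3, 10, 11, 12, 13),
                   g = c("a", "a", "a", "a", "b", "b", "b"),
                   cls = c("N", "N", "N", "Y", "Y", "Y", "Y"),
                   stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  fit <- induce_tree(tab, min_num_obj = 2L, prune = FALSE)
  expect_equal(fit$root$feature, "x")
  pr <- predict(fit, list(x = 11, g = "a"))
  expect_equal(pr$label, "Y")
  expect_true(length(pr$paths[[1]]) >= 1L)
  # missing split value descends to the largest branch (x > 6.5, 4 rows)
  pr_na <- predict(fit, list(x = NA, g = "a"))
  expect_equal(pr_na$label, "Y")
  # a single-leaf tree predicts with an empty path
  leaf <- induce_tree(tab, min_num_obj = 10L)
  pr_leaf <- predict(leaf, list(x = 1, g = "a"))
  expect_equal(length(pr_leaf$paths[[1]]), 0L)
  # vectorized routing agrees with the per-instance walk
  expect_equal(descforest:::predict_labels(fit, tab), predict(fit, tab)$label)
})

test_that("tree statistics count leaves, nodes and depth exactly", {
  leaf <- list(type = "leaf", label = "Y", n_pos = 1L, n_neg = 0L)
  t_leaf <- structure(list(root = leaf), class = "c45_tree")
  expect_equal(tree_stats(t_leaf), list(n = 1L, m = 1L, depth = 0L))
  three <- structure(list(root = list(
    type = "split", feature = "f", kind = "categorical",
    children = list(leaf, leaf, leaf))), class = "c45_tree")
  expect_equal(tree_stats(three), list(n = 3L, m = 4L, depth = 1L))
  nested <- structure(list(root = list(
    type = "split", feature = "f", kind = "numeric",
    children = list(leaf, list(type = "split", feature = "g",
                               kind = "numeric",
                               children = list(leaf, leaf))))),
    class = "c45_tree")
  expect_equal(tree_stats(nested), list(n = 3L, m = 5L, depth = 2L))
})

test_that("If-Then rendering follows the nested boundary format", {
  pure <- item_table(
    data.frame(f = "a", cls = "Yes", stringsAsFactors = FALSE),
    schema = feature_schema(list(f = "a", cls = c("Yes", "No")),
                            class_name = "cls", positive_label = "Yes"))
  leaf_tree <- induce_tree(pure, min_num_obj = 1L)
  expect_match(to_rules(leaf_tree), "\\{cls = Yes\\}$")
  df <- data.frame(x = c(1, 2, 9, 10), cls = c("No", "No", "Yes", "Yes"),
                   stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Yes")
  fit <- induce_tree(tab, min_num_obj = 2L, prune = FALSE)
  txt <- to_rules(fit)
  expect_match(txt, "if \\{x <= 5.5\\} then \\{cls = No\\}")
  expect_match(txt, "if \\{x > 5.5\\} then \\{cls = Yes\\}")
  bound <- to_rules(fit, boundary = itemset(item("Sex", value = "M")))
  expect_match(bound, "^If \\{Sex = M\\}, then consider \\{x\\}")
})

test_that("a perfectly separating feature yields full training accuracy", {
  set.seed(2)
  n <- 30L
  cls <- sample(c("Y", "N"), n, replace = TRUE)
  df <- data.frame(sep = ifelse(cls == "Y", "hi", "lo"),
                   noise = runif(n), cls = cls, stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  fit <- induce_tree(tab, min_num_obj = 2L)
  expect_equal(mean(predict(fit, tab)$label == cls), 1.0)
  # independent check against a recursive-partitioning reference
  if (requireNamespace("rpart", quietly = TRUE)) {
    rfit <- rpart::rpart(factor(cls) ~ sep + noise, data = df,
                         control = rpart::rpart.control(minbucket = 2, cp = 0.01))
    rpred <- as.character(predict(rfit, df, type = "class"))
    expect_equal(mean(rpred == cls), 1.0)
  }
})
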