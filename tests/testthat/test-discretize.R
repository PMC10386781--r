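test_that("MDLP reproduces the brute-force best entropy cut and MDL gate", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- c("N", "N", "N", "Y", "Y", "Y")
  # oracle: evaluate every midpoint, pick minimal weighted entropy, then
  # check the Fayyad-Irani acceptance inequality by hand
  mids <- (head(sort(v), -1) + tail(sort(v), -1)) / 2
  went <- vapply(mids, function(m) {
    l <- y[v <= m]; r <- y[v > m]
    length(l) / 6 * oracle_entropy(l) + length(r) / 6 * oracle_entropy(r)
  }, numeric(1))
  best <- mids[which.min(went)]
  gain <- oracle_entropy(y) - min(went)
  delta <- log2(3^2 - 2) - (2 * oracle_entropy(y) - 0 - 0)
  expect_true(gain > (log2(5) + delta) / 6)  # the cut must be accepted
  expect_equal(mdlp_cuts(v, y), best)
  expect_equal(best, 6.5)

  expect_equal(mdlp_cuts(v, rep("Y", 6)), numeric(0))     # zero gain
  expect_equal(mdlp_cuts(rep(4, 6), y), numeric(0))       # no boundaries
  expect_error(mdlp_cuts(c(NA, NA), c("Y", "N")), "missing")
})

test_that("MDLP is idempotent on the partitions it induces", {
  set.seed(11)
  v <- c(rnorm(30, 0), rnorm(30, 6))
  y <- rep(c("N", "Y"), each = 30)
  cuts <- mdlp_cuts(v, y)
  expect_true(length(cuts) >= 1L)
  edges <- c(-Inf, cuts, Inf)
  for (i in seq_len(length(edges) - 1L)) {
    sel <- v > edges[i] & v <= edges[i + 1L]
    expect_equal(mdlp_cuts(v[sel], y[sel]), numeric(0))
  }
})

test_that("apply_discretization bins values, drops flat features, expands binary mode", {
  df <- data.frame(Oldpeak = c(0.2, 1.5, 3.1), Flat = c(5, 5.1, 5.2),
                   Sex = c("M", "F", "M"), cls = c("N", "Y", "Y"),
                   stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  map <- structure(list(cuts = list(Oldpeak = c(0.85, 2.4), Flat = numeric(0)),
                        dropped = "Flat", binary_mode = FALSE),
                   class = "discretization_map")
  out <- apply_discretization(tab, map)
  expect_false("Flat" %in% names(out$data))
  expect_equal(out$data$Oldpeak[2], "(0.85-2.4]")
  expect_equal(out$data$Oldpeak[3], "(2.4-inf)")
  # a value outside the training range falls into the boundary bin
  tab2 <- tab; tab2$data$Oldpeak[1] <- -99
  expect_equal(apply_discretization(tab2, map)$data$Oldpeak[1], "(-inf-0.85]")
  # binary mode: one indicator feature per bin
  map$binary_mode <- TRUE
  out_b <- apply_discretization(tab, map)
  expect_setequal(setdiff(names(out_b$data), c("Sex", "cls")),
                  c("Oldpeak_1", "Oldpeak_2", "Oldpeak_3"))
  expect_equal(out_b$data$Oldpeak_2, c("no", "yes", "no"))
})

test_that("information-gain selection ranks a perfect predictor first", {
  set.seed(5)
  n <- 40L
  cls <- sample(c("Y", "N"), n, replace = TRUE)
  df <- data.frame(noise1 = sample(c("a", "b"), n, TRUE),
                   perfect = cls,
                   noise2 = sample(c("a", "b"), n, TRUE),
                   cls = cls, stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  expect_equal(rank_and_select(tab, 1L), "perfect")
  expect_setequal(rank_and_select(tab, 3L), c("noise1", "perfect", "noise2"))
  # two clones tie; the earlier schema column wins
  df2 <- df; df2$clone <- df2$perfect
  tab2 <- item_table(df2[c("perfect", "clone", "noise1", "cls")],
                     class_name = "cls", positive_label = "Y")
  expect_equal(rank_and_select(tab2, 2L), c("perfect", "clone"))
  # ranking is invariant to row order
  perm <- sample(n)
  tab3 <- item_table(df[perm, ], class_name = "cls", positive_label = "Y")
  expect_equal(rank_and_select(tab3, 3L), rank_and_select(tab, 3L))
  expect_error(rank_and_select(tab, 0L), "between")
})

test_that("mdlp_map flags cut-free features as dropped for mining", {
  set.seed(3)
  df <- data.frame(signal = c(rnorm(25, 0), rnorm(25, 8)),
                   noise = runif(50),
                   cls = rep(c("N", "Y"), each = 25), stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  map <- mdlp_map(tab)
  expect_true(length(map$cuts$signal) >= 1L)
  expect_true("noise" %in% map$dropped)
})
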