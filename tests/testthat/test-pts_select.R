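test_that("PTS applies the 2n - m formula and rejects bad counts", {
  expect_equal(pts(10, 18), 2L)
  expect_equal(pts(1, 1), 1L)
  expect_equal(pts(4, 7), 1L)
  expect_error(pts(5, 4), "n <= m")
})

test_that("least-PTS selection follows the full tie-break chain", {
  entries <- data.frame(min_num_obj = c(2L, 5L, 10L),
                        accuracy = c(0.9, 0.80, 0.85),
                        leaves = c(5L, 3L, 3L), size = c(8L, 5L, 5L),
                        pts = c(2L, 1L, 1L))
  expect_equal(select_least_pts(entries), 10L)   # least PTS, then accuracy
  entries2 <- data.frame(min_num_obj = c(3L, 7L),
                         accuracy = c(0.8, 0.8),
                         leaves = c(4L, 5L), size = c(7L, 9L),
                         pts = c(1L, 1L))
  expect_equal(select_least_pts(entries2), 3L)   # smaller size wins
  single <- entries2[1L, ]
  expect_equal(select_least_pts(single), 3L)
  # equal PTS, accuracy and size: the larger minNumObj wins
  entries3 <- data.frame(min_num_obj = c(3L, 7L), accuracy = c(0.8, 0.8),
                         leaves = c(4L, 4L), size = c(7L, 7L),
                         pts = c(1L, 1L))
  expect_equal(select_least_pts(entries3), 7L)
  # grid order never matters
  expect_equal(select_least_pts(entries[c(3, 1, 2), ]),
               select_least_pts(entries))
})

test_that("sweeps are deterministic and structurally sound", {
  set.seed(4)
  n <- 120L
  cls <- sample(c("Y", "N"), n, replace = TRUE)
  df <- data.frame(sep = ifelse(cls == "Y", "hi", "lo"),
                   noise = runif(n),
                   multi = sample(c("p", "q", "r"), n, TRUE),
                   cls = cls, stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  grid <- c(2L, 5L, 10L, 25L)
  s1 <- sweep_minnumobj(tab, grid = grid, folds = 5L, seed = 1L)
  s2 <- sweep_minnumobj(tab, grid = grid, folds = 5L, seed = 1L)
  expect_identical(s1$entries, s2$entries)
  expect_identical(s1$chosen, s2$chosen)
  # a perfect single split keeps PTS at 1 across the grid
  expect_true(all(s1$entries$pts >= 1L))
  expect_true(all(s1$entries$pts[s1$entries$min_num_obj <= 10L] == 1L))
  # a grid beyond the row count gives single-leaf stumps
  s3 <- sweep_minnumobj(tab, grid = n + 1L, folds = 5L, seed = 1L)
  expect_equal(s3$entries$size, 1L)
  expect_equal(s3$entries$pts, 1L)
  expect_error(sweep_minnumobj(tab, grid = integer(0)), "empty")
})

test_that("mean tree size does not grow with minNumObj on synthetic sweeps", {
  sizes <- matrix(0, nrow = 3L, ncol = 4L)
  grid <- c(2L, 6L, 15L, 40L)
  for (s in 1:3) {
    spec <- synthetic_spec(n_rows = 300L)
    tab <- generate_synthetic(spec, seed = s)$table
    sw <- sweep_minnumobj(tab, grid = grid, folds = 3L, seed = 1L)
    sizes[s, ] <- sw$entries$size
    expect_true(all(sw$entries$pts >= 1L))
  }
  avg <- colMeans(sizes)
  expect_true(all(diff(avg) <= 0))
})

test_that("folds shrink with a warning when a class is rare", {
  df <- data.frame(f = rep(c("a", "b"), 10L),
                   cls = c(rep("Y", 3L), rep("N", 17L)),
                   stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  expect_warning(sweep_minnumobj(tab, grid = 2L, folds = 10L, seed = 1L),
                 "folds reduced")
})

test_that("hill climbing lands in the least-PTS basin on a clean sweep", {
  set.seed(6)
  n <- 150L
  cls <- sample(c("Y", "N"), n, replace = TRUE)
  df <- data.frame(sep = ifelse(cls == "Y", "hi", "lo"),
                   multi = sample(c("p", "q", "r"), n, TRUE),
                   cls = cls, stringsAsFactors = FALSE)
  tab <- item_table(df, class_name = "cls", positive_label = "Y")
  cl <- climb_minnumobj(tab, grid = c(2L, 5L, 10L, 25L), folds = 3L, seed = 1L)
  expect_true(cl$chosen %in% c(2L, 5L, 10L, 25L))
  expect_true(min(cl$entries$pts) ==
                min(sweep_minnumobj(tab, grid = c(2L, 5L, 10L, 25L),
                                    folds = 3L, seed = 1L)$entries$pts))
})
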