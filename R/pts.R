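#' Prodigality for the tree structure (PTS)
#'
#' `PTS = 2n - m` for a tree with `n` leaves and `m` total nodes. Because
#' every internal node of a >= 2-ary tree has at least two children,
#' `m <= 2n - 1` and PTS is always >= 1; trees with prodigal (overgrown)
#' structure have high PTS, and the least PTS marks the most parsimonious
#' structure in a sweep.
#'
#' @param n leaf count.
#' @param m total node count (internal + leaves), `m >= n`.
#' @return integer PTS.
#' @examples
#' pts(10, 18) # 2
#' pts(4, 7)   # 1
#' @export
pts <- function(n, m) {
  if (any(n < 1L) || any(n > m)) stop("need 1 <= n <= m")
  as.integer(2L * n - m)
}

stratified_folds <- function(y, positive, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

cv_accuracy <- function(table, min_num_obj, prune, folds, seed) {
  y <- class_vector(table)
  n_pos <- sum(y == table$schema$positive_label)
  n_neg <- length(y) - n_pos
  k <- min(folds, max(2L, min(n_pos, n_neg)))
  if (k < folds)
    warning("folds reduced to ", k, " (class counts too small)")
  fold_id <- stratified_folds(y, table$schema$positive_label, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    test_i <- fold_id == f
    if (all(test_i) || !any(test_i)) next
    tr <- subset_table(table, !test_i)
    te <- subset_table(table, test_i)
    fit <- induce_tree(tr, min_num_obj = min_num_obj, prune = prune)
    pred <- predict_labels(fit, te)
    correct <- correct + sum(pred == class_vector(te))
  }
  correct / n_rows(table)
}

#' Default minimum-instances-per-leaf sweep grid
#'
#' @return the reference grid `2..15, 20, 25, 30, 35, 40`.
#' @export
default_grid <- function() c(2:15, 20L, 25L, 30L, 35L, 40L)

#' Sweep minNumObj and record PTS and cross-validated accuracy
#'
#' For each grid value the tree is induced on the full table (for the
#' structural statistics) and its accuracy estimated by stratified k-fold
#' cross-validation with a fixed seed, so the sweep is deterministic.
#'
#' @param table an [item_table()].
#' @param grid integer vector of minNumObj values.
#' @param folds cross-validation folds (reduced with a warning when a class
#'   has fewer rows than folds).
#' @param seed RNG seed for the fold assignment.
#' @param prune apply pessimistic pruning to every induced tree.
#' @return an object of class `sweep_result`: a data frame of entries
#'   (min_num_obj, accuracy, leaves, size, depth, pts) plus the chosen row.
#' @export
sweep_minnumobj <- function(table, grid = default_grid(), folds = 10L,
                            seed = 1L, prune = TRUE) {
  if (!length(grid)) stop("sweep grid is empty")
  grid <- as.integer(grid)
  entries <- lapply(grid, function(mno) {
    fit <- induce_tree(table, min_num_obj = mno, prune = prune)
    st <- tree_stats(fit)
    acc <- cv_accuracy(table, mno, prune, folds, seed)
    data.frame(min_num_obj = mno, accuracy = acc, leaves = st$n,
               size = st$m, depth = st$depth, pts = pts(st$n, st$m))
  })
  tab <- do.call(rbind, entries)
  res <- structure(list(entries = tab, folds = folds, seed = seed,
                        prune = prune), class = "sweep_result")
  res$chosen <- select_least_pts(res)
  res
}

#' Select the least-PTS entry of a sweep
#'
#' Minimum PTS; ties broken by maximum cross-validated accuracy, then by
#' smaller tree size, then by larger minNumObj (the coarser, more
#' parsimonious setting), giving a fully deterministic choice.
#'
#' @param result a `sweep_result` (or its `entries` data frame).
#' @return the chosen `min_num_obj` value.
#' @export
select_least_pts <- function(result) {
  tab <- if (inherits(result, "sweep_result")) result$entries else result
  if (!nrow(tab)) stop("empty sweep")
  ord <- order(tab$pts, -tab$accuracy, tab$size, -tab$min_num_obj)
  tab$min_num_obj[ord[1L]]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("minNumObj sweep (", nrow(x$entries), " values, ", x$folds,
      "-fold CV, seed ", x$seed, ")\n", sep = "")
  print(x$entries, row.names = FALSE)
  cat("chosen minNumObj:", x$chosen, "\n")
  invisible(x)
}

#' Export a sweep as CSV
#'
#' Columns mirror the reference report layout: minNumObj, accuracy, leaf
#' count, size, PTS.
#'
#' @param result a `sweep_result`.
#' @param path output CSV path.
#' @export
write_sweep <- function(result, path) {
  utils::write.csv(result$entries, path, row.names = FALSE)
  invisible(path)
}

#' Hill-climbing search for the least-PTS minNumObj
#'
#' Optional faster alternative to the exhaustive grid: starts at the grid's
#' smallest value and walks upward while PTS does not increase, then applies
#' the same tie-break chain on the visited entries. The exhaustive
#' [sweep_minnumobj()] is the reference behavior.
#'
#' @inheritParams sweep_minnumobj
#' @return a `sweep_result` over the visited grid points.
#' @export
climb_minnumobj <- function(table, grid = default_grid(), folds = 10L,
                            seed = 1L, prune = TRUE) {
  grid <- sort(as.integer(grid))
  visited <- list()
  best_pts <- Inf
  for (mno in grid) {
    fit <- induce_tree(table, min_num_obj = mno, prune = prune)
    st <- tree_stats(fit)
    p <- pts(st$n, st$m)
    acc <- cv_accuracy(table, mno, prune, folds, seed)
    visited[[length(visited) + 1L]] <-
      data.frame(min_num_obj = mno, accuracy = acc, leaves = st$n,
                 size = st$m, depth = st$depth, pts = p)
    if (p > best_pts) break        # climbed past the basin
    best_pts <- min(best_pts, p)
  }
  tab <- do.call(rbind, visited)
  res <- structure(list(entries = tab, folds = folds, seed = seed,
                        prune = prune), class = "sweep_result")
  res$chosen <- select_least_pts(res)
  res
}
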