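#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts; `not_predicted` counts rows
#'   outside a tree's boundary (never predicted by it).
#' @return an object of class `confusion`.
#' @export
confusion <- function(tp, tn, fp, fn, not_predicted = 0L) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn, not_predicted = not_predicted)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (not predicted: %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$not_predicted))
  m <- metrics(x)
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F %.4f\n",
              m$accuracy, m$precision, m$recall, m$f_measure))
  invisible(x)
}

#' Correctness and coverage metrics from confusion counts
#'
#' Accuracy (Correctness I), precision (Correctness II), recall (coverage)
#' and F-measure of a descriptive task. A ratio whose denominator is zero is
#' reported as 0 and flagged in `defined`.
#'
#' @param c a [confusion()] object (or list with tp/tn/fp/fn).
#' @return list with `accuracy`, `precision`, `recall`, `f_measure` and a
#'   logical `defined` vector naming the well-defined ratios.
#' @examples
#' metrics(confusion(tp = 12, tn = 3, fp = 2, fn = 0))
#' @export
metrics <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot < 1) stop("need at least one predicted row")
  acc <- (c$tp + c$tn) / tot
  prec_def <- (c$tp + c$fp) > 0
  rec_def <- (c$tp + c$fn) > 0
  prec <- if (prec_def) c$tp / (c$tp + c$fp) else 0
  rec <- if (rec_def) c$tp / (c$tp + c$fn) else 0
  f_def <- prec_def && rec_def && (prec + rec) > 0
  f <- if (f_def) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, precision = prec, recall = rec, f_measure = f,
       defined = c(accuracy = TRUE, precision = prec_def,
                   recall = rec_def, f_measure = f_def))
}

tally_confusion <- function(pred_pos, truth_pos, not_predicted = 0L) {
  confusion(tp = sum(pred_pos & truth_pos),
            tn = sum(!pred_pos & !truth_pos),
            fp = sum(pred_pos & !truth_pos),
            fn = sum(!pred_pos & truth_pos),
            not_predicted = as.integer(not_predicted))
}

#' Evaluate a topic tree on the rows of its boundary
#'
#' Rows matching the tree's boundary (its topic minus its exclusions) are
#' predicted and tallied; every other row is counted as `not_predicted`, so
#' `tp + tn + fp + fn + not_predicted` equals the table's row count.
#'
#' @param topic_tree a `topic_tree` from [build_forest()].
#' @param table an [item_table()] on the same schema.
#' @return a [confusion()].
#' @export
evaluate_tree <- function(topic_tree, table) {
  keep <- matches(table, topic_tree$topic)
  for (ex in topic_tree$exclusions) keep <- keep & !matches(table, ex)
  sub <- subset_table(table, keep)
  if (n_rows(sub) == 0L)
    return(confusion(0L, 0L, 0L, 0L, not_predicted = n_rows(table)))
  pred <- predict_labels(topic_tree$tree, sub)
  tally_confusion(pred == table$schema$positive_label,
                  positive_mask(sub),
                  not_predicted = n_rows(table) - n_rows(sub))
}

#' Evaluate a descriptive forest over a whole table
#'
#' Votes every row; the no-risk outcome counts as a negative prediction, so
#' the forest-level counts conserve the table's rows
#' (`tp + tn + fp + fn = nrow`). Also reports per-tree confusion counts and
#' the positive-class ratio of each topic's boundary subdataset (the
#' imbalance diagnostic).
#'
#' @param forest a `descriptive_forest`.
#' @param table an [item_table()] on the same schema.
#' @return list with `forest` (a [confusion()]), `per_tree` (named list of
#'   confusions), `class_ratios` (data frame: topic, rows, positives,
#'   ratio) and `votes` (the per-row [vote()] records).
#' @export
evaluate_forest <- function(forest, table) {
  n <- n_rows(table)
  k <- length(forest$trees)
  match_m <- vapply(forest$trees, function(tt)
    matches(table, tt$topic), logical(n))
  if (n == 1L) match_m <- matrix(match_m, nrow = 1L)
  # maximal-matched-topic rule: a subset topic never claims a row one of
  # its matched strict supersets claims
  applicable <- match_m
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && itemset_strict_subset(forest$trees[[i]]$topic,
                                        forest$trees[[j]]$topic))
      applicable[, i] <- applicable[, i] & !match_m[, j]
  }
  pred_m <- vapply(forest$trees, function(tt)
    predict_labels(tt$tree, table) == forest$schema$positive_label,
    logical(n))
  if (n == 1L) pred_m <- matrix(pred_m, nrow = 1L)
  yes <- rowSums(applicable & pred_m)
  napp <- rowSums(applicable)
  no <- napp - yes
  outcome <- ifelse(napp == 0L, "no_risk",
                    ifelse(yes > no, "positive", "negative"))
  tie <- napp > 0L & yes == no
  if (forest$config$tie_policy == "best_f_measure" && any(tie)) {
    f <- vapply(forest$trees, `[[`, numeric(1), "f_measure")
    for (r in which(tie)) {
      app <- which(applicable[r, ])
      best <- app[which.max(f[app])]
      outcome[r] <- if (pred_m[r, best]) "positive" else "negative"
    }
  }
  votes <- lapply(seq_len(n), function(r) {
    structure(list(id = r,
                   applicable = lapply(which(applicable[r, ]), function(i)
                     list(topic = forest$trees[[i]]$topic,
                          label = forest$trees[[i]]$label,
                          independent = forest$trees[[i]]$independent,
                          prediction = if (pred_m[r, i])
                            forest$schema$positive_label
                          else forest$schema$negative_label,
                          f_measure = forest$trees[[i]]$f_measure)),
                   yes_count = yes[r], no_count = no[r],
                   outcome = outcome[r], tie_flag = tie[r]),
              class = "vote_record")
  })
  pred_pos <- outcome == "positive"
  forest_conf <- tally_confusion(pred_pos, positive_mask(table),
                                 not_predicted = 0L)
  per_tree <- lapply(forest$trees, evaluate_tree, table = table)
  names(per_tree) <- vapply(forest$trees, function(tt)
    format_itemset(tt$topic), character(1))
  ratios <- do.call(rbind, lapply(forest$trees, function(tt) {
    m <- matches(table, tt$topic)
    data.frame(topic = format_itemset(tt$topic),
               rows = sum(m),
               positives = sum(m & positive_mask(table)),
               ratio = if (any(m)) sum(m & positive_mask(table)) / sum(m)
               else 0,
               stringsAsFactors = FALSE)
  }))
  list(forest = forest_conf, per_tree = per_tree, class_ratios = ratios,
       votes = votes)
}

#' Write an evaluation report
#'
#' One row per tree plus the forest row, mirroring the standard report
#' layout: TP, TN, FP, FN, Correctness I/II, coverage, F-measure, Not
#' predict.
#'
#' @param evaluation result of [evaluate_forest()].
#' @param path output CSV path (or JSON if it ends in `.json`).
#' @export
write_evaluation <- function(evaluation, path) {
  row_for <- function(name, cf) {
    m <- if (cf$tp + cf$tn + cf$fp + cf$fn > 0) metrics(cf)
    else list(accuracy = 0, precision = 0, recall = 0, f_measure = 0)
    data.frame(model = name, tp = cf$tp, tn = cf$tn, fp = cf$fp, fn = cf$fn,
               accuracy = round(m$accuracy, 4), precision = round(m$precision, 4),
               recall = round(m$recall, 4), f_measure = round(m$f_measure, 4),
               not_predicted = cf$not_predicted, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(
    lapply(names(evaluation$per_tree), function(nm)
      row_for(nm, evaluation$per_tree[[nm]])),
    list(row_for("descriptive forest", evaluation$forest))))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
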