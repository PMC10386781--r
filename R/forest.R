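#' Configuration for building a descriptive forest
#'
#' @param grid minNumObj sweep grid (see [default_grid()]).
#' @param folds cross-validation folds for the sweep.
#' @param seed RNG seed for fold assignment.
#' @param prune apply pessimistic pruning.
#' @param tie_policy `"negative"` (an equal vote is read as no risk, for
#'   precision) or `"best_f_measure"` (the applicable tree with the best
#'   F-measure decides).
#' @param exclusion_training train a subset topic's tree only on the rows
#'   its strict-superset topics do not claim (the reconstructed-subset-tree
#'   behavior); `FALSE` trains every tree on all rows matching its topic.
#' @param min_num_obj fix minNumObj for every tree and skip the sweep
#'   (mainly for small worked examples); `NULL` selects per tree by least
#'   PTS.
#' @param min_rows topics matching fewer rows are skipped with a warning.
#' @return a list of class `forest_config`.
#' @export
forest_config <- function(grid = default_grid(), folds = 10L, seed = 1L,
                          prune = TRUE,
                          tie_policy = c("negative", "best_f_measure"),
                          exclusion_training = TRUE, min_num_obj = NULL,
                          min_rows = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(min_rows)) min_rows <- 2L * folds
  structure(list(grid = grid, folds = folds, seed = seed, prune = prune,
                 tie_policy = tie_policy,
                 exclusion_training = exclusion_training,
                 min_num_obj = min_num_obj, min_rows = min_rows),
            class = "forest_config")
}

#' Build the descriptive forest from a topic set
#'
#' One boundary-bound decision tree per topic. A topic possessing strict
#' supersets within the topic set is dependent: its tree is trained with
#' those supersets as exclusions, so it only models the rows its supersets
#' do not claim. Each tree's minNumObj is selected by the least-PTS sweep on
#' its own subdataset, and its confusion counts and F-measure are computed
#' on its related instances.
#'
#' @param table an [item_table()].
#' @param topics a `topic_set` (from [extract_topics()] or [topic_set()]).
#' @param config a [forest_config()].
#' @return an object of class `descriptive_forest`.
#' @export
build_forest <- function(table, topics, config = forest_config()) {
  if (!length(topics$topics)) stop("topic set is empty")
  trees <- list()
  for (i in seq_along(topics$topics)) {
    tp <- topics$topics[[i]]
    exclusions <- if (config$exclusion_training)
      topics$topics[topics$supersets[[i]]] else list()
    sub <- filter_by_topic(table, tp, exclusions)
    if (n_rows(sub) < config$min_rows) {
      warning("topic ", format_itemset(tp), " matches only ", n_rows(sub),
              " rows after exclusions; tree skipped")
      next
    }
    if (!is.null(config$min_num_obj)) {
      mno <- config$min_num_obj
      sweep <- NULL
    } else {
      sweep <- sweep_minnumobj(sub, grid = config$grid, folds = config$folds,
                               seed = config$seed, prune = config$prune)
      mno <- sweep$chosen
    }
    fit <- induce_tree(sub, min_num_obj = mno, prune = config$prune)
    tt <- structure(
      list(topic = tp, label = topics$labels[i],
           independent = topics$independent[i],
           exclusions = exclusions,
           exclusion_labels = vapply(exclusions, format_itemset, character(1)),
           tree = fit, min_num_obj = mno, stats = tree_stats(fit),
           sweep = if (!is.null(sweep)) sweep$entries,
           n_training = n_rows(sub)),
      class = "topic_tree")
    cf <- evaluate_tree(tt, table)
    tt$confusion <- cf
    tt$f_measure <- if (cf$tp + cf$tn + cf$fp + cf$fn > 0)
      metrics(cf)$f_measure else 0
    trees[[length(trees) + 1L]] <- tt
  }
  if (!length(trees)) stop("no topic retained enough rows to build a tree")
  structure(list(trees = trees, schema = table$schema, config = config),
            class = "descriptive_forest")
}

#' @export
print.topic_tree <- function(x, ...) {
  cat("Topic tree ", x$label,
      if (x$independent) " [independent]" else " [dependent]",
      ": ", x$n_training, " training rows, minNumObj ", x$min_num_obj,
      ", ", x$stats$n, " leaves / ", x$stats$m, " nodes (PTS ",
      pts(x$stats$n, x$stats$m), "), F = ", sprintf("%.4f", x$f_measure),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.descriptive_forest <- function(x, ...) {
  cat("Descriptive forest:", length(x$trees), "topic trees\n")
  for (tt in x$trees) print(tt)
  invisible(x)
}

#' Trees applicable to an instance
#'
#' All trees whose topic the instance matches, excluding any tree whose
#' topic is a strict subset of another matched topic: only the maximal
#' matched topics survive, so a subset-topic tree speaks only for instances
#' none of its supersets claim.
#'
#' @param forest a `descriptive_forest`.
#' @param instance named list / one-row data frame.
#' @return list of `topic_tree`s (possibly empty).
#' @export
applicable_trees <- function(forest, instance) {
  inst <- as.list(instance)
  matched <- Filter(function(tt) matches(inst, tt$topic, forest$schema),
                    forest$trees)
  if (!length(matched)) return(list())
  keep <- vapply(seq_along(matched), function(i) {
    !any(vapply(seq_along(matched), function(j) {
      j != i && itemset_strict_subset(matched[[i]]$topic, matched[[j]]$topic)
    }, logical(1)))
  }, logical(1))
  matched[keep]
}

#' Vote the risk outcome for one instance
#'
#' Each applicable tree predicts; the outcome is positive iff the Yes votes
#' strictly outnumber the No votes. An equal vote is resolved by the
#' configured tie policy, and an instance matching no tree receives the
#' `no_risk` outcome (counted as negative in forest-level metrics).
#'
#' @param forest a `descriptive_forest`.
#' @param instance named list / one-row data frame.
#' @param id optional instance identifier carried into the record.
#' @return an object of class `vote_record`: applicable topics with their
#'   predictions and explanation paths, the Yes/No counts, the outcome
#'   (`"positive"`, `"negative"`, `"no_risk"`) and a tie flag.
#' @export
vote <- function(forest, instance, id = NULL) {
  inst <- as.list(instance)
  app <- applicable_trees(forest, inst)
  pos_label <- forest$schema$positive_label
  entries <- lapply(app, function(tt) {
    pr <- predict_one(tt$tree, inst)
    list(topic = tt$topic, label = tt$label, independent = tt$independent,
         prediction = pr$label, path = pr$conditions,
         f_measure = tt$f_measure)
  })
  yes <- sum(vapply(entries, function(e) e$prediction == pos_label, logical(1)))
  no <- length(entries) - yes
  tie <- length(entries) > 0L && yes == no
  outcome <- if (!length(entries)) "no_risk"
  else if (yes > no) "positive"
  else if (yes < no) "negative"
  else if (forest$config$tie_policy == "negative") "negative"
  else {
    best <- which.max(vapply(entries, `[[`, numeric(1), "f_measure"))
    if (entries[[best]]$prediction == pos_label) "positive" else "negative"
  }
  structure(list(id = id, applicable = entries, yes_count = yes,
                 no_count = no, outcome = outcome, tie_flag = tie),
            class = "vote_record")
}

#' @export
print.vote_record <- function(x, ...) {
  cat("Vote", if (!is.null(x$id)) paste0("(instance ", x$id, ")"), ":",
      x$yes_count, "Yes /", x$no_count, "No ->", x$outcome,
      if (x$tie_flag) "(tie)" else "", "\n")
  invisible(x)
}

#' Explain an instance through the forest
#'
#' Per applicable tree: the topic, its independent/dependent status and the
#' decision path rendered as feature conditions (with a dependent tree's
#' subset topic flagged as promoting co-factor), followed by the vote
#' summary. An instance matching no tree receives the fixed no-risk
#' statement.
#'
#' @param forest a `descriptive_forest`.
#' @param instance named list / one-row data frame.
#' @param id optional identifier.
#' @return character vector of report lines (class `forest_explanation`),
#'   with the `vote_record` attached as attribute `"vote"`.
#' @export
explain <- function(forest, instance, id = NULL) {
  v <- vote(forest, instance, id = id)
  hdr <- if (!is.null(id)) paste0("Instance ", id) else "Instance"
  if (v$outcome == "no_risk") {
    lines <- paste0(hdr, ": no risk from the main topics discovered from",
                    " the dataset.")
  } else {
    lines <- c(sprintf("%s: %d tree(s) vote Yes, %d vote No -> %s%s.",
                       hdr, v$yes_count, v$no_count,
                       if (v$outcome == "positive") "has risk" else "no risk",
                       if (v$tie_flag) paste0(" (tie, ",
                                              forest$config$tie_policy,
                                              " policy)") else ""))
    for (e in v$applicable) {
      status <- if (e$independent) "independent" else "dependent"
      lines <- c(lines, sprintf("  %s-tree [%s]: predicts %s", e$label,
                                status, e$prediction))
      if (!e$independent) {
        subs <- Filter(function(tt)
          itemset_strict_subset(tt$topic, e$topic), forest$trees)
        if (length(subs))
          lines <- c(lines, sprintf("    promoting co-factor topic: %s",
                                    paste(vapply(subs, `[[`, character(1),
                                                 "label"), collapse = ", ")))
      }
      if (length(e$path))
        lines <- c(lines, paste0("    risk path: ",
                                 paste(e$path, collapse = ", ")))
    }
  }
  structure(lines, class = "forest_explanation", vote = v)
}

#' @export
print.forest_explanation <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a forest to JSON
#'
#' @param forest a `descriptive_forest`.
#' @param path output file.
#' @export
write_forest <- function(forest, path) {
  trees <- lapply(forest$trees, function(tt) {
    list(topic = itemset_to_list(tt$topic), label = tt$label,
         independent = tt$independent,
         exclusions = lapply(tt$exclusions, itemset_to_list),
         min_num_obj = tt$min_num_obj, n_training = tt$n_training,
         stats = tt$stats, f_measure = tt$f_measure,
         confusion = unclass(tt$confusion),
         rules = to_rules(tt$tree, boundary = tt$topic,
                          exclusions = tt$exclusions),
         tree = tree_to_list(tt$tree$root))
  })
  jsonlite::write_json(
    list(tie_policy = forest$config$tie_policy,
         exclusion_training = forest$config$exclusion_training,
         trees = trees),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
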