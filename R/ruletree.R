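#' Assemble a rule set from antecedents and printed statistics
#'
#' Builds a `car_set` directly from known (support, confidence) pairs, e.g.
#' to replay a published rule table through [grow_rule_tree()] without
#' re-mining the data.
#'
#' @param antecedents list of [itemset()]s (include the empty domain
#'   antecedent).
#' @param support,confidence numeric vectors aligned with `antecedents`.
#' @param positive_label consequent class value (display only).
#' @return a `car_set`.
#' @export
car_set <- function(antecedents, support, confidence, positive_label = "Yes") {
  stopifnot(length(antecedents) == length(support),
            length(support) == length(confidence))
  schema <- list(positive_label = positive_label)
  new_car_set(antecedents, support, confidence,
              rep(TRUE, length(support)), schema)
}

#' Slope of interestingness between two rules
#'
#' The slope of the segment joining the parent and child rule points in
#' support x confidence space: `(c_child - c_parent) / (s_child -
#' s_parent)`. A child worth keeping trades a small support loss for a
#' confidence gain, making the slope strongly negative.
#'
#' @param parent,child lists (or `car_set` rows) with `support` and
#'   `confidence` elements.
#' @return the slope (a real number).
#' @examples
#' slope(list(support = 0.55, confidence = 0.55),
#'       list(support = 0.50, confidence = 0.63)) # -1.6
#' @export
slope <- function(parent, child) {
  ds <- child$support - parent$support
  if (ds == 0) stop("slope undefined: parent and child have equal support")
  (child$confidence - parent$confidence) / ds
}

#' Grow the association-rule tree from the domain rule
#'
#' Breadth-first growth in support x confidence space, starting at the
#' domain rule (empty antecedent). A candidate rule extends an existing
#' node's antecedent by exactly one item; it is accepted iff its confidence
#' strictly exceeds that parent's and the slope of interestingness is at
#' most `tau`. When several parents qualify, the candidate attaches to the
#' parent with the steepest (most negative) slope. Growth stops when no
#' candidate is accepted.
#'
#' @param cars a `car_set` including the empty-antecedent domain rule.
#' @param tau acceptance threshold; the default -1 keeps a rule only when
#'   its confidence gain at least offsets its support loss.
#' @return an object of class `rule_tree`: a flat node list with parent and
#'   children indices, each node carrying its rule and slope to parent.
#' @export
grow_rule_tree <- function(cars, tau = -1) {
  root_i <- which(cars$length == 0L)
  if (length(root_i) != 1L)
    stop("cars must contain exactly one empty-antecedent domain rule")
  nodes <- list(list(antecedent = cars$antecedent[[root_i]],
                     label = cars$label[root_i],
                     support = cars$support[root_i],
                     confidence = cars$confidence[root_i],
                     slope = NA_real_, parent = NA_integer_,
                     children = integer(0)))
  in_tree_keys <- cars$key[root_i]
  max_len <- max(cars$length)
  if (max_len >= 1L) for (len in seq_len(max_len)) {
    parents_at <- which(vapply(nodes, function(nd)
      itemset_size(nd$antecedent), integer(1)) == len - 1L)
    if (!length(parents_at)) break
    cand_i <- which(cars$length == len & !cars$key %in% in_tree_keys)
    for (ci in cand_i) {                       # already length+lex ordered
      cand_ant <- cars$antecedent[[ci]]
      best_parent <- NA_integer_; best_slope <- Inf
      for (pi in parents_at) {
        nd <- nodes[[pi]]
        if (!itemset_subset(nd$antecedent, cand_ant)) next
        if (cars$confidence[ci] <= nd$confidence) next
        if (cars$support[ci] == nd$support) next
        sl <- (cars$confidence[ci] - nd$confidence) /
          (cars$support[ci] - nd$support)
        if (sl <= tau && sl < best_slope) { best_slope <- sl; best_parent <- pi }
      }
      if (!is.na(best_parent)) {
        nodes[[length(nodes) + 1L]] <-
          list(antecedent = cand_ant, label = cars$label[ci],
               support = cars$support[ci], confidence = cars$confidence[ci],
               slope = best_slope, parent = best_parent,
               children = integer(0))
        nodes[[best_parent]]$children <-
          c(nodes[[best_parent]]$children, length(nodes))
        in_tree_keys <- c(in_tree_keys, cars$key[ci])
      }
    }
  }
  structure(list(nodes = nodes, tau = tau), class = "rule_tree")
}

#' @export
print.rule_tree <- function(x, ...) {
  cat("Association-rule tree:", length(x$nodes) - 1L,
      "accepted rules (tau =", x$tau, ")\n")
  rec <- function(i, depth) {
    nd <- x$nodes[[i]]
    sl <- if (is.na(nd$slope)) "" else sprintf("  slope=%.3f", nd$slope)
    cat(strrep("  ", depth), nd$label,
        sprintf("  (s=%.3f, c=%.3f)%s\n", nd$support, nd$confidence, sl),
        sep = "")
    for (ch in nd$children) rec(ch, depth + 1L)
  }
  rec(1L, 0L)
  invisible(x)
}

#' Extract the main topics and their dependency structure
#'
#' The topics are the antecedents of every non-root node of the grown rule
#' tree. Two relations are reported. The strict-subset partial order
#' (`supersets` / `subsets`) drives exclusion training and vote-time
#' applicability: a subset topic never claims an instance one of its
#' supersets claims. The independent/dependent labels follow the rule
#' tree's branches, the way the discovered subgroups are read off the
#' interestingness space: a topic is dependent when another topic sits on
#' its own root-to-leaf branch (its branch supersets extend it item by
#' item), and independent when its branch holds no other topic.
#'
#' @param tree a `rule_tree` from [grow_rule_tree()].
#' @return an object of class `topic_set`: `topics` (list of itemsets),
#'   `labels`, `independent` (logical), and `supersets` / `subsets` (per
#'   topic, indices of its strict supersets / subsets within the set).
#' @export
extract_topics <- function(tree) {
  nonroot <- tree$nodes[-1L]
  topics <- lapply(nonroot, `[[`, "antecedent")
  labels <- vapply(nonroot, `[[`, character(1), "label")
  k <- length(topics)
  supersets <- rep(list(integer(0)), max(k, 1L))[seq_len(k)]
  subsets <- rep(list(integer(0)), max(k, 1L))[seq_len(k)]
  if (k > 1L) for (i in seq_len(k)) {
    supersets[[i]] <- which(vapply(seq_len(k), function(j)
      j != i && itemset_strict_subset(topics[[i]], topics[[j]]), logical(1)))
    subsets[[i]] <- which(vapply(seq_len(k), function(j)
      j != i && itemset_strict_subset(topics[[j]], topics[[i]]), logical(1)))
  }
  has_parents <- all(vapply(nonroot, function(nd)
    !is.null(nd$parent), logical(1)))
  if (k && has_parents) {
    # branch relation: ancestors within the grown tree (root excluded)
    parent_of <- vapply(tree$nodes, function(nd)
      if (is.null(nd$parent) || is.na(nd$parent)) NA_integer_ else nd$parent,
      integer(1))
    node_idx <- seq_along(tree$nodes)[-1L]
    has_tree_ancestor <- vapply(node_idx, function(ni) {
      p <- parent_of[ni]
      !is.na(p) && p != 1L
    }, logical(1))
    has_tree_descendant <- vapply(node_idx, function(ni)
      length(tree$nodes[[ni]]$children) > 0L, logical(1))
    independent <- !(has_tree_ancestor | has_tree_descendant)
  } else {
    independent <- !vapply(seq_len(k), function(i)
      length(supersets[[i]]) > 0L || length(subsets[[i]]) > 0L, logical(1))
  }
  structure(list(topics = topics, labels = labels,
                 independent = independent,
                 supersets = supersets, subsets = subsets),
            class = "topic_set")
}

#' @export
print.topic_set <- function(x, ...) {
  cat("Topic set:", length(x$topics), "main topics\n")
  for (i in seq_along(x$topics))
    cat("  ", x$labels[i],
        if (x$independent[i]) "  [independent]" else "  [dependent]", "\n",
        sep = "")
  invisible(x)
}

#' Build a topic set directly from itemsets
#'
#' Convenience constructor for topic sets that do not come from a grown rule
#' tree (e.g. hand-specified boundary topics).
#'
#' @param topics list of non-empty [itemset()]s.
#' @return a `topic_set`.
#' @export
topic_set <- function(topics) {
  if (any(vapply(topics, itemset_size, integer(1)) == 0L))
    stop("the empty itemset cannot be a topic")
  keys <- vapply(topics, itemset_key, character(1))
  if (anyDuplicated(keys)) stop("topics must be pairwise distinct")
  fake_nodes <- c(list(list(antecedent = itemset())),
                  lapply(topics, function(tp)
                    list(antecedent = tp, label = format_itemset(tp))))
  extract_topics(structure(list(nodes = fake_nodes), class = "rule_tree"))
}

#' Export a rule tree as JSON or DOT
#'
#' @param tree a `rule_tree`.
#' @param path output file.
#' @param format `"json"` (nodes with support, confidence, slope, parent) or
#'   `"dot"` (Graphviz).
#' @export
write_rule_tree <- function(tree, path, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    nodes <- lapply(tree$nodes, function(nd) {
      list(label = nd$label, antecedent = itemset_to_list(nd$antecedent),
           support = nd$support, confidence = nd$confidence,
           slope = if (is.na(nd$slope)) NULL else nd$slope,
           parent = if (is.na(nd$parent)) NULL else nd$parent,
           children = as.list(nd$children))
    })
    jsonlite::write_json(list(tau = tree$tau, nodes = nodes), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lines <- c("digraph rule_tree {", "  node [shape=box];")
    for (i in seq_along(tree$nodes)) {
      nd <- tree$nodes[[i]]
      lines <- c(lines, sprintf(
        "  n%d [label=\"%s\\n(s=%.2f, c=%.2f)\"];", i,
        gsub("\"", "'", nd$label), nd$support, nd$confidence))
      if (!is.na(nd$parent))
        lines <- c(lines, sprintf("  n%d -> n%d [label=\"%.2f\"];",
                                  nd$parent, i, nd$slope))
    }
    writeLines(c(lines, "}"), path)
  }
  invisible(path)
}
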