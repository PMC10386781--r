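# C4.5-style decision-tree induction: multiway splits on categorical
# features (one child per schema value, each categorical feature tested at
# most once per path), binary splits on numeric features at midpoints
# between adjacent distinct values. Split selection maximizes the gain
# ratio; a split is admissible only if at least two branches receive
# >= min_num_obj rows. Rows with a missing split value descend to the
# largest branch. Optional pessimistic-error pruning (CF = 0.25).

# branch assignment for a candidate split; missing -> largest branch
branch_assignment <- function(col, kind, threshold = NULL, values = NULL) {
  if (kind == "numeric") {
    b <- ifelse(col <= threshold, 1L, 2L)
    k <- 2L
  } else {
    b <- match(col, values)
    k <- length(values)
  }
  miss <- is.na(b)
  if (any(miss)) {
    sizes <- tabulate(b[!miss], nbins = k)
    b[miss] <- which.max(sizes)
  }
  list(branch = b, k = k)
}

# x * log2(x) with the 0 log 0 = 0 convention, vectorized
xlog2 <- function(x) {
  out <- x * log2(x)
  out[x <= 0] <- 0
  out
}

split_measures <- function(branch, k, pos) {
  n <- length(branch)
  npos <- tabulate(branch[pos], nbins = k)
  ntot <- tabulate(branch, nbins = k)
  nneg <- ntot - npos
  # weighted conditional entropy via counts: sum_b (t log t - a log a - b log b)/n
  cond <- sum(xlog2(ntot) - xlog2(npos) - xlog2(nneg)) / n
  base <- entropy_counts(c(sum(pos), n - sum(pos)))
  si <- log2(n) - sum(xlog2(ntot)) / n
  list(gain = base - cond, split_info = si, sizes = ntot)
}

#' Gain ratio of a candidate split
#'
#' Information gain of the class under the candidate split, divided by the
#' split information of the branch-size distribution, both in bits. Rows
#' with a missing value on the split feature are routed to the largest
#' branch before the computation.
#'
#' @param table an [item_table()].
#' @param feature feature to split on.
#' @param threshold numeric threshold (needed for a numeric feature): the
#'   branches are `<= threshold` and `> threshold`.
#' @return the gain ratio (a real number).
#' @export
gain_ratio <- function(table, feature, threshold = NULL) {
  schema <- table$schema
  if (!feature %in% predictor_names(schema)) stop("unknown feature: ", feature)
  kind <- schema$kinds[[feature]]
  if (kind == "numeric" && is.null(threshold))
    stop("numeric split needs a threshold")
  ba <- branch_assignment(table$data[[feature]], kind, threshold,
                          schema$features[[feature]])
  if (length(unique(ba$branch)) < 2L)
    stop("candidate split produces fewer than two non-empty branches")
  sm <- split_measures(ba$branch, ba$k, positive_mask(table))
  sm$gain / sm$split_info
}

# best admissible split over all usable features; returns NULL if none.
# `data` is a named list of column vectors (faster than data.frame rows).
best_split <- function(data, pos, schema, usable, min_num_obj) {
  n <- length(pos)
  base <- entropy_counts(c(sum(pos), n - sum(pos)))
  best <- NULL
  best_gr <- -Inf
  for (f in usable) {
    kind <- schema$kinds[[f]]
    col <- data[[f]]
    if (kind == "categorical") {
      vals <- schema$features[[f]]
      ba <- branch_assignment(col, "categorical", values = vals)
      sm <- split_measures(ba$branch, ba$k, pos)
      if (sum(sm$sizes >= min_num_obj) < 2L) next
      if (sm$gain <= 1e-10 || sm$split_info <= 0) next
      gr <- sm$gain / sm$split_info
      if (gr > best_gr + 1e-10) {
        best_gr <- gr
        best <- list(feature = f, kind = "categorical", values = vals,
                     branch = ba$branch, k = ba$k, gain_ratio = gr)
      }
    } else {
      nm <- !is.na(col)
      x <- col[nm]; p <- pos[nm]
      if (length(x) < 2L) next
      ord <- order(x)
      xs <- x[ord]; ps <- p[ord]
      bidx <- which(diff(xs) > 0)
      if (!length(bidx)) next
      nmiss <- n - length(x)
      pmiss <- sum(pos) - sum(p)
      n_l <- bidx
      pos_l <- cumsum(ps)[bidx]
      n_r <- length(x) - n_l
      pos_r <- sum(ps) - pos_l
      left_big <- as.numeric(n_l >= n_r)
      nl <- n_l + nmiss * left_big
      pl <- pos_l + pmiss * left_big
      nr <- n_r + nmiss * (1 - left_big)
      pr <- pos_r + pmiss * (1 - left_big)
      ok <- nl >= min_num_obj & nr >= min_num_obj
      if (!any(ok)) next
      cond <- (xlog2(nl) - xlog2(pl) - xlog2(nl - pl) +
                 xlog2(nr) - xlog2(pr) - xlog2(nr - pr)) / n
      gain <- base - cond
      si <- log2(n) - (xlog2(nl) + xlog2(nr)) / n
      gr <- gain / si
      gr[!ok | gain <= 1e-10 | si <= 0] <- -Inf
      bi <- which.max(gr)
      if (gr[bi] > best_gr + 1e-10) {
        thr <- (xs[bidx[bi]] + xs[bidx[bi] + 1L]) / 2
        ba <- branch_assignment(col, "numeric", threshold = thr)
        best_gr <- gr[bi]
        best <- list(feature = f, kind = "numeric", threshold = thr,
                     branch = ba$branch, k = 2L, gain_ratio = gr[bi])
      }
    }
  }
  best
}

make_leaf <- function(npos, nneg, schema, parent_majority = NULL) {
  label <- if (npos > nneg) schema$positive_label
  else if (nneg > npos) schema$negative_label
  else if (npos > 0) schema$positive_label   # tie toward positive
  else if (!is.null(parent_majority)) parent_majority
  else schema$positive_label
  list(type = "leaf", label = label, n_pos = npos, n_neg = nneg)
}

grow_node <- function(data, pos, schema, usable, min_num_obj, depth_limit) {
  npos <- sum(pos); nneg <- length(pos) - npos
  if (npos == 0L || nneg == 0L || length(pos) < 2L * min_num_obj ||
      depth_limit <= 0L)
    return(make_leaf(npos, nneg, schema))
  sp <- best_split(data, pos, schema, usable, min_num_obj)
  if (is.null(sp)) return(make_leaf(npos, nneg, schema))
  child_usable <- if (sp$kind == "categorical") setdiff(usable, sp$feature)
  else usable
  majority <- make_leaf(npos, nneg, schema)$label
  children <- vector("list", sp$k)
  branch_n <- tabulate(sp$branch, nbins = sp$k)
  for (b in seq_len(sp$k)) {
    sel <- sp$branch == b
    if (!any(sel)) {
      children[[b]] <- make_leaf(0L, 0L, schema, parent_majority = majority)
    } else {
      children[[b]] <- grow_node(lapply(data, `[`, sel), pos[sel], schema,
                                 child_usable, min_num_obj, depth_limit - 1L)
    }
  }
  list(type = "split", feature = sp$feature, kind = sp$kind,
       threshold = sp$threshold, values = if (sp$kind == "categorical")
         sp$values, gain_ratio = sp$gain_ratio,
       n_pos = npos, n_neg = nneg, branch_n = branch_n,
       children = children)
}

# pessimistic-error estimate: upper binomial confidence limit on the error
# rate at confidence CF, times n
pessimistic_errors <- function(e, n, cf = 0.25) {
  if (n == 0) return(0)
  if (e >= n) return(n)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

subtree_error_estimate <- function(node, cf = 0.25) {
  if (node$type == "leaf") {
    e <- min(node$n_pos, node$n_neg)
    return(pessimistic_errors(e, node$n_pos + node$n_neg, cf))
  }
  sum(vapply(node$children, subtree_error_estimate, numeric(1), cf = cf))
}

prune_tree_nodes <- function(node, schema, cf = 0.25) {
  if (node$type == "leaf") return(node)
  node$children <- lapply(node$children, prune_tree_nodes, schema = schema,
                          cf = cf)
  subtree_est <- sum(vapply(node$children, subtree_error_estimate,
                            numeric(1), cf = cf))
  e_leaf <- min(node$n_pos, node$n_neg)
  leaf_est <- pessimistic_errors(e_leaf, node$n_pos + node$n_neg, cf)
  if (leaf_est <= subtree_est + 1e-9)
    return(make_leaf(node$n_pos, node$n_neg, schema))
  node
}

#' Induce a C4.5-style decision tree
#'
#' Greedy top-down growth choosing the admissible split with maximal gain
#' ratio; a split is admissible only if at least two branches receive at
#' least `min_num_obj` rows, otherwise a majority-class leaf is made (ties
#' toward the positive class). Numeric thresholds sit at midpoints between
#' adjacent distinct sorted values; gain-ratio ties break by schema feature
#' order, then smaller threshold. Pessimistic-error pruning (CF = 0.25) is
#' applied bottom-up by default.
#'
#' @param table an [item_table()] with a binary class.
#' @param min_num_obj minimum training instances per leaf.
#' @param prune apply pessimistic-error pruning.
#' @param cf pruning confidence factor.
#' @return an object of class `c45_tree`.
#' @export
induce_tree <- function(table, min_num_obj = 2L, prune = TRUE, cf = 0.25) {
  if (n_rows(table) == 0L) stop("cannot induce a tree from an empty table")
  schema <- table$schema
  usable <- predictor_names(schema)
  all_missing <- vapply(usable, function(f) all(is.na(table$data[[f]])),
                        logical(1))
  usable <- usable[!all_missing]
  pos <- positive_mask(table)
  pos[is.na(pos)] <- FALSE
  root <- grow_node(as.list(table$data), pos, schema, usable,
                    max(1L, as.integer(min_num_obj)), depth_limit = 60L)
  if (prune) root <- prune_tree_nodes(root, schema, cf)
  structure(list(root = root, schema = schema,
                 min_num_obj = as.integer(min_num_obj), pruned = prune),
            class = "c45_tree")
}

#' Structural statistics of a decision tree
#'
#' @param tree a `c45_tree`.
#' @return list with `n` (leaf count), `m` (all nodes) and `depth` (max
#'   edges root to leaf).
#' @export
tree_stats <- function(tree) {
  rec <- function(node) {
    if (node$type == "leaf") return(c(n = 1L, m = 1L, depth = 0L))
    ch <- vapply(node$children, rec, c(n = 0L, m = 0L, depth = 0L))
    c(n = sum(ch["n", ]), m = 1L + sum(ch["m", ]),
      depth = 1L + max(ch["depth", ]))
  }
  as.list(rec(tree$root))
}

#' @export
print.c45_tree <- function(x, ...) {
  st <- tree_stats(x)
  cat(sprintf("C4.5 tree: %d leaves, %d nodes, depth %d (minNumObj = %d%s)\n",
              st$n, st$m, st$depth, x$min_num_obj,
              if (x$pruned) ", pruned" else ""))
  rec <- function(node, prefix) {
    if (node$type == "leaf") {
      cat(prefix, "-> ", x$schema$class_name, " = ", node$label,
          sprintf(" (%d/%d)\n", node$n_pos, node$n_neg), sep = "")
      return(invisible())
    }
    for (b in seq_along(node$children)) {
      lab <- if (node$kind == "numeric") {
        if (b == 1L) paste0(node$feature, " <= ", format(node$threshold))
        else paste0(node$feature, " > ", format(node$threshold))
      } else paste0(node$feature, " = ", node$values[b])
      cat(prefix, lab, "\n", sep = "")
      rec(node$children[[b]], paste0(prefix, "  "))
    }
  }
  rec(x$root, "")
  invisible(x)
}

route_instance <- function(node, inst) {
  # returns branch index; missing or unseen value -> largest branch
  v <- inst[[node$feature]]
  b <- NA_integer_
  if (!is.null(v) && length(v) == 1L && !is.na(v)) {
    if (node$kind == "numeric") {
      b <- if (as.numeric(v) <= node$threshold) 1L else 2L
    } else {
      b <- match(as.character(v), node$values)
    }
  }
  if (is.na(b)) b <- which.max(node$branch_n)
  b
}

predict_one <- function(tree, inst) {
  node <- tree$root
  path <- list()
  while (node$type == "split") {
    b <- route_instance(node, inst)
    cond <- if (node$kind == "numeric") {
      if (b == 1L) paste0(node$feature, " <= ", format(node$threshold))
      else paste0(node$feature, " > ", format(node$threshold))
    } else paste0(node$feature, " = ", node$values[b])
    path[[length(path) + 1L]] <-
      list(feature = node$feature, condition = cond)
    node <- node$children[[b]]
  }
  list(label = node$label, path = path,
       conditions = vapply(path, `[[`, character(1), "condition"))
}

#' Predict with explanation paths
#'
#' Routes each instance from the root to a leaf; the sequence of tests taken
#' is returned as the explanation path. A missing (or unseen) value at a
#' split routes to the branch that received the most training rows.
#'
#' @param object a `c45_tree`.
#' @param newdata an [item_table()], data frame, or single named-list
#'   instance.
#' @param ... unused.
#' @return list with `label` (character vector) and `paths` (list of
#'   condition-string vectors).
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "item_table")) newdata$data
  else if (is.data.frame(newdata)) newdata
  else as.data.frame(newdata, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    predict_one(object, as.list(df[i, , drop = FALSE])))
  list(label = vapply(out, `[[`, character(1), "label"),
       paths = lapply(out, `[[`, "conditions"))
}

# vectorized whole-table routing; returns the leaf label per row
predict_labels <- function(tree, data) {
  if (inherits(data, "item_table")) data <- data$data
  data <- as.list(data)
  n <- length(data[[1L]])
  out <- character(n)
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$type == "leaf") { out[idx] <<- node$label; return(invisible()) }
    v <- data[[node$feature]][idx]
    if (node$kind == "numeric") {
      b <- rep(2L, length(idx)); b[!is.na(v) & v <= node$threshold] <- 1L
      b[is.na(v)] <- NA_integer_
    } else b <- match(v, node$values)
    b[is.na(b)] <- which.max(node$branch_n)
    for (k in seq_along(node$children)) rec(node$children[[k]], idx[b == k])
  }
  rec(tree$root, seq_len(n))
  out
}

rules_text_node <- function(node, schema) {
  if (node$type == "leaf")
    return(paste0("{", schema$class_name, " = ", node$label, "}"))
  parts <- character(0)
  for (b in seq_along(node$children)) {
    cond <- if (node$kind == "numeric") {
      if (b == 1L) paste0("{", node$feature, " <= ", format(node$threshold), "}")
      else paste0("{", node$feature, " > ", format(node$threshold), "}")
    } else paste0("{", node$feature, " = ", node$values[b], "}")
    child <- node$children[[b]]
    if (child$type == "leaf") {
      parts <- c(parts, paste0("if ", cond, " then ",
                               rules_text_node(child, schema)))
    } else {
      parts <- c(parts, paste0("if ", cond, " then consider {", child$feature,
                               "} (", rules_text_node(child, schema), ")"))
    }
  }
  paste(parts, collapse = ", ")
}

#' Render a tree as nested If--Then rules
#'
#' Produces the compact nested rule text, e.g. `"If {ChestPainType = ASY},
#' then consider {ST_Slope} (if {ST_Slope = Flat} then {Heart Disease =
#' Yes}, ...)"`. When a boundary topic is supplied it is prepended, since a
#' topic-bound tree only speaks for the rows matching its boundary.
#'
#' @param tree a `c45_tree`.
#' @param boundary optional [itemset()] (plus `exclusions`, itemsets whose
#'   rows the tree does not claim) prepended as the outer If.
#' @param exclusions list of itemsets excluded from the boundary.
#' @return a single string.
#' @export
to_rules <- function(tree, boundary = NULL, exclusions = list()) {
  schema <- tree$schema
  head_txt <- ""
  if (!is.null(boundary) && itemset_size(boundary) > 0L) {
    ex_txt <- if (length(exclusions)) {
      paste0(", not ", paste(vapply(exclusions, format_itemset, character(1)),
                             collapse = ", not "))
    } else ""
    head_txt <- paste0("If ", format_itemset(boundary), ex_txt, ", then ")
  }
  if (tree$root$type == "leaf")
    return(paste0(head_txt, if (nzchar(head_txt)) "" else "then ",
                  rules_text_node(tree$root, schema)))
  body <- paste0("consider {", tree$root$feature, "} (",
                 rules_text_node(tree$root, schema), ")")
  if (nzchar(head_txt)) paste0(head_txt, body) else paste0("If ", body)
}

tree_to_list <- function(node) {
  if (node$type == "leaf")
    return(list(type = "leaf", label = node$label,
                n_pos = node$n_pos, n_neg = node$n_neg))
  list(type = "split", feature = node$feature, kind = node$kind,
       threshold = node$threshold,
       values = if (!is.null(node$values)) as.list(node$values),
       n_pos = node$n_pos, n_neg = node$n_neg,
       branch_n = as.list(node$branch_n),
       children = lapply(node$children, tree_to_list))
}

#' Serialize a tree to JSON
#'
#' @param tree a `c45_tree`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(
    list(min_num_obj = tree$min_num_obj, pruned = tree$pruned,
         root = tree_to_list(tree$root)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
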