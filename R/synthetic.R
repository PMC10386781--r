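# Synthetic "integrated" datasets: a mixture of subpopulations whose rows
# carry planted main topics (categorical values or numeric-threshold
# events) that elevate the positive-class probability above a base rate.
# Feature values are drawn independently within a subpopulation, so the
# expected support and confidence of every planted antecedent have closed
# forms and topic recovery is testable end to end without external data.

normalize_feature_def <- function(def) {
  if (is.character(def)) {
    list(kind = "categorical", values = def,
         probs = rep(1 / length(def), length(def)))
  } else if (is.numeric(def) && length(def) == 2L) {
    list(kind = "numeric", range = sort(def))
  } else if (is.list(def) && !is.null(def$values)) {
    p <- if (is.null(def$probs)) rep(1 / length(def$values), length(def$values))
    else def$probs / sum(def$probs)
    list(kind = "categorical", values = def$values, probs = p)
  } else if (is.list(def) && !is.null(def$range)) {
    list(kind = "numeric", range = sort(def$range))
  } else stop("bad feature definition")
}

#' Specify a synthetic dataset with planted risk topics
#'
#' The default specification emulates a pooled ("integrated")
#' heart-disease-style dataset: a community-screening subpopulation mixed
#' with a clinic-referral subpopulation in which all risk markers are more
#' common (so the planted topics co-occur, as clinical risk factors do),
#' seven mixed-type features including a four-valued chest-pain code and
#' three numeric columns, prevalence near 0.45, and four planted topics —
#' three singletons (two categorical, one numeric-threshold) and one
#' two-item superset of `{Sex = M}` — so topic discovery exercises both
#' independent and dependent trees. At these defaults the closed-form
#' slopes of interestingness of the planted antecedents are all at most
#' -1.3, comfortably inside the acceptance threshold of -1.
#'
#' @param n_rows number of rows to draw.
#' @param features named list; a character vector declares a categorical
#'   feature (optionally `list(values=, probs=)`), a length-2 numeric or
#'   `list(range=)` a uniform numeric feature.
#' @param planted_topics list of `list(itemset, p)` pairs: when a row
#'   matches the itemset, its positive-class probability is at least `p`.
#'   The strongest (maximal `p`) matched topic wins; unmatched rows use
#'   `base_rate`.
#' @param base_rate positive probability for rows matching no topic.
#' @param subpopulations optional mixture: list of `list(weight, features)`
#'   where `features` overrides per-subpopulation distributions; weights are
#'   normalized.
#' @param class_name,positive_label,negative_label class column naming.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_rows = 2000L,
    features = list(
      Sex = list(values = c("M", "F"), probs = c(0.40, 0.60)),
      Smoking = list(values = c("Y", "N"), probs = c(0.22, 0.78)),
      Angina = list(values = c("Y", "N"), probs = c(0.15, 0.85)),
      ChestPain = list(values = c("ASY", "ATA", "NAP", "TA"),
                       probs = c(0.4, 0.25, 0.2, 0.15)),
      RestingBP = c(110, 172),
      Cholesterol = c(150, 300),
      Age = c(30, 80)),
    planted_topics = list(
      list(itemset = itemset(item("Sex", value = "M")), p = 0.35),
      list(itemset = itemset(item("Sex", value = "M"),
                             item("Smoking", value = "Y")), p = 0.93),
      list(itemset = itemset(item("RestingBP", lo = 170)), p = 0.88),
      list(itemset = itemset(item("Angina", value = "Y")), p = 0.68)),
    base_rate = 0.02,
    subpopulations = list(
      list(weight = 0.65, features = list()),
      list(weight = 0.35, features = list(
        Sex = list(values = c("M", "F"), probs = c(0.75, 0.25)),
        Smoking = list(values = c("Y", "N"), probs = c(0.5, 0.5)),
        Angina = list(values = c("Y", "N"), probs = c(0.65, 0.35)),
        RestingBP = c(130, 190)))),
    class_name = "Disease", positive_label = "Yes",
    negative_label = "No") {
  feats <- lapply(features, normalize_feature_def)
  for (pt in planted_topics) {
    if (pt$p < 0 || pt$p > 1) stop("topic probabilities must be in [0, 1]")
    for (it in unclass(pt$itemset)) {
      if (!it$feature %in% names(feats))
        stop("planted topic uses undeclared feature: ", it$feature)
      kind <- feats[[it$feature]]$kind
      if (it$type == "interval" && kind != "numeric")
        stop("interval topic item on categorical feature: ", it$feature)
      if (it$type == "eq" && kind != "categorical")
        stop("equality topic item on numeric feature: ", it$feature)
    }
  }
  if (base_rate < 0 || base_rate > 1) stop("base_rate must be in [0, 1]")
  if (is.null(subpopulations)) {
    subpopulations <- list(list(weight = 1, features = list()))
  }
  w <- vapply(subpopulations, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0) stop("bad subpopulation weights")
  for (g in seq_along(subpopulations)) {
    subpopulations[[g]]$weight <- w[g] / sum(w)
    subpopulations[[g]]$features <-
      lapply(subpopulations[[g]]$features, normalize_feature_def)
  }
  structure(list(n_rows = as.integer(n_rows), features = feats,
                 planted_topics = planted_topics, base_rate = base_rate,
                 subpopulations = subpopulations,
                 class_name = class_name, positive_label = positive_label,
                 negative_label = negative_label),
            class = "synthetic_spec")
}

sub_features <- function(spec, g) {
  utils::modifyList(spec$features, spec$subpopulations[[g]]$features)
}

# P(item) under one subpopulation's independent feature distributions
item_prob <- function(def, it) {
  if (it$type == "eq") {
    i <- match(it$value, def$values)
    if (is.na(i)) 0 else def$probs[i]
  } else {
    lo <- max(it$lo, def$range[1]); hi <- min(it$hi, def$range[2])
    max(0, hi - lo) / (def$range[2] - def$range[1])
  }
}

# merge the items of several itemsets per feature (predicate intersection),
# then multiply the per-feature probabilities (independence within subpop)
joint_prob <- function(feats, itemsets) {
  by_feat <- list()
  for (s in itemsets) for (it in unclass(s)) {
    f <- it$feature
    cur <- by_feat[[f]]
    if (is.null(cur)) by_feat[[f]] <- it
    else if (cur$type == "eq") {
      if (it$value != cur$value) return(0)
    } else {
      by_feat[[f]]$lo <- max(cur$lo, it$lo)
      by_feat[[f]]$hi <- min(cur$hi, it$hi)
      if (by_feat[[f]]$lo >= by_feat[[f]]$hi) return(0)
    }
  }
  prod(vapply(by_feat, function(it) item_prob(feats[[it$feature]], it),
              numeric(1)), 1)
}

# probability of each exact match pattern over the planted topics, and the
# class probability each pattern implies
pattern_table <- function(spec) {
  k <- length(spec$planted_topics)
  if (k == 0L)
    return(list(patterns = matrix(logical(0), nrow = 1L), prob = 1,
                p_class = spec$base_rate))
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  lifts <- vapply(spec$planted_topics, `[[`, numeric(1), "p")
  sets <- lapply(spec$planted_topics, `[[`, "itemset")
  prob <- numeric(nrow(pats))
  for (g in seq_along(spec$subpopulations)) {
    feats <- sub_features(spec, g)
    w <- spec$subpopulations[[g]]$weight
    at_least <- vapply(seq_len(nrow(pats)), function(r) {
      joint_prob(feats, sets[unlist(pats[r, ])])
    }, numeric(1))
    # exact = inclusion-exclusion over supersets of each pattern
    exact <- numeric(nrow(pats))
    for (r in seq_len(nrow(pats))) {
      a <- unlist(pats[r, ])
      sup <- which(vapply(seq_len(nrow(pats)), function(r2) {
        b <- unlist(pats[r2, ]); all(b[a])
      }, logical(1)))
      sgn <- vapply(sup, function(r2)
        (-1)^(sum(unlist(pats[r2, ])) - sum(a)), numeric(1))
      exact[r] <- sum(sgn * at_least[sup])
    }
    prob <- prob + w * exact
  }
  p_class <- vapply(seq_len(nrow(pats)), function(r) {
    a <- unlist(pats[r, ])
    if (any(a)) max(lifts[a]) else spec$base_rate
  }, numeric(1))
  list(patterns = as.matrix(pats), prob = prob, p_class = p_class)
}

#' Closed-form expected rule statistics of a synthetic spec
#'
#' Expected positive-class prevalence (the domain rule's support and
#' confidence) and, for each planted topic, the expected match probability,
#' support and confidence of its antecedent under the spec's mixture.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `prevalence` and a data frame `topics`.
#' @export
expected_rule_stats <- function(spec) {
  pt <- pattern_table(spec)
  prevalence <- sum(pt$prob * pt$p_class)
  k <- length(spec$planted_topics)
  rows <- lapply(seq_len(k), function(i) {
    sel <- pt$patterns[, i]
    match_prob <- sum(pt$prob[sel])
    support <- sum(pt$prob[sel] * pt$p_class[sel])
    data.frame(
      topic = format_itemset(spec$planted_topics[[i]]$itemset),
      match_prob = match_prob, support = support,
      confidence = if (match_prob > 0) support / match_prob else 0,
      stringsAsFactors = FALSE)
  })
  list(prevalence = prevalence, topics = do.call(rbind, rows))
}

#' Generate a synthetic item table with planted topics
#'
#' Rows are drawn from the spec's subpopulation mixture; each row's class is
#' Bernoulli with the probability of the strongest matched planted topic
#' (otherwise the base rate). Deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed.
#' @return list with `table` (an [item_table()]), `schema`, and
#'   `ground_truth` (planted topics plus [expected_rule_stats()]).
#' @export
generate_synthetic <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$n_rows
  w <- vapply(spec$subpopulations, `[[`, numeric(1), "weight")
  grp <- sample.int(length(w), n, replace = TRUE, prob = w)
  cols <- list()
  for (nm in names(spec$features)) cols[[nm]] <- rep(NA, n)
  for (g in seq_along(spec$subpopulations)) {
    sel <- grp == g
    if (!any(sel)) next
    feats <- sub_features(spec, g)
    for (nm in names(feats)) {
      def <- feats[[nm]]
      if (def$kind == "categorical") {
        cols[[nm]][sel] <- sample(def$values, sum(sel), replace = TRUE,
                                  prob = def$probs)
      } else {
        cols[[nm]][sel] <- stats::runif(sum(sel), def$range[1], def$range[2])
      }
    }
  }
  data <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  feats_schema <- lapply(spec$features, function(def) {
    if (def$kind == "numeric") "numeric" else sort(def$values)
  })
  feats_schema[[spec$class_name]] <- sort(c(spec$positive_label,
                                            spec$negative_label))
  schema <- feature_schema(feats_schema, spec$class_name, spec$positive_label)
  # class probability: strongest matched planted topic, else base rate
  p_row <- rep(spec$base_rate, n)
  tmp <- item_table(cbind(data, stats::setNames(
    data.frame(rep(spec$negative_label, n), stringsAsFactors = FALSE),
    spec$class_name)), schema = schema)
  lifts <- vapply(spec$planted_topics, `[[`, numeric(1), "p")
  for (i in order(lifts)) {                 # ascending, strongest wins last
    m <- matches(tmp, spec$planted_topics[[i]]$itemset)
    p_row[m] <- pmax(p_row[m], lifts[i])
  }
  cls <- ifelse(stats::runif(n) < p_row, spec$positive_label,
                spec$negative_label)
  data[[spec$class_name]] <- cls
  table <- item_table(data, schema = schema)
  list(table = table, schema = schema,
       ground_truth = list(planted_topics = spec$planted_topics,
                           expected = expected_rule_stats(spec)))
}

numeric_tolerances <- function(spec, tol_frac) {
  vapply(spec$features, function(def) {
    if (def$kind == "numeric") tol_frac * (def$range[2] - def$range[1])
    else NA_real_
  }, numeric(1))
}

# does an extracted topic reproduce a planted one? categorical items must
# match exactly; a numeric threshold may drift by tol (MDLP places the cut
# at a data midpoint near the planted boundary)
topic_recovers <- function(extracted, planted, tol) {
  ex <- unclass(extracted); pl <- unclass(planted)
  if (length(ex) != length(pl)) return(FALSE)
  all(vapply(pl, function(p) {
    any(vapply(ex, function(e) {
      if (e$feature != p$feature || e$type != p$type) return(FALSE)
      if (p$type == "eq") return(e$value == p$value)
      t <- tol[[p$feature]]
      lo_ok <- (is.infinite(p$lo) && is.infinite(e$lo)) ||
        (is.finite(p$lo) && is.finite(e$lo) && abs(e$lo - p$lo) <= t)
      hi_ok <- (is.infinite(p$hi) && is.infinite(e$hi)) ||
        (is.finite(p$hi) && is.finite(e$hi) && abs(e$hi - p$hi) <= t)
      lo_ok && hi_ok
    }, logical(1)))
  }, logical(1)))
}

#' Planted-topic recovery experiment
#'
#' For each seed: generate a dataset from the spec, run the full pipeline
#' (MDLP discretization, CAR mining, rule-tree topic discovery, forest
#' construction), check which planted topics reappear among the extracted
#' topics, and compare the forest's recall with a single least-PTS tree
#' trained on the whole dataset.
#'
#' @param spec a [synthetic_spec()].
#' @param seeds integer vector of generation seeds.
#' @param tau slope threshold passed to [grow_rule_tree()].
#' @param config [forest_config()] for the forest stage.
#' @param max_len antecedent cap for mining.
#' @param tol_frac numeric-threshold tolerance when matching a recovered
#'   topic, as a fraction of the feature's range.
#' @return an object of class `recovery_report`: per-seed data frame
#'   (`n_planted`, `n_recovered`, `all_recovered`, `n_topics`,
#'   `forest_recall`, `single_recall`) plus per-seed topic labels.
#' @export
recovery_experiment <- function(spec, seeds = 1:5, tau = -1,
                                config = forest_config(), max_len = 2L,
                                tol_frac = 0.15) {
  tol <- numeric_tolerances(spec, tol_frac)
  rows <- list(); topics_by_seed <- list()
  for (sd in seeds) {
    gen <- generate_synthetic(spec, seed = sd)
    table <- gen$table
    map <- mdlp_map(table)
    cars <- mine_cars(table, map = map, max_len = max_len)
    rt <- grow_rule_tree(cars, tau = tau)
    topics <- extract_topics(rt)
    planted <- lapply(spec$planted_topics, `[[`, "itemset")
    recovered <- vapply(planted, function(p)
      any(vapply(topics$topics, topic_recovers, logical(1),
                 planted = p, tol = tol)), logical(1))
    forest_recall <- NA_real_
    if (length(topics$topics)) {
      forest <- build_forest(table, topics, config)
      ev <- evaluate_forest(forest, table)
      forest_recall <- metrics(ev$forest)$recall
    }
    single_sweep <- sweep_minnumobj(table, grid = config$grid,
                                    folds = config$folds, seed = config$seed,
                                    prune = config$prune)
    single <- induce_tree(table, min_num_obj = single_sweep$chosen,
                          prune = config$prune)
    single_pred <- predict_labels(single, table)
    single_recall <- metrics(tally_confusion(
      single_pred == table$schema$positive_label,
      positive_mask(table)))$recall
    rows[[length(rows) + 1L]] <- data.frame(
      seed = sd, n_planted = length(planted),
      n_recovered = sum(recovered), all_recovered = all(recovered),
      n_topics = length(topics$topics),
      forest_recall = forest_recall, single_recall = single_recall)
    topics_by_seed[[as.character(sd)]] <- topics$labels
  }
  structure(list(results = do.call(rbind, rows),
                 topics_by_seed = topics_by_seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Planted-topic recovery across", nrow(x$results), "seeds\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' A small worked descriptive-forest example
#'
#' Builds, from a deterministic 36-row table over binary features A--E and a
#' co-feature W, the five-topic forest ({A}, {B}, {C}, {C,D}, {C,E}) whose
#' voting behavior illustrates the dependent-tree exclusion rule: the
#' {C}-tree is trained and used only where neither {C,D} nor {C,E} applies.
#' Three probe instances are included; their votes land at 2, 2 and 1 Yes.
#'
#' @param tie_policy forwarded to [forest_config()].
#' @return list with `table`, `forest`, `instances` (3-row data frame,
#'   instances "001", "002", "N") and `votes` (list of [vote()] records).
#' @export
toy_forest_example <- function(tie_policy = "negative") {
  k <- 6L
  block <- function(A, B, C, D, E, W, cls)
    data.frame(A = A, B = B, C = C, D = D, E = E, W = W, cls = cls,
               stringsAsFactors = FALSE)[rep(1L, k), ]
  data <- rbind(
    block("Y", "N", "N", "N", "N", "lo", "Yes"),   # {A} rows: all risk
    block("N", "Y", "N", "N", "N", "lo", "No"),    # {B} rows split on W
    block("N", "Y", "N", "N", "N", "hi", "Yes"),
    block("N", "N", "Y", "N", "N", "lo", "Yes"),   # {C} alone: risk
    block("N", "N", "Y", "Y", "N", "lo", "Yes"),   # {C,D}: risk
    block("N", "N", "Y", "N", "Y", "lo", "No"))    # {C,E}: no risk
  rownames(data) <- NULL
  table <- item_table(data, class_name = "cls", positive_label = "Yes")
  topics <- topic_set(list(
    itemset(item("A", value = "Y")),
    itemset(item("B", value = "Y")),
    itemset(item("C", value = "Y")),
    itemset(item("C", value = "Y"), item("D", value = "Y")),
    itemset(item("C", value = "Y"), item("E", value = "Y"))))
  forest <- build_forest(table, topics,
                         forest_config(min_num_obj = 3L, min_rows = 1L,
                                       tie_policy = tie_policy))
  instances <- data.frame(
    A = c("Y", "Y", "N"), B = c("N", "Y", "Y"), C = c("Y", "Y", "Y"),
    D = c("Y", "N", "N"), E = c("Y", "N", "Y"), W = c("lo", "lo", "hi"),
    row.names = c("001", "002", "N"), stringsAsFactors = FALSE)
  votes <- lapply(rownames(instances), function(id)
    vote(forest, as.list(instances[id, , drop = FALSE]), id = id))
  names(votes) <- rownames(instances)
  list(table = table, forest = forest, instances = instances, votes = votes)
}
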