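test_that("the worked example reproduces the dependent-tree voting walkthrough", {
  toy <- toy_forest_example()
  # the {C}-tree is trained only on rows claimed by neither superset
  ctree <- Filter(function(tt) tt$label == "{C = Y}", toy$forest$trees)[[1]]
  expect_equal(ctree$n_training, 6L)
  expect_equal(length(ctree$exclusions), 2L)

  app_labels <- function(id) sort(vapply(
    applicable_trees(toy$forest, as.list(toy$instances[id, ])),
    `[[`, character(1), "label"))
  expect_equal(app_labels("001"),
               sort(c("{A = Y}", "{C = Y, D = Y}", "{C = Y, E = Y}")))
  expect_equal(app_labels("002"), sort(c("{A = Y}", "{B = Y}", "{C = Y}")))
  expect_equal(app_labels("N"), sort(c("{B = Y}", "{C = Y, E = Y}")))

  expect_equal(vapply(toy$votes, `[[`, numeric(1), "yes_count"),
               c("001" = 2, "002" = 2, "N" = 1))
  expect_equal(vapply(toy$votes, `[[`, character(1), "outcome"),
               c("001" = "positive", "002" = "positive", "N" = "negative"))
  expect_true(toy$votes$N$tie_flag)
})

test_that("the best-F-measure tie policy can flip a tied vote", {
  toy <- toy_forest_example(tie_policy = "best_f_measure")
  # instance N ties 1-1; the perfectly fitting {B}-tree outranks the
  # {C,E}-tree (whose boundary has no positives, so its F is 0)
  expect_equal(toy$votes$N$outcome, "positive")
})

test_that("degenerate topics are skipped and lone topics dominate", {
  toy <- toy_forest_example()
  tab <- toy$table
  ghost <- topic_set(list(itemset(item("A", value = "Y")),
                          itemset(item("A", value = "Y"),
                                  item("B", value = "Y"))))
  expect_warning(
    f <- build_forest(tab, ghost, forest_config(min_num_obj = 3L,
                                                min_rows = 1L)),
    "matches only 0 rows")
  expect_equal(length(f$trees), 1L)
  # a single-topic forest equals its tree on matched rows, no_risk elsewhere
  solo <- build_forest(tab, topic_set(list(itemset(item("A", value = "Y")))),
                       forest_config(min_num_obj = 3L, min_rows = 1L))
  v_in <- vote(solo, list(A = "Y", B = "N", C = "N", D = "N", E = "N", W = "lo"))
  expect_equal(v_in$outcome, "positive")
  v_out <- vote(solo, list(A = "N", B = "N", C = "N", D = "N", E = "N", W = "lo"))
  expect_equal(v_out$outcome, "no_risk")
  expect_error(build_forest(tab, structure(list(topics = list()),
                                           class = "topic_set")), "empty")
})

test_that("explanations cite paths, co-factors and the fixed no-risk sentence", {
  toy <- toy_forest_example()
  ex1 <- explain(toy$forest, as.list(toy$instances["002", ]), id = "002")
  txt <- paste(unclass(ex1), collapse = "\n")
  expect_match(txt, "\\{A = Y\\}-tree")
  expect_match(txt, "risk path: W = lo")          # the {B}-tree's test
  ex_none <- explain(toy$forest,
                     list(A = "N", B = "N", C = "N", D = "N", E = "N",
                          W = "lo"))
  expect_match(unclass(ex_none)[1], "no risk from the main topics")
  # a dependent tree names its subset topic as promoting co-factor
  ex_dep <- explain(toy$forest, as.list(toy$instances["001", ]))
  expect_match(paste(unclass(ex_dep), collapse = "\n"),
               "promoting co-factor topic: \\{C = Y\\}")
})

test_that("no instance is claimed by both a topic and its strict superset", {
  spec <- synthetic_spec(n_rows = 400L)
  gen <- generate_synthetic(spec, seed = 2L)
  topics <- topic_set(lapply(spec$planted_topics, `[[`, "itemset"))
  forest <- build_forest(gen$table, topics,
                         forest_config(grid = c(2L, 10L, 25L), folds = 3L))
  ev <- evaluate_forest(forest, gen$table)
  for (v in ev$votes) {
    tps <- lapply(v$applicable, `[[`, "topic")
    if (length(tps) > 1L) {
      for (i in seq_along(tps)) for (j in seq_along(tps)) {
        if (i != j) expect_false(itemset_strict_subset(tps[[i]], tps[[j]]))
      }
    }
    # total coverage: an explanation or the no-risk outcome
    expect_true(length(v$applicable) > 0L || v$outcome == "no_risk")
  }
  # determinism: rebuilding with the same seed gives identical votes
  forest2 <- build_forest(gen$table, topics,
                          forest_config(grid = c(2L, 10L, 25L), folds = 3L))
  ev2 <- evaluate_forest(forest2, gen$table)
  expect_identical(vapply(ev$votes, `[[`, character(1), "outcome"),
                   vapply(ev2$votes, `[[`, character(1), "outcome"))
})
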