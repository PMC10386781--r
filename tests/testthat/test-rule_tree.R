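test_that("slope is the segment slope in support x confidence space", {
  expect_equal(slope(list(support = 0.55, confidence = 0.55),
                     list(support = 0.50, confidence = 0.63)), -1.6)
  expect_equal(slope(list(support = 0.43, confidence = 0.79),
                     list(support = 0.38, confidence = 0.83)), -0.8)
  expect_error(slope(list(support = 0.4, confidence = 0.5),
                     list(support = 0.4, confidence = 0.9)), "equal support")
})

test_that("the printed nine-rule fixture grows the published topology", {
  rt <- grow_rule_tree(printed_rule_fixture(), tau = -1)
  labels <- vapply(rt$nodes, `[[`, character(1), "label")
  root_children <- sort(labels[rt$nodes[[1]]$children])
  expect_equal(root_children,
               sort(c("{ChestPainType = ASY}", "{ExerciseAngina = Y}",
                      "{Oldpeak > 0.85}", "{ST_Slope = Flat}", "{Sex = M}")))
  sexm <- which(labels == "{Sex = M}")
  expect_equal(sort(labels[rt$nodes[[sexm]]$children]),
               sort(c("{ChestPainType = ASY, Sex = M}",
                      "{ExerciseAngina = Y, Sex = M}",
                      "{ST_Slope = Flat, Sex = M}")))
  expect_equal(length(rt$nodes), 9L)
  # hand-checked slopes: the root -> {Sex = M} edge, and the rejected
  # {ChestPainType = ASY} -> {Sex = M, ChestPainType = ASY} attachment
  expect_equal(rt$nodes[[sexm]]$slope, -1.6)
  masy <- which(labels == "{ChestPainType = ASY, Sex = M}")
  expect_equal(rt$nodes[[masy]]$parent, sexm)
  expect_equal(rt$nodes[[masy]]$slope, (0.83 - 0.63) / (0.38 - 0.50))
})

test_that("a boundary slope of exactly tau is accepted", {
  cars <- car_set(list(itemset(),
                       itemset(item("ExerciseAngina", value = "Y")),
                       itemset(item("Sex", value = "M"),
                               item("ExerciseAngina", value = "Y"))),
                  support = c(0.55, 0.34, 0.31),
                  confidence = c(0.55, 0.85, 0.88))
  rt <- grow_rule_tree(cars, tau = -1)
  # (0.88 - 0.85) / (0.31 - 0.34) = -1 exactly: boundary inclusive
  expect_equal(length(rt$nodes), 3L)
  expect_equal(rt$nodes[[3]]$slope, -1)
})

test_that("growth stops when no extension raises confidence", {
  cars <- car_set(list(itemset(), itemset(item("A", value = "1"))),
                  support = c(0.5, 0.4), confidence = c(0.5, 0.45))
  rt <- grow_rule_tree(cars)
  expect_equal(length(rt$nodes), 1L)
  expect_error(grow_rule_tree(car_set(list(itemset(item("A", value = "1"))),
                                      0.4, 0.6)), "domain rule")
})

test_that("rule-tree paths trade support for confidence at every edge", {
  rt <- grow_rule_tree(printed_rule_fixture(), tau = -1)
  for (i in seq_along(rt$nodes)[-1]) {
    nd <- rt$nodes[[i]]
    parent <- rt$nodes[[nd$parent]]
    expect_true(nd$support < parent$support)
    expect_true(nd$confidence > parent$confidence)
    expect_true(nd$slope <= -1)
  }
})

test_that("extract_topics separates independent and dependent topics", {
  tp <- extract_topics(grow_rule_tree(printed_rule_fixture()))
  expect_equal(length(tp$topics), 8L)
  ind <- sort(tp$labels[tp$independent])
  expect_equal(ind, sort(c("{ChestPainType = ASY}", "{ExerciseAngina = Y}",
                           "{Oldpeak > 0.85}", "{ST_Slope = Flat}")))
  dep <- sort(tp$labels[!tp$independent])
  expect_equal(dep, sort(c("{Sex = M}", "{ChestPainType = ASY, Sex = M}",
                           "{ExerciseAngina = Y, Sex = M}",
                           "{ST_Slope = Flat, Sex = M}")))
  # no topic is ever the empty itemset
  expect_true(all(vapply(tp$topics, itemset_size, integer(1)) > 0L))
  # exclusion-relevant supersets follow the subset order
  sexm <- which(tp$labels == "{Sex = M}")
  expect_equal(length(tp$supersets[[sexm]]), 3L)
})

test_that("hand-built topic sets fall back to the subset order", {
  tp <- topic_set(list(
    itemset(item("A", value = "1")), itemset(item("B", value = "1")),
    itemset(item("C", value = "1")),
    itemset(item("C", value = "1"), item("D", value = "1")),
    itemset(item("C", value = "1"), item("E", value = "1"))))
  expect_equal(tp$independent,
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  cidx <- which(tp$labels == "{C = 1}")
  expect_equal(length(tp$supersets[[cidx]]), 2L)
  # a lone topic is independent
  solo <- topic_set(list(itemset(item("A", value = "1"))))
  expect_true(solo$independent)
})
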