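# Nested edit distance, padded bijective matching, failure-mode
# attribution, lenient equivalence and report aggregation.

test_that("node_distance counts missing, extra and unequal leaves", {
  a <- make_compound("THF", volume = 10, role = "SOLVENT")
  expect_equal(node_distance(a, a), 0)
  expect_equal(node_distance(a, NULL), 5)
  expect_equal(node_distance(NULL, NULL), 0)

  # one altered value plus one leaf present on only one side
  gt <- make_compound("NaH", mass = 5)
  gt$reaction_role <- NULL
  pred <- make_compound("NaH", mass = 7, role = "REACTANT")
  expect_equal(node_distance(gt, pred), 2)
})

test_that("scalar comparison parses numbers and trims strings", {
  expect_equal(node_distance(list(v = 5L), list(v = 5.0)), 0)
  expect_equal(node_distance(list(v = "5"), list(v = 5)), 0)
  expect_equal(node_distance(list(v = " GRAM "), list(v = "GRAM")), 0)
  expect_equal(node_distance(list(v = "GRAM"), list(v = "gram")), 1)
})

test_that("repeated sub-lists are aligned so order never costs anything", {
  a <- list(identifiers = list(
    list(type = "NAME", value = "x"), list(type = "SMILES", value = "C")
  ))
  b <- list(identifiers = list(
    list(type = "SMILES", value = "C"), list(type = "NAME", value = "x")
  ))
  expect_equal(node_distance(a, b), 0)
})

test_that("node_distance is a symmetric premetric on generated compounds", {
  corpus <- gen_corpus(gen_config(n_reactions = 6, seed = 5,
                                  compounds_range = c(2, 4)))
  comps <- unlist(lapply(corpus$record, ordbench:::input_compounds),
                  recursive = FALSE)
  set.seed(1)
  for (rep in 1:40) {
    ijk <- sample(length(comps), 3, replace = TRUE)
    a <- comps[[ijk[1]]]; b <- comps[[ijk[2]]]; c <- comps[[ijk[3]]]
    dab <- node_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, node_distance(b, a))
    expect_equal(node_distance(a, a), 0)
    expect_lte(dab, node_distance(a, c) + node_distance(c, b))
  }
})

test_that("matching pads the shorter list and attributes failure modes", {
  a <- make_compound("benzaldehyde", mass = 2)
  b <- make_compound("aniline", mass = 3)
  pairs <- match_messages(list(a), list(a, b))
  expect_equal(sort(pairs$mode), c("ACCURATE", "ADDITION"))
  acc <- pairs[pairs$mode == "ACCURATE", ]
  expect_equal(acc$gt_index, 1L)
  expect_equal(acc$pred_index, 1L)
  expect_equal(nrow(match_messages(list(), list())), 0)
})

test_that("matching recovers alteration and removal in the three-compound case", {
  c1 <- make_compound("benzaldehyde", mass = 2)
  c2 <- make_compound("aniline", mass = 3)
  c3 <- make_compound("methanol", volume = 30, role = "SOLVENT")
  c2_alt <- c2
  c2_alt$amount$mass$value <- 99
  pairs <- match_messages(list(c1, c2, c3), list(c1, c2_alt))
  tally <- classify_messages(pairs)
  expect_equal(tally$accurate, 1)
  expect_equal(tally$alteration, 1)
  expect_equal(tally$removal, 1)
  expect_equal(tally$addition, 0)
  expect_equal(tally$total, 3)
  alt <- pairs[pairs$mode == "ALTERATION", ]
  expect_equal(alt$gt_index, 2L)
  expect_equal(alt$pred_index, 2L)
})

test_that("assignment matches the exhaustive brute-force oracle", {
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(2:5, 1)
    cost <- matrix(sample(0:6, n * n, replace = TRUE), n, n)
    a <- solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), brute_force_min_cost(cost))
  }
})

test_that("leaf classification mirrors the message assignment", {
  # altered pair: one changed amount value, one extra reaction_role leaf
  gt <- make_compound("NaH", mass = 5)
  gt$reaction_role <- NULL
  pred <- make_compound("NaH", mass = 7, role = "REACTANT")
  pairs <- match_messages(list(gt), list(pred))
  leaves <- classify_leaves(list(gt), list(pred), pairs, "Compound")
  expect_equal(sum(leaves$alteration), 1) # amount value
  expect_equal(sum(leaves$addition), 1) # reaction_role
  expect_equal(leaves$alteration[leaves$field_type == "amount"], 1)
  expect_equal(leaves$addition[leaves$field_type == "reaction role"], 1)

  # removed message: every leaf becomes a removal
  pairs_rm <- match_messages(list(gt), list())
  leaves_rm <- classify_leaves(list(gt), list(), pairs_rm, "Compound")
  expect_equal(sum(leaves_rm$removal), ordbench:::n_leaves(gt))
  expect_equal(sum(leaves_rm$accurate), 0)

  # accurate pair: k accurate leaves, no failures
  pairs_ok <- match_messages(list(pred), list(pred))
  leaves_ok <- classify_leaves(list(pred), list(pred), pairs_ok, "Compound")
  expect_equal(sum(leaves_ok$accurate), ordbench:::n_leaves(pred))
  expect_equal(sum(leaves_ok$removal + leaves_ok$addition + leaves_ok$alteration), 0)
})

test_that("lenient equivalence ignores derived fields but not identifiers/amounts", {
  a <- make_product("compound 7", yield = 83, mass = 1.2,
                    texture = "SOLID", color = "white")
  b <- make_product("compound 7", yield = 83, mass = 1.2,
                    texture = "OIL", color = "yellow")
  expect_true(lenient_equal(a, b))
  expect_true(lenient_equal(a, a))

  c <- make_product("compound 8", yield = 83, mass = 1.2)
  expect_false(lenient_equal(a, c))
  d <- make_product("compound 7", yield = 83, mass = 9.9)
  expect_false(lenient_equal(a, d))
  # a differing calculated yield is a derived field: still leniently equal
  e <- make_product("compound 7", yield = 12, mass = 1.2)
  expect_true(lenient_equal(a, e))
})

test_that("a perfect prediction scores 100 percent everywhere", {
  corpus <- gen_corpus(gen_config(n_reactions = 4, seed = 9))
  evals <- evaluate_records(corpus, corpus)
  report <- aggregate_report(evals)
  expect_true(all(report$message$accurate == report$message$total))
  expect_true(all(report$message$accurate_pct == 100))
  expect_true(all(report$leaf$accurate == report$leaf$total))
})

test_that("a deleted workup counts as one removal", {
  corpus <- gen_corpus(gen_config(n_reactions = 1, seed = 13,
                                  workup_range = c(3, 5)))
  gt <- corpus$record[[1]]
  pred <- gt
  pred$workups[[2]] <- NULL
  ev <- evaluate_reaction(gt, pred)
  wk <- ev$message[ev$message$message_type == "ReactionWorkup" &
                     ev$message$variant == "strict", ]
  expect_equal(wk$removal, 1)
  expect_equal(wk$accurate, length(gt$workups) - 1)
})

test_that("an unparseable prediction removes all messages (conditions alter)", {
  corpus <- gen_corpus(gen_config(n_reactions = 1, seed = 21))
  gt <- corpus$record[[1]]
  ev <- evaluate_reaction(gt, NULL)
  msg <- ev$message[ev$message$variant == "strict", ]
  cmp <- msg[msg$message_type == "Compound", ]
  expect_equal(cmp$removal, cmp$total)
  cond <- msg[msg$message_type == "ReactionConditions", ]
  expect_equal(cond$alteration, 1)
})

test_that("conditions are a single message: only accurate or altered", {
  corpus <- gen_corpus(gen_config(n_reactions = 1, seed = 31))
  gt <- corpus$record[[1]]
  pred <- gt
  pred$conditions$temperature$setpoint$value <- 999
  ev <- evaluate_reaction(gt, pred)
  cond <- ev$message[ev$message$message_type == "ReactionConditions", ]
  expect_true(all(cond$removal == 0))
  expect_true(all(cond$addition == 0))
  expect_equal(unique(cond$alteration), 1L)
})

test_that("lenient variant upgrades role-only compound alterations", {
  corpus <- gen_corpus(gen_config(n_reactions = 1, seed = 41,
                                  compounds_range = c(2, 3)))
  gt <- corpus$record[[1]]
  pred <- gt
  comp <- pred$inputs[["m1"]]$components[[1]]
  comp$reaction_role <- setdiff(c("REACTANT", "SOLVENT", "CATALYST"),
                                comp$reaction_role)[1]
  pred$inputs[["m1"]]$components[[1]] <- comp
  ev <- evaluate_reaction(gt, pred)
  strict <- ev$message[ev$message$variant == "strict" &
                         ev$message$message_type == "Compound", ]
  lenient <- ev$message[ev$message$variant == "lenient" &
                          ev$message$message_type == "Compound", ]
  expect_equal(strict$alteration, 1)
  expect_equal(lenient$alteration, 0)
  expect_equal(lenient$accurate, strict$accurate + 1)
})

test_that("aggregation reproduces printed-table percentage arithmetic", {
  row <- tally_percentages(tibble::tibble(
    accurate = 38470, removal = 2242, addition = 1015,
    alteration = 4242, total = 44954
  ))
  expect_equal(row$accurate_pct, 85.6)
  expect_equal(row$removal_pct, 5.0)
  expect_equal(row$addition_pct, 2.3)
  expect_equal(row$alteration_pct, 9.4)
  expect_equal(pct_half_up(9105, 10451), 87.1)
  empty <- aggregate_report(list())
  expect_equal(nrow(empty$message), 0)
})
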