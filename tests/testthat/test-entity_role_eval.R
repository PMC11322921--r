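# Compound-name recognition scoring and reaction-role classification
# evaluation with the popularity baseline.

test_that("extract_names collects NAME identifiers incl. referencing tokens", {
  rec <- list(
    inputs = list(m1 = list(components = list(
      make_compound("THF", volume = 5, role = "SOLVENT"),
      make_compound("NaH", mass = 1)
    ))),
    outcomes = list(list(products = list(make_product("compound 5", yield = 80))))
  )
  expect_setequal(extract_names(rec), c("THF", "NaH", "compound 5"))
  expect_length(extract_names(list()), 0)
  rec2 <- list(outcomes = list(list(products = list(
    make_product("desired product")
  ))))
  expect_equal(extract_names(rec2), "desired product")
})

test_that("name comparison pairs by edit distance and tallies modes", {
  same <- compare_names(c("a", "b"), c("b", "a"))
  expect_equal(same$accurate, 2)
  expect_equal(same$total, 2)

  t1 <- compare_names(c("tryptophan methyl ester", "9"),
                      "tryptophan methyl ester")
  expect_equal(t1$accurate, 1)
  expect_equal(t1$removal, 1)
  expect_equal(t1$addition, 0)

  t2 <- compare_names("A", c("A", "1H"))
  expect_equal(t2$accurate, 1)
  expect_equal(t2$addition, 1)

  t3 <- compare_names("palladium on carbon", "palladium on  carbon ")
  expect_equal(t3$accurate, 1) # whitespace-normalized

  t4 <- compare_names("benzaldehyde", "benzaldehyd")
  expect_equal(t4$alteration, 1)
})

test_that("name tallies conserve on random multisets", {
  pool <- c("THF", "NaH", "benzaldehyde", "compound 12", "aniline", "brine")
  set.seed(6)
  for (rep in 1:25) {
    gt <- sample(pool, sample(0:5, 1), replace = TRUE)
    pred <- sample(pool, sample(0:5, 1), replace = TRUE)
    t <- compare_names(gt, pred)
    expect_equal(t$accurate + t$removal + t$alteration, length(gt))
    expect_equal(t$accurate + t$addition + t$alteration, length(pred))
    expect_equal(t$total, length(gt))
  }
})

test_that("popularity table counts per-name role frequencies", {
  rec <- list(inputs = list(m1 = list(components = list(
    make_compound("THF", volume = 5, role = "SOLVENT")
  ))))
  tab <- build_popularity_table(list(rec))
  expect_equal(tab$name, "THF")
  expect_equal(tab$role, "SOLVENT")
  expect_equal(tab$n, 1L)
  expect_equal(nrow(build_popularity_table(list())), 0)
  # the same name may be counted under several roles
  rec2 <- list(inputs = list(m1 = list(components = list(
    make_compound("THF", volume = 5, role = "REACTANT")
  ))))
  tab2 <- build_popularity_table(list(rec, rec2))
  expect_equal(sort(tab2$role), c("REACTANT", "SOLVENT"))
})

test_that("popularity prediction is argmax with uniform tie/unseen draws", {
  tab <- tibble::tibble(
    name = c("THF", "THF", "mix", "mix"),
    role = c("SOLVENT", "REACTANT", "REACTANT", "SOLVENT"),
    n = c(10L, 1L, 5L, 5L)
  )
  expect_equal(popularity_predict("THF", tab), "SOLVENT")

  # tie: 10 000 seeded draws within 3 sigma of 50/50
  set.seed(123)
  draws <- popularity_predict(rep("mix", 10000), tab)
  p_hat <- mean(draws == "REACTANT")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(draws %in% c("REACTANT", "SOLVENT")))

  # unseen: uniform over all three roles
  set.seed(321)
  draws2 <- popularity_predict(rep("unobtainium", 9000), tab)
  for (r in c("REACTANT", "SOLVENT", "CATALYST")) {
    expect_lt(abs(mean(draws2 == r) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 9000))
  }

  # deterministic given a seed
  set.seed(99)
  a <- popularity_predict(rep("mix", 5), tab)
  set.seed(99)
  b <- popularity_predict(rep("mix", 5), tab)
  expect_identical(a, b)
})

test_that("role confusion matrix attributes MISSING and ERROR correctly", {
  gt_rec <- list(inputs = list(m1 = list(components = list(
    make_compound("benzaldehyde", mass = 2, role = "REACTANT"),
    make_compound("THF", volume = 30, role = "SOLVENT"),
    make_compound("palladium on carbon", mass = 0.1, role = "CATALYST")
  ))))
  gt <- tibble::tibble(source_id = "r1", record = list(gt_rec))

  # perfect prediction: identity diagonal
  cm <- role_confusion(gt, gt)
  expect_equal(diag(unclass(cm)[, 1:3]), setNames(rep(1L, 3),
    c("REACTANT", "SOLVENT", "CATALYST")))
  expect_equal(sum(cm[, c("MISSING", "ERROR")]), 0)

  # dropped compound -> MISSING for its true role
  pred_rec <- gt_rec
  pred_rec$inputs$m1$components[[2]] <- NULL
  pred <- tibble::tibble(source_id = "r1", record = list(pred_rec))
  cm2 <- role_confusion(gt, pred)
  expect_equal(cm2["SOLVENT", "MISSING"], 1L)

  # wrong name on the paired catalyst -> ERROR
  pred_rec2 <- gt_rec
  pred_rec2$inputs$m1$components[[3]]$identifiers[[1]]$value <- "palladium black"
  pred2 <- tibble::tibble(source_id = "r1", record = list(pred_rec2))
  cm3 <- role_confusion(gt, pred2)
  expect_equal(cm3["CATALYST", "ERROR"], 1L)

  # row sums always equal ground-truth per-role counts
  for (cmx in list(cm, cm2, cm3)) expect_equal(unname(rowSums(cmx)), c(1, 1, 1))
})

test_that("macro F1 follows the stated conventions", {
  perfect <- ordbench:::new_role_confusion(ordbench:::empty_confusion())
  diag(perfect[, 1:3]) <- 10L
  expect_equal(macro_f1(perfect), 1.0)

  # constant-REACTANT predictor on a balanced 30-compound set
  cm <- ordbench:::empty_confusion()
  cm[, "REACTANT"] <- 10L
  expect_equal(macro_f1(ordbench:::new_role_confusion(cm)), 1 / 6)

  # single-class ground truth predicted perfectly: zero-support roles add 0
  cm2 <- ordbench:::empty_confusion()
  cm2["REACTANT", "REACTANT"] <- 5L
  expect_equal(macro_f1(ordbench:::new_role_confusion(cm2)), 1 / 3)

  expect_true(is.na(macro_f1(ordbench:::new_role_confusion(
    ordbench:::empty_confusion()
  ))))

  # MISSING/ERROR are false negatives of the true role
  cm3 <- ordbench:::empty_confusion()
  cm3["REACTANT", "REACTANT"] <- 5L
  cm3["REACTANT", "MISSING"] <- 5L
  f1_reactant <- 2 * 1 * 0.5 / 1.5
  expect_equal(macro_f1(ordbench:::new_role_confusion(cm3)), f1_reactant / 3)
})

test_that("tidy and row percentages are consistent", {
  cm <- ordbench:::empty_confusion()
  cm["REACTANT", "REACTANT"] <- 3L
  cm["REACTANT", "MISSING"] <- 1L
  cm <- ordbench:::new_role_confusion(cm)
  td <- tidy(cm)
  expect_equal(sum(td$n), 4)
  expect_equal(
    td$row_pct[td$true == "REACTANT" & td$predicted == "REACTANT"], 75.0
  )
})
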