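# Corpus preparation: admission, scrubbing, prompt rendering, dedup,
# token filtering, splitting and the prep report.

test_that("admission requires populated inputs and a procedure paragraph", {
  good <- list(inputs = list(
    m1 = list(components = list(make_compound("a", mass = 1))),
    m2 = list(components = list(make_compound("b", volume = 2)))
  ))
  expect_true(admit_record(good, "A solution of a and b was stirred."))

  empty_input <- list(inputs = list(m1 = list(components = list())))
  expect_false(admit_record(empty_input, "Some text."))
  expect_false(admit_record(good, ""))
  expect_false(admit_record(good, "   "))
})

test_that("scrubbing removes names absent from the text and mismatched yields", {
  rec <- list(
    inputs = list(m1 = list(components = list(
      make_compound("benzaldehyde", mass = 2)
    ))),
    outcomes = list(list(products = list(
      make_product("4-methylbenzanilide", yield = 83, mass = 1.0)
    )))
  )
  # product named only in the patent title: NAME identifier removed + logged
  corpus <- tibble::tibble(
    source_id = "r1",
    procedure_text = "benzaldehyde was stirred; the product formed in 85% yield.",
    record = list(rec)
  )
  out <- scrub_implicit(corpus)
  paths <- out$scrubbed_paths[[1]]
  expect_setequal(paths, c(
    "outcomes[0].products[0].identifiers[0]",
    "outcomes[0].products[0].measurements[0]"
  ))
  scrubbed <- out$record[[1]]
  expect_null(scrubbed$outcomes[[1]]$products[[1]]$identifiers)
  kept_types <- vapply(
    scrubbed$outcomes[[1]]$products[[1]]$measurements,
    function(m) m$type, character(1)
  )
  expect_equal(kept_types, "AMOUNT")

  # stated yield and name are retained
  corpus2 <- tibble::tibble(
    source_id = "r1",
    procedure_text = "benzaldehyde gave 4-methylbenzanilide in 83% yield.",
    record = list(rec)
  )
  out2 <- scrub_implicit(corpus2)
  expect_length(out2$scrubbed_paths[[1]], 0)
  expect_identical(out2$record[[1]], rec)
})

test_that("scrubbing is idempotent", {
  cfg <- gen_config(n_reactions = 6, seed = 8, p_omit_product_name = 0.5)
  corpus <- gen_corpus(cfg)
  once <- scrub_implicit(corpus)
  twice <- scrub_implicit(once)
  expect_identical(twice$record, once$record)
  expect_true(all(lengths(twice$scrubbed_paths) == 0))
})

test_that("prompt rendering is deterministic and round-trips the record", {
  corpus <- gen_corpus(gen_config(n_reactions = 2, seed = 3))
  ex1 <- render_prompts(corpus)
  ex2 <- render_prompts(corpus)
  expect_identical(ex1, ex2)
  expect_true(all(grepl("### Input:", ex1$prompt, fixed = TRUE)))
  expect_false(any(grepl("{input}", ex1$prompt, fixed = TRUE)))
  for (i in seq_len(nrow(ex1))) {
    expect_identical(parse_record(ex1$completion[i]), corpus$record[[i]])
  }
  expect_error(
    render_prompts(corpus, template = "no placeholders here"),
    class = "ordbench_config_error"
  )
})

test_that("dedup keeps first occurrence per prompt and logs conflicts", {
  ex <- tibble::tibble(
    prompt = c("p1", "p1", "p2", "p1"),
    completion = c("c1", "c1", "c2", "cX")
  )
  out <- dedupe(ex)
  expect_equal(out$prompt, c("p1", "p2"))
  expect_equal(out$completion, c("c1", "c2"))
  conflicts <- attr(out, "conflicts")
  expect_equal(nrow(conflicts), 1)
  expect_equal(conflicts$completion, "cX")
  # idempotent
  again <- dedupe(out)
  expect_equal(again$prompt, out$prompt)
  expect_equal(nrow(dedupe(ex[0, ])), 0)
})

test_that("token filter is inclusive at the limit", {
  ex <- tibble::tibble(
    prompt = "p", completion = "c",
    token_count = c(2048L, 2049L, 0L)
  )
  out <- token_filter(ex)
  expect_equal(out$kept$token_count, c(2048L, 0L))
  expect_equal(out$dropped$token_count, 2049L)
})

test_that("the default tokenizer counts words and punctuation", {
  expect_equal(count_tokens("benzaldehyde (2.5 g, 80%)"), 10L)
  expect_equal(count_tokens(""), 0L)
})

test_that("splits are apportioned by largest remainder, seeded and disjoint", {
  ex <- tibble::tibble(prompt = as.character(1:100), completion = "c",
                       token_count = 1L, split = "none")
  s1 <- split_examples(ex, seed = 11)
  expect_equal(as.vector(table(s1$split)[c("train", "validation", "test")]),
               c(80L, 10L, 10L))
  s2 <- split_examples(ex, seed = 11)
  expect_identical(s1$split, s2$split)

  ex10 <- ex[1:10, ]
  s10 <- split_examples(ex10, seed = 4)
  expect_equal(sort(as.vector(table(s10$split)), decreasing = TRUE),
               c(8L, 1L, 1L))

  for (n in 3:8) {
    sn <- split_examples(ex[seq_len(n), ], seed = n)
    expect_equal(sum(table(sn$split)), n) # exhaustive, disjoint by column
  }
  expect_error(split_examples(ex[1:2, ]), class = "ordbench_config_error")
})

test_that("prep report computes retention at one decimal, half-up", {
  rep <- prep_report(1400000, 1380000, 1339260, 1300613)
  expect_equal(rep$retention_pct, 97.1)
  expect_equal(prep_report(10, 10, 10, 10)$retention_pct, 100.0)
  expect_equal(prep_report(10, 10, 10, 0)$retention_pct, 0.0)
  expect_true(is.na(prep_report(0, 0, 0, 0)$retention_pct))
  expect_error(prep_report(5, 6, 4, 3), class = "ordbench_config_error")
})

test_that("the full prep pipeline holds its stage-count invariants", {
  cfg <- gen_config(n_reactions = 20, seed = 15, p_omit_product_name = 0.3)
  corpus <- gen_corpus(cfg)
  prep <- prep_corpus(corpus, seed = 5)
  r <- prep$report
  expect_true(r$n_in >= r$n_admitted)
  expect_true(r$n_admitted >= r$n_unique)
  expect_true(r$n_unique >= r$n_within_limit)
  expect_equal(nrow(prep$examples), r$n_within_limit)
  expect_true(all(prep$examples$split %in% c("train", "validation", "test")))
  # scrub log lines come only from records whose product name was omitted
  expect_setequal(
    unique(prep$scrub_log$source_id),
    corpus$source_id[!corpus$product_name_in_text]
  )
})
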