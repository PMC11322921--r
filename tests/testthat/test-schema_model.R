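# Schema loading, parsing, leaf flattening and syntactic validation.

test_that("schema vocabulary loads with unique paths and populated enums", {
  spec <- ord_schema()
  expect_true(all(!duplicated(spec$path)))
  enums <- spec$enum[spec$kind == "enum"]
  expect_true(all(lengths(enums) > 0))
  expect_true("workups[].type" %in% spec$path)
  expect_true("FILTRATION" %in% ordbench:::schema_enum(spec, "workups[].type"))
})

test_that("parsing handles empty records, nested compounds and bad JSON", {
  expect_equal(nrow(leaf_fields(parse_record("{}"))), 0)

  json <- '{
    "inputs": {"m1": {"components": [{
      "identifiers": [{"type": "NAME", "value": "benzaldehyde"}],
      "amount": {"mass": {"value": 5.0, "units": "GRAM"}}
    }]}}
  }'
  node <- parse_record(json)
  leaves <- leaf_fields(node)
  expect_setequal(
    leaves$path,
    c('inputs["m1"].components[0].identifiers[0].type',
      'inputs["m1"].components[0].identifiers[0].value',
      'inputs["m1"].components[0].amount.mass.value',
      'inputs["m1"].components[0].amount.mass.units')
  )
  expect_error(parse_record('{"a": 1'), class = "ordbench_parse_error")
})

test_that("explicit nulls are stripped so unpopulated fields are absent", {
  node <- parse_record('{"workups": [{"type": "WASH", "details": null}]}')
  expect_equal(leaf_fields(node)$path, "workups[0].type")
})

test_that("leaf enumeration is depth-first and index-ordered", {
  node <- parse_record('{
    "identifiers": [
      {"type": "NAME", "value": "a"},
      {"type": "SMILES", "value": "C"}
    ]
  }')
  expect_equal(
    leaf_fields(node)$path,
    c("identifiers[0].type", "identifiers[0].value",
      "identifiers[1].type", "identifiers[1].value")
  )
  amount <- parse_record('{"amount": {"mass": {"value": 5.0, "units": "GRAM"}}}')
  lf <- leaf_fields(amount)
  expect_equal(lf$path, c("amount.mass.value", "amount.mass.units"))
  expect_equal(lf$value[[1]], 5.0)
  expect_equal(lf$value[[2]], "GRAM")
})

test_that("validation flags out-of-vocabulary enums, bad types and unknown fields", {
  ok <- parse_record('{"workups": [{"type": "FILTRATION"}]}')
  expect_equal(nrow(validate_record(ok)), 0)
  expect_equal(nrow(validate_record(parse_record("{}"))), 0)

  bad_enum <- parse_record('{"workups": [{"type": "SHAKEN_VIGOROUSLY"}]}')
  rep <- validate_record(bad_enum)
  expect_equal(rep$violation, "out-of-vocabulary enum")
  expect_equal(rep$path, "workups[0].type")

  # enum matching is case-sensitive
  expect_false(is_valid_record(parse_record('{"workups": [{"type": "filtration"}]}')))

  bad_type <- parse_record(
    '{"conditions": {"temperature": {"setpoint": {"value": "hot"}}}}'
  )
  expect_equal(validate_record(bad_type)$violation, "wrong scalar type")

  unknown <- parse_record('{"conditions": {"vortex_speed": 3}}')
  expect_equal(validate_record(unknown)$violation, "unknown field")
})

test_that("validation is idempotent and side-effect free", {
  node <- parse_record('{"workups": [{"type": "NOT_A_THING"}]}')
  before <- ord_serialize(node)
  r1 <- validate_record(node)
  r2 <- validate_record(node)
  expect_identical(r1, r2)
  expect_identical(ord_serialize(node), before)
})

test_that("records round-trip through canonical serialization", {
  corpus <- gen_corpus(gen_config(n_reactions = 10, seed = 42))
  for (rec in corpus$record) {
    again <- parse_record(ord_serialize(rec))
    expect_identical(again, rec)
  }
})
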