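SCHEMAS <- emit_json_schema(REG, "all")

test_that("emission yields one combined plus seven category schemas", {
  expect_length(SCHEMAS, 8L)
  expect_identical(names(SCHEMAS)[1], "record_schema.json")
  expect_setequal(names(SCHEMAS)[-1],
                  paste0(tolower(REG$categories), "_schema.json"))
  # deterministic: identical registries produce byte-identical documents
  again <- emit_json_schema(build_default_registry(), "all")
  expect_identical(vapply(SCHEMAS, schema_to_json, ""),
                   vapply(again, schema_to_json, ""))
})

test_that("vocabularies become enumerations of the exact values", {
  spec <- emit_json_schema(REG, "Specimen")
  expect_identical(spec$properties$Sex$enum,
                   c("Male", "Female", "Unknown"))
  expect_length(spec$properties$Sex$enum, 3L)
  img <- emit_json_schema(REG, "Image")
  expect_length(img$properties$xAxis$enum, 7L)
  # unconditionally required scalar fields are in the required list
  expect_setequal(unlist(emit_json_schema(REG, "Dataset")$required),
                  c("Title", "Rights", "Abstract"))
})

test_that("the generic evaluator enforces the dialect subset", {
  sch <- list(type = "object",
              properties = list(a = list(type = "number",
                                         exclusiveMinimum = 0),
                                b = list(enum = list("x", "y"))),
              required = list("a"), additionalProperties = FALSE)
  expect_true(validate_against_schema(list(a = 1, b = "x"), sch)$valid)
  expect_false(validate_against_schema(list(a = 0), sch)$valid)
  expect_false(validate_against_schema(list(a = 1, z = 2), sch)$valid)
  expect_false(validate_against_schema(list(b = "x"), sch)$valid)
  expect_false(validate_against_schema(list(a = 1, b = "q"), sch)$valid)
  cond <- list(`if` = list(properties = list(t = list(const = "P")),
                           required = list("t")),
               then = list(required = list("id")))
  expect_false(validate_against_schema(list(t = "P"), cond)$valid)
  expect_true(validate_against_schema(list(t = "O"), cond)$valid)
  arr <- list(type = "array", minItems = 1L,
              contains = list(properties = list(k = list(const = "Yes")),
                              required = list("k")))
  expect_true(validate_against_schema(list(list(k = "Yes")), arr)$valid)
  expect_false(validate_against_schema(list(list(k = "No")), arr)$valid)
})

test_that("clean records pass the combined schema; gutted ones fail", {
  combined <- SCHEMAS$record_schema.json
  for (seed in c(5, 17, 23, 31)) {
    rec <- generate_valid_record(generator_config(seed = seed), REG)
    doc <- jsonlite::fromJSON(record_bytes(rec), simplifyVector = FALSE)
    res <- validate_against_schema(doc, combined)
    expect_true(res$valid, label = paste("seed", seed,
                                         paste(res$errors, collapse = "; ")))
    inj <- inject_errors(rec, "REQUIRED_MISSING", seed = seed)
    bad <- jsonlite::fromJSON(record_bytes(inj$record),
                              simplifyVector = FALSE)
    expect_false(validate_against_schema(bad, combined)$valid,
                 label = paste("fault seed", seed))
  }
})

test_that("schema files are written and re-readable", {
  dir <- withr::local_tempdir()
  paths <- write_schema_files(REG, dir)
  expect_length(paths, 8L)
  expect_true(all(file.exists(paths)))
  sch <- jsonlite::fromJSON(file.path(dir, "record_schema.json"),
                            simplifyVector = FALSE)
  # the re-read schema document drives the evaluator identically
  rec <- generate_valid_record(generator_config(seed = 77), REG)
  doc <- jsonlite::fromJSON(record_bytes(rec), simplifyVector = FALSE)
  expect_true(validate_against_schema(doc, sch)$valid)
  expect_match(sch$`$schema`, "2020-12")
})
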