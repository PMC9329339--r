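test_that("the built-in registry reproduces the standard's structure", {
  expect_s3_class(REG, "mms_registry")
  expect_identical(registry_version(REG), "1.0.0")
  expect_identical(REG$categories,
                   c("Contributors", "Funders", "Dataset", "Image",
                     "Instrument", "Publication", "Specimen"))
  expect_identical(count_fields(REG), 91L)
  totals <- c(Contributors = 9L, Funders = 5L, Dataset = 15L, Image = 33L,
              Instrument = 12L, Publication = 5L, Specimen = 12L)
  for (cat_ in names(totals))
    expect_identical(count_fields(REG, category = cat_), totals[[cat_]])
  # sum of per-category counts equals the total
  expect_identical(sum(vapply(REG$categories, function(c)
    count_fields(REG, category = c), 0L)), count_fields(REG))
})

test_that("requirement levels follow the required-field table", {
  required <- c(Contributors = 9L, Dataset = 5L, Funders = 5L,
                Instrument = 2L, Image = 8L, Specimen = 5L,
                Publication = 0L)
  for (cat_ in names(required))
    expect_identical(
      count_fields(REG, category = cat_, requirement = "bil_required"),
      required[[cat_]], label = paste("bil_required in", cat_))
  expect_identical(count_fields(REG, category = "Publication",
                                requirement = "optional"), 5L)
  # conditional fields: Funders block, Personal identifiers, common license
  f <- registry_fields(REG)
  cond <- f$name[f$requirement_level == "conditional"]
  expect_setequal(cond, c("funderName", "fundingReferenceIdentifier",
                          "fundingReferenceIdentifierType", "awardNumber",
                          "awardTitle", "nameIdentifier",
                          "nameIdentifierScheme", "rightsURI",
                          "rightsIdentifier"))
})

test_that("DOI-support flags match the standard", {
  expect_identical(count_fields(REG, requirement = "bil_required",
                                doi_support = TRUE), 19L)
  # all Contributors and Funders fields, plus the five required Dataset
  # fields, and nothing in Image/Instrument/Specimen
  for (cat_ in c("Contributors", "Funders"))
    expect_identical(count_fields(REG, category = cat_,
                                  doi_support = TRUE),
                     count_fields(REG, category = cat_))
  expect_identical(count_fields(REG, category = "Dataset",
                                doi_support = TRUE), 5L)
  for (cat_ in c("Image", "Instrument", "Specimen", "Publication"))
    expect_identical(count_fields(REG, category = cat_,
                                  doi_support = TRUE), 0L)
})

test_that("field lookup is case-aware with near-miss suggestions", {
  fs <- get_field(REG, "displayColor")
  expect_identical(fs$category, "Image")
  expect_identical(fs$requirement_level, "required")
  expect_warning(fs2 <- get_field(REG, "DISPLAYCOLOR"),
                 "case-insensitively")
  expect_identical(fs2$name, "displayColor")
  expect_error(get_field(REG, "displayColour"), "displayColor")
  expect_error(get_field(REG, "Sex", category = "Image"), "did you mean")
  expect_error(count_fields(REG, category = "Imagery"), "unknown category")
  expect_error(count_fields(REG, requirement = "mandatory"),
               "unknown requirement")
})

test_that("vocabularies are encoded exactly", {
  expect_identical(get_field(REG, "Sex")$vocabulary[[1]],
                   c("Male", "Female", "Unknown"))
  expect_identical(get_field(REG, "Ageunit")$vocabulary[[1]],
                   c("Days", "Months", "Years"))
  expect_length(get_field(REG, "contributorType")$vocabulary[[1]], 10L)
  expect_identical(get_field(REG, "nameIdentifierScheme")$vocabulary[[1]],
                   c("GRID", "ISNI", "ORCID", "ROR", "RRID"))
  expect_length(get_field(REG, "xAxis")$vocabulary[[1]], 7L)
  # vocabulary non-empty iff declared as a vocabulary field
  f <- registry_fields(REG)
  expect_identical(vapply(f$vocabulary, length, 0L) > 0L,
                   f$value_kind == "vocabulary")
})

test_that("the registry dump is machine-readable and complete", {
  txt <- export_registry_json(REG)
  dump <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(dump$version, "1.0.0")
  expect_length(dump$fields, 91L)
  provs <- vapply(dump$fields, `[[`, "", "provenance")
  expect_setequal(unique(provs), c("table-1", "synthesized-from-prose"))
  # the printed required-field table contributes exactly 34 field names
  expect_identical(sum(provs == "table-1"), 34L)
})
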