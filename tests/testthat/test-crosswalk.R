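test_that("crosswalk counts match the pinned per-category statements", {
  expect_identical(mapping_counts(REG, "DataCite", "Contributors"), 9L)
  expect_identical(mapping_counts(REG, "DataCite", "Funders"), 5L)
  expect_identical(mapping_counts(REG, "DataCite", "Dataset"), 8L)
  expect_identical(mapping_counts(REG, "DataCite", "Publication"), 3L)
  expect_identical(mapping_counts(REG, "DataCite"), 25L)
  expect_identical(mapping_counts(REG, "OME", "Instrument"), 12L)
  expect_identical(mapping_counts(REG, "OME", "Image"), 15L)
  expect_identical(mapping_counts(REG, "OME"), 27L)
  # every Instrument field maps to OME
  expect_identical(mapping_counts(REG, "OME", "Instrument"),
                   count_fields(REG, category = "Instrument"))
  # required-and-DataCite equals the DOI-support flag count
  f <- registry_fields(REG)
  expect_identical(sum(!is.na(f$datacite_property) &
                         f$requirement_level != "optional" &
                         f$doi_support), 19L)
  # (mms_field, target) pairs unique
  cw <- crosswalk_table(REG)
  expect_false(any(duplicated(cw[, c("mms_field", "target")])))
})

test_that("creators partition contributors in the DataCite export", {
  rec <- empty_record(funding_declared = FALSE)
  rec$Contributors <- list(
    list(contributorName = "Doe, Jane", Creator = TRUE,
         contributorType = "ProjectLeader", nameType = "Personal",
         nameIdentifier = make_orcid(), nameIdentifierScheme = "ORCID",
         affiliation = "Inst", affiliationIdentifier = "05gvnxz63",
         affiliationIdentifierScheme = "ROR"),
    list(contributorName = "Imaging Core", Creator = FALSE,
         contributorType = "ResearchGroup", nameType = "Organizational",
         affiliation = "Inst", affiliationIdentifier = "05gvnxz63",
         affiliationIdentifierScheme = "ROR"))
  rec$Dataset <- list(Title = "T", Rights = "CC BY", Abstract = "A")
  doc <- export_datacite(rec, REG)
  expect_length(doc$creators, 1L)
  expect_length(doc$contributors, 2L)
  expect_identical(doc$creators[[1]]$name, "Doe, Jane")
  expect_identical(doc$contributors[[2]]$contributorType, "ResearchGroup")
  expect_identical(doc$descriptions[[1]]$descriptionType, "Abstract")
})

test_that("export refuses records that fail the DOI profile", {
  rec <- generate_valid_record(generator_config(seed = 61), REG)
  for (i in seq_along(rec$Contributors))
    rec$Contributors[[i]]$Creator <- FALSE
  err <- tryCatch(export_datacite(rec, REG), error = function(e) e)
  expect_s3_class(err, "mms_doi_validation_error")
  expect_true("NO_CREATOR" %in% err$report$issues$code)
})

test_that("every populated DOI-supporting value lands in the export", {
  text_doi_fields <- list(
    c("Dataset", "Title"), c("Dataset", "Rights"),
    c("Dataset", "rightsURI"), c("Dataset", "rightsIdentifier"),
    c("Dataset", "Abstract"))
  for (seed in c(2, 9, 33)) {
    rec <- generate_valid_record(generator_config(seed = seed), REG)
    out <- as.character(jsonlite::toJSON(export_datacite(rec, REG),
                                         auto_unbox = TRUE, digits = NA))
    for (tgt in text_doi_fields) {
      v <- rec[[tgt[1]]][[tgt[2]]]
      if (!is.null(v))
        expect_true(grepl(v, out, fixed = TRUE),
                    label = paste(seed, tgt[2]))
    }
    for (e in rec$Contributors)
      for (nm in c("contributorName", "nameIdentifier", "affiliation",
                   "affiliationIdentifier"))
        if (!is.null(e[[nm]]))
          expect_true(grepl(e[[nm]], out, fixed = TRUE),
                      label = paste(seed, nm))
    for (e in rec$Funders)
      for (nm in names(e))
        expect_true(grepl(e[[nm]], out, fixed = TRUE),
                    label = paste(seed, nm))
  }
})

test_that("the XML rendering mirrors the JSON kernel properties", {
  rec <- generate_valid_record(generator_config(seed = 71), REG)
  doc <- export_datacite(rec, REG)
  x <- datacite_xml(doc)
  expect_identical(xml2::xml_name(x), "resource")
  creators <- xml2::xml_find_all(x, ".//*[local-name()='creator']")
  expect_length(creators, length(doc$creators))
  fr <- xml2::xml_find_all(x, ".//*[local-name()='fundingReference']")
  expect_length(fr, length(doc$fundingReferences))
})

test_that("the OME report lists populated mapped fields with terms", {
  rec <- generate_valid_record(generator_config(seed = 81), REG)
  rep <- ome_report(rec, REG)
  expect_true(all(rep$ome_term != ""))
  expect_true("stepSizeX" %in% rep$mms_field)
  # one displayColor row per channel
  expect_identical(sum(rep$mms_field == "displayColor"),
                   length(rec$Image$Channels))
  # unmapped fields never appear
  expect_false("numberOfFiles" %in% rep$mms_field)
})
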