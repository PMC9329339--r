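test_that("parsing copies recognized fields and flags unknown keys", {
  doc <- list(Specimen = list(Sex = "Female", weight = "20g"),
              Dataset = list(Title = "t"))
  res <- parse_record(doc, REG)
  expect_identical(res$record$Specimen$Sex, "Female")
  expect_identical(res$record$Dataset$Title, "t")
  expect_identical(nrow(res$issues), 1L)
  expect_identical(res$issues$code, "UNKNOWN_FIELD")
  expect_identical(res$issues$path, "Specimen.weight")
})

test_that("parsing is total: multiplicity and bad scalars become issues", {
  doc <- list(Dataset = list(Title = list("a", "b")),
              Image = list(stepSizeX = "fast"),
              Contributors = list(contributorName = "Doe, J"))
  res <- parse_record(doc, REG)
  expect_identical(sort(unique(res$issues$code)),
                   c("MULTIPLICITY", "UNPARSEABLE"))
  # values are kept, not dropped
  expect_identical(res$record$Dataset$Title, c("a", "b"))
  expect_identical(res$record$Image$stepSizeX, "fast")
  # single object wrapped as one contributor entry
  expect_length(res$record$Contributors, 1L)
})

test_that("display colors accept spreadsheet dialects, canonical out", {
  for (raw in list("255,0,0", "(255, 0, 0)", "[255,0,0]",
                   list(255L, 0L, 0L))) {
    doc <- list(Image = list(Channels = list(list(Number = "1",
                                                  displayColor = raw))))
    res <- parse_record(doc, REG)
    expect_identical(res$record$Image$Channels[[1]]$displayColor,
                     c(255L, 0L, 0L), label = paste("dialect", raw))
  }
  rec <- empty_record()
  rec$Image$Channels <- list(list(Number = "1",
                                  displayColor = c(255L, 0L, 0L)))
  doc <- serialize_record(rec, REG)
  expect_identical(doc$Image$Channels[[1]]$displayColor, "255,0,0")
})

test_that("Creator flags and Age sentinel round-trip", {
  doc <- list(Contributors = list(list(contributorName = "Doe, J",
                                       Creator = "Yes"),
                                  list(contributorName = "Lab",
                                       Creator = "No")),
              Specimen = list(Age = "unknown"))
  res <- parse_record(doc, REG)
  expect_true(res$record$Contributors[[1]]$Creator)
  expect_false(res$record$Contributors[[2]]$Creator)
  expect_identical(res$record$Specimen$Age, "unknown")
  out <- serialize_record(res$record, REG)
  expect_identical(out$Contributors[[1]]$Creator, "Yes")
  expect_identical(out$Specimen$Age, "unknown")
})

test_that("serialize-parse is the identity over a seeded corpus", {
  corpus <- generate_corpus(50, generator_config(seed = 11), fault_rate = 0,
                            registry = REG)
  for (x in corpus) {
    j <- record_bytes(x$record)
    res <- parse_record(jsonlite::fromJSON(j, simplifyVector = FALSE), REG)
    expect_identical(nrow(res$issues), 0L)
    expect_identical(record_bytes(res$record), j)
  }
  # serialization determinism: two runs, byte-identical
  rec <- corpus[[1]]$record
  expect_identical(record_bytes(rec), record_bytes(rec))
})

test_that("attaching shared contributors/funders appends and dedups", {
  recs <- lapply(1:3, function(i)
    generate_valid_record(generator_config(seed = i), REG))
  funder <- list(funderName = "National Institutes of Health",
                 fundingReferenceIdentifier = "01cwqze88",
                 fundingReferenceIdentifierType = "ROR",
                 awardNumber = "R01MH000001", awardTitle = "Shared grant")
  shared <- list(Funders = list(funder))
  out <- attach_common_metadata(recs, shared)
  for (i in 1:3)
    expect_length(out[[i]]$Funders, length(recs[[i]]$Funders) + 1L)
  # idempotent: attaching again changes nothing
  out2 <- attach_common_metadata(out, shared)
  expect_identical(lapply(out2, record_bytes), lapply(out, record_bytes))
  # identity on the empty list
  expect_identical(attach_common_metadata(list(), shared), list())
  # anything beyond Contributors/Funders is refused
  expect_error(attach_common_metadata(recs, list(Specimen = list(Sex = "F"))),
               "only Contributors and Funders")
})
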