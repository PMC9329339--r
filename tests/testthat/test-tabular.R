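test_that("entry tables map one row to one entry", {
  tb <- tibble::tibble(
    contributorName = c("Doe, Jane", "Roe, Rex", "Imaging Core"),
    Creator = c("Yes", "No", "No"),
    contributorType = c("ProjectLeader", "Researcher", "ResearchGroup"),
    nameType = c("Personal", "Personal", "Organizational"))
  bundle <- structure(list(tables = list(Contributors = tb)),
                      class = "mms_bundle")
  res <- read_tabular(bundle, REG)
  expect_length(res$record$Contributors, 3L)
  expect_true(res$record$Contributors[[1]]$Creator)
  expect_identical(res$record$Contributors[[3]]$nameType,
                   "Organizational")
  expect_identical(nrow(res$issues), 0L)
})

test_that("misspelled headers become issues and are ignored", {
  tb <- tibble::tibble(contributorNmae = "Doe, Jane", Creator = "Yes")
  bundle <- structure(list(tables = list(Contributors = tb)),
                      class = "mms_bundle")
  res <- read_tabular(bundle, REG)
  expect_identical(res$issues$code, "UNKNOWN_FIELD")
  expect_identical(res$issues$path, "Contributors.contributorNmae")
  expect_null(res$record$Contributors[[1]]$contributorNmae)
  expect_true(res$record$Contributors[[1]]$Creator)
})

test_that("template emission carries the full registry headers", {
  bundle <- write_tabular(empty_record(), REG)
  expect_setequal(names(bundle$tables), c(REG$categories, "Submission"))
  for (cat_ in REG$categories) {
    tb <- bundle$tables[[cat_]]
    expect_identical(names(tb),
                     registry_fields(REG)$name[
                       registry_fields(REG)$category == cat_],
                     label = cat_)
    expect_identical(nrow(tb), 0L)
  }
  expect_identical(ncol(bundle$tables$Specimen), 12L)
  expect_identical(ncol(bundle$tables$Image), 33L)
})

test_that("tabular round-trip is the identity over a seeded corpus", {
  corpus <- generate_corpus(30, generator_config(seed = 12), fault_rate = 0,
                            registry = REG)
  for (x in corpus) {
    res <- read_tabular(write_tabular(x$record, REG), REG)
    expect_identical(nrow(res$issues), 0L)
    expect_identical(record_bytes(res$record), record_bytes(x$record))
  }
})

test_that("CSV files round-trip byte-identically", {
  rec <- generate_valid_record(generator_config(seed = 55), REG)
  dir <- withr::local_tempdir()
  paths <- write_tabular_csv(rec, dir, REG)
  expect_length(paths, 8L)
  res <- read_tabular(read_tabular_csv(dir, REG), REG)
  expect_identical(record_bytes(res$record), record_bytes(rec))
  # determinism: a second write is byte-identical
  dir2 <- withr::local_tempdir()
  write_tabular_csv(rec, dir2, REG)
  for (p in paths) {
    q <- file.path(dir2, basename(p))
    expect_identical(readLines(p), readLines(q))
  }
})

test_that("the channel/landmark rows of the Image table interleave", {
  rec <- generate_valid_record(
    generator_config(seed = 14, n_channels = c(3L, 3L)), REG)
  rec$Image$Landmarks <- list(
    list(landmarkName = "bregma", landmarkX = 10, landmarkY = 20,
         landmarkZ = 30))
  bundle <- write_tabular(rec, REG)
  tb <- bundle$tables$Image
  expect_identical(nrow(tb), 3L)              # max(channels, landmarks)
  expect_identical(tb$Number, c("1", "2", "3"))
  expect_identical(tb$landmarkName, c("bregma", "", ""))
  expect_identical(tb$xAxis[2], "")           # scalars on row 1 only
  res <- read_tabular(bundle, REG)
  expect_length(res$record$Image$Channels, 3L)
  expect_length(res$record$Image$Landmarks, 1L)
  expect_identical(record_bytes(res$record), record_bytes(rec))
})
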