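valid_rec <- generate_valid_record(generator_config(seed = 101), REG)

test_that("a fully populated generated record validates clean", {
  rep <- validate_record(valid_rec, REG, "bil")
  expect_true(rep$valid)
  expect_identical(rep$counts[["error"]], 0L)
})

test_that("a missing required field yields exactly one issue at its path", {
  rec <- valid_rec
  rec$Dataset$Abstract <- NULL
  rep <- validate_record(rec, REG, "bil")
  hits <- rep$issues[rep$issues$code == "REQUIRED_MISSING", ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$path, "Dataset.Abstract")
  expect_false(rep$valid)
})

test_that("Personal contributors need identifier and scheme", {
  rec <- valid_rec
  rec$Contributors[[1]]$nameType <- "Personal"
  rec$Contributors[[1]]$nameIdentifier <- NULL
  rec$Contributors[[1]]$nameIdentifierScheme <- NULL
  rep <- validate_record(rec, REG, "bil")
  hits <- rep$issues[rep$issues$code == "COND_PERSONAL_ID", ]
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$path, c("Contributors[1].nameIdentifier",
                               "Contributors[1].nameIdentifierScheme"))
  # Organizational names do not trigger the conditional
  rec$Contributors[[1]]$nameType <- "Organizational"
  rep2 <- validate_record(rec, REG, "bil")
  expect_identical(sum(rep2$issues$code == "COND_PERSONAL_ID"), 0L)
})

test_that("the funders conditionality follows the declared-funding flag", {
  rec <- valid_rec
  rec$Funders <- list()
  rec$funding_declared <- TRUE
  rep <- validate_record(rec, REG, "bil")
  expect_true("COND_FUNDERS Funders" %in% issue_keys(rep))
  rec$funding_declared <- FALSE
  rep2 <- validate_record(rec, REG, "bil")
  expect_identical(sum(rep2$issues$code == "COND_FUNDERS"), 0L)
  expect_true(rep2$valid)
})

test_that("vocabulary violations distinguish casing from wrong values", {
  rec <- valid_rec
  rec$Specimen$Sex <- "female"   # casing only: advice, record stays valid
  rep <- validate_record(rec, REG, "bil")
  adv <- rep$issues[rep$issues$path == "Specimen.Sex", ]
  expect_identical(adv$severity, "advice")
  expect_true(rep$valid)
  rec$Specimen$Sex <- "Hermaphrodite"
  rep2 <- validate_record(rec, REG, "bil")
  bad <- rep2$issues[rep2$issues$path == "Specimen.Sex", ]
  expect_identical(bad$severity, "error")
  expect_false(rep2$valid)
})

test_that("numeric and syntax rules fire at their paths", {
  rec <- valid_rec
  rec$Image$stepSizeZ <- 0
  rec$Specimen$Age <- -4
  rec$Specimen$NCBITaxonomy <- "mus10090"
  rec$Image$Channels[[1]]$displayColor <- "260,0,0"
  rep <- validate_record(rec, REG, "bil")
  keys <- issue_keys(rep)
  expect_true("STEP_NONPOSITIVE Image.stepSizeZ" %in% keys)
  expect_true("AGE_NEGATIVE Specimen.Age" %in% keys)
  expect_true("TAXON_SYNTAX Specimen.NCBITaxonomy" %in% keys)
  expect_true("COLOR_FORMAT Image.Channels[1].displayColor" %in% keys)
})

test_that("advisory rules never invalidate a record", {
  rec <- valid_rec
  rec$Dataset$generalModality <- "levitation imaging"
  rec$Dataset$rightsIdentifier <- "home-grown license!!"
  rep <- validate_record(rec, REG, "bil")
  expect_true(rep$valid)
  sm <- summarize_report(rep)
  expect_identical(sm[["SUGGESTED_VALUE_MISS"]], 1L)
  expect_identical(sm[["SPDX_HINT"]], 1L)
})

test_that("profiles nest: lenient errors are a subset of bil errors", {
  for (seed in c(3, 8, 21)) {
    inj <- inject_errors(
      generate_valid_record(generator_config(seed = seed), REG),
      c("COND_FUNDERS", "COND_PERSONAL_ID", "VOCAB_VIOLATION"),
      seed = seed)
    err_keys <- function(p) {
      rep <- validate_record(inj$record, REG, p)
      issue_keys(rep)[rep$issues$severity == "error"]
    }
    bil <- err_keys("bil")
    lenient <- err_keys("lenient")
    expect_true(all(lenient %in% bil))
    expect_lt(length(lenient), length(bil))
  }
})

test_that("the doi_only profile checks only the DOI metadata subset", {
  rec <- valid_rec
  rec$Image$stepSizeX <- -1            # outside the DOI subset
  rec$Specimen$Sex <- "Hermaphrodite"  # outside the DOI subset
  rec$Dataset$Title <- NULL            # inside
  rep <- validate_record(rec, REG, "doi_only")
  expect_identical(unique(rep$issues$code), "REQUIRED_MISSING")
  expect_identical(rep$issues$path[rep$issues$severity == "error"],
                   "Dataset.Title")
})

test_that("reports are deterministic, ordered, and summable", {
  rec <- inject_errors(valid_rec,
                       c("AGE_NEGATIVE", "NO_CREATOR", "VOCAB_VIOLATION"),
                       seed = 4)$record
  rep1 <- validate_record(rec, REG, "bil")
  rep2 <- validate_record(rec, REG, "bil")
  expect_identical(rep1$issues, rep2$issues)
  sm <- summarize_report(rep1)
  expect_identical(sum(sm), nrow(rep1$issues))
  expect_identical(length(summarize_report(validate_record(valid_rec, REG))),
                   0L)
  # verdict is a pure function of the issues
  expect_identical(rep1$valid, rep1$counts[["error"]] == 0L)
})

test_that("adding a fault never decreases the issue count", {
  codes <- c("AGE_NEGATIVE", "VOCAB_VIOLATION", "STEP_NONPOSITIVE",
             "NO_CREATOR", "TAXON_SYNTAX")
  for (k in seq_len(length(codes) - 1L)) {
    a <- inject_errors(valid_rec, codes[seq_len(k)], seed = 2)$record
    b <- inject_errors(valid_rec, codes[seq_len(k + 1L)], seed = 2)$record
    expect_gte(nrow(validate_record(b, REG)$issues),
               nrow(validate_record(a, REG)$issues))
  }
})
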