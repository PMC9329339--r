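test_that("generated records validate clean for many seeds", {
  for (seed in seq(1, 97, by = 2)) {
    rec <- generate_valid_record(generator_config(seed = seed), REG)
    rep <- validate_record(rec, REG, "bil")
    expect_true(rep$valid, label = paste(
      "seed", seed, paste(utils::head(issue_keys(rep), 3), collapse = "; ")))
  }
})

test_that("generation is deterministic and respects forced ranges", {
  a <- generate_valid_record(generator_config(seed = 7), REG)
  b <- generate_valid_record(generator_config(seed = 7), REG)
  expect_identical(record_bytes(a), record_bytes(b))
  expect_false(identical(
    record_bytes(generate_valid_record(generator_config(seed = 8), REG)),
    record_bytes(a)))
  forced <- generate_valid_record(
    generator_config(seed = 3, n_channels = c(3L, 3L),
                     n_contributors = c(2L, 2L)), REG)
  expect_length(forced$Image$Channels, 3L)
  expect_length(forced$Contributors, 2L)
  # generator leaves the caller's RNG stream untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_valid_record(generator_config(9), REG))
  expect_identical(stats::runif(1), before)
})

test_that("config arguments are checked", {
  expect_error(generator_config(optional_fill_probability = 1.5))
  expect_error(generator_config(n_channels = c(4L, 1L)))
})

test_that("injection labels faults without touching the original", {
  rec <- generate_valid_record(generator_config(seed = 19), REG)
  before <- record_bytes(rec)
  inj <- inject_errors(rec, c("NO_CREATOR", "AGE_NEGATIVE"), seed = 5)
  expect_identical(record_bytes(rec), before)
  expect_identical(nrow(inj$labels), 2L)
  expect_false(any(vapply(inj$record$Contributors,
                          function(e) isTRUE(e$Creator), NA)))
  expect_lt(inj$record$Specimen$Age, 0)
  # empty code list is the identity
  none <- inject_errors(rec, character(0), seed = 5)
  expect_identical(record_bytes(none$record), before)
  expect_identical(nrow(none$labels), 0L)
  expect_error(inject_errors(rec, "NOT_A_CODE", seed = 1), "no corruption")
})

test_that("every catalog code is injectable and detected at its path", {
  rec <- generate_valid_record(generator_config(seed = 23), REG)
  for (code in names(fault_codes())) {
    inj <- inject_errors(rec, code, seed = 31)
    expect_identical(inj$labels$code, code)
    rep <- validate_record(inj$record, REG, "bil")
    expect_true(paste(code, inj$labels$path) %in% issue_keys(rep),
                label = code)
  }
})

test_that("corpora respect the fault rate and reproduce bytewise", {
  clean <- generate_corpus(20, generator_config(seed = 5), fault_rate = 0,
                           registry = REG)
  expect_true(all(vapply(clean, function(x)
    validate_record(x$record, REG)$valid, NA)))
  dirty <- generate_corpus(20, generator_config(seed = 5), fault_rate = 1,
                           registry = REG)
  expect_true(all(vapply(dirty, function(x) nrow(x$labels) >= 1L, NA)))
  again <- generate_corpus(20, generator_config(seed = 5), fault_rate = 1,
                           registry = REG)
  expect_identical(lapply(dirty, function(x) record_bytes(x$record)),
                   lapply(again, function(x) record_bytes(x$record)))
  expect_identical(lapply(dirty, `[[`, "labels"),
                   lapply(again, `[[`, "labels"))
})
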