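test_that("ORCID validation agrees with the closed-form checksum oracle", {
  set.seed(401)
  for (i in 1:200) {
    good <- make_orcid(valid = TRUE)
    bad <- make_orcid(valid = FALSE)
    expect_identical(nrow(check_identifier("ORCID", good)), 0L,
                     label = paste("valid", good))
    iss <- check_identifier("ORCID", bad)
    expect_identical(iss$code, "ID_SYNTAX", label = paste("broken", bad))
    expect_match(iss$message, "check digit")
  }
})

test_that("ISNI uses the same checksum with optional separators", {
  set.seed(402)
  d <- sample(0:9, 15, replace = TRUE)
  chk <- oracle_iso7064_check(d)
  isni <- paste0(paste(d, collapse = ""), chk)
  expect_identical(nrow(check_identifier("ISNI", isni)), 0L)
  spaced <- paste(substring(isni, c(1, 5, 9, 13), c(4, 8, 12, 16)),
                  collapse = " ")
  expect_identical(nrow(check_identifier("ISNI", spaced)), 0L)
  flipped <- paste0(substr(isni, 1, 15),
                    if (chk == "X") "0" else
                      as.character((as.integer(chk) + 1) %% 10))
  expect_identical(check_identifier("ISNI", flipped)$code, "ID_SYNTAX")
})

test_that("ROR, RRID and GRID follow their shape rules", {
  expect_identical(nrow(check_identifier("ROR", "05gvnxz63")), 0L)
  expect_identical(check_identifier("ROR", "15gvnxz63")$code, "ID_SYNTAX")
  expect_identical(check_identifier("ROR", "0abc")$code, "ID_SYNTAX")
  expect_identical(nrow(check_identifier("RRID", "RRID:SCR_016152")), 0L)
  expect_identical(check_identifier("RRID", "SCR_016152")$code,
                   "ID_SYNTAX")
  expect_identical(nrow(check_identifier("GRID", "grid.5335.0")), 0L)
  expect_identical(check_identifier("GRID", "5335.0")$code, "ID_SYNTAX")
})

test_that("identifiers tolerate a leading resolver URL", {
  expect_identical(
    nrow(check_identifier("ORCID",
                          paste0("https://orcid.org/", make_orcid()))), 0L)
  expect_identical(nrow(check_identifier("ROR",
                                         "https://ror.org/05gvnxz63")), 0L)
  expect_identical(
    nrow(check_identifier("GRID",
                          "https://www.grid.ac/institutes/grid.5335.0")),
    0L)
})

test_that("unknown schemes are a usage error", {
  expect_error(check_identifier("DOI", "10.1/abc"), "unknown identifier")
})
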