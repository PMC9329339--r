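# shared fixtures and independent oracles

REG <- build_default_registry()

# Independent ISO 7064 mod 11-2 oracle: closed-form power sum
# (the package uses a Horner-style running remainder; this evaluates
#  sum(d_i * 2^(n-i+1)) mod 11 directly, so the two can cross-check)
oracle_iso7064_check <- function(digits) {
  n <- length(digits)
  total <- sum(digits * 2^seq(n, 1)) %% 11
  r <- (12 - total) %% 11
  if (r == 10) "X" else as.character(r)
}

oracle_orcid_valid <- function(orcid) {
  chars <- strsplit(gsub("-", "", orcid), "")[[1]]
  d <- suppressWarnings(as.integer(chars[1:15]))
  if (anyNA(d)) return(FALSE)
  chars[16] == oracle_iso7064_check(d)
}

# random syntactically-shaped ORCID with a correct or flipped check digit
make_orcid <- function(valid = TRUE) {
  d <- sample(0:9, 15, replace = TRUE)
  chk <- oracle_iso7064_check(d)
  if (!valid)
    chk <- if (chk == "X") "3" else as.character((as.integer(chk) + 1) %% 10)
  g <- function(i) paste(d[i], collapse = "")
  paste0(g(1:4), "-", g(5:8), "-", g(9:12), "-", g(13:15), chk)
}

record_bytes <- function(rec) record_to_json(rec, REG)

issue_keys <- function(report) {
  paste(report$issues$code, report$issues$path)
}
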