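# Rule catalog. Order is part of the contract: reports are sorted by
# category order, then field order, then this catalog order, so identical
# records always yield identical reports.
MMS_RULES <- c(
  REQUIRED_MISSING = "error",
  COND_FUNDERS = "error",
  COND_PERSONAL_ID = "error",
  NO_CREATOR = "error",
  VOCAB_VIOLATION = "error",
  COLOR_FORMAT = "error",
  STEP_NONPOSITIVE = "error",
  AGE_NEGATIVE = "error",
  TAXON_SYNTAX = "error",
  ID_SYNTAX = "error",
  SPDX_HINT = "warning",
  SUGGESTED_VALUE_MISS = "advice",
  CARDINALITY = "error",
  CHANNEL_MISMATCH = "error"
)

#' The validation rule catalog
#'
#' @return Named character vector: rule code -> default severity.
#' @export
fault_codes <- function() MMS_RULES

is_missing_value <- function(v) {
  if (is.null(v) || length(v) == 0L) return(TRUE)
  if (length(v) == 1L && is.na(v)) return(TRUE)
  if (is.character(v) && length(v) == 1L && !nzchar(trimws(v))) return(TRUE)
  FALSE
}

# ---- identifier syntax ------------------------------------------------------

# ISO 7064 mod 11-2 check character over a vector of base digits
iso7064_mod11_2_check <- function(digits) {
  total <- 0L
  for (d in digits) total <- ((total + d) * 2L) %% 11L
  r <- (12L - total) %% 11L
  if (r == 10L) "X" else as.character(r)
}

strip_resolver <- function(value) {
  # tolerate a leading resolver URL such as https://orcid.org/ or
  # https://www.grid.ac/institutes/
  sub("^https?://[^[:space:]]*/", "", trimws(value))
}

#' Check an identifier against its scheme's syntax
#'
#' ORCID: four hyphenated quartets whose final character is the ISO 7064
#' mod 11-2 check digit over the first 15. ISNI: 16 digits (hyphens and
#' spaces optional) with the same checksum. ROR: `0` followed by 8
#' alphanumerics. RRID: `RRID:` prefix. GRID: `grid.` prefix. All schemes
#' tolerate a leading resolver URL.
#'
#' @param scheme One of GRID, ISNI, ORCID, ROR, RRID.
#' @param value Identifier text.
#' @param path Issue path to report (defaults to empty).
#' @return A tibble of 0 or 1 `ID_SYNTAX` issues (columns path, code,
#'   severity, message).
#' @examples
#' check_identifier("ORCID", "0000-0002-1825-0097")  # 0 rows: valid
#' check_identifier("RRID", "SCR_016152")            # missing prefix
#' @export
check_identifier <- function(scheme, value, path = "") {
  schemes <- c("GRID", "ISNI", "ORCID", "ROR", "RRID")
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% schemes)
    stop("unknown identifier scheme: ", paste(scheme, collapse = ","),
         call. = FALSE)
  bad <- function(msg) tibble::tibble(path = path, code = "ID_SYNTAX",
                                      severity = "error", message = msg)
  ok <- tibble::tibble(path = character(), code = character(),
                       severity = character(), message = character())
  v <- strip_resolver(as.character(value)[1L])
  if (scheme == "ORCID") {
    if (!grepl("^[0-9]{4}-[0-9]{4}-[0-9]{4}-[0-9]{3}[0-9X]$", v))
      return(bad(sprintf(
        "ORCID '%s' is not four hyphenated quartets of digits", v)))
    chars <- strsplit(gsub("-", "", v), "")[[1L]]
    expect <- iso7064_mod11_2_check(as.integer(chars[1:15]))
    if (chars[16] != expect)
      return(bad(sprintf(
        "ORCID '%s' fails its ISO 7064 mod 11-2 check digit (expected %s)",
        v, expect)))
  } else if (scheme == "ISNI") {
    digits <- gsub("[- ]", "", v)
    if (!grepl("^[0-9]{15}[0-9X]$", digits))
      return(bad(sprintf("ISNI '%s' is not 16 digits", v)))
    chars <- strsplit(digits, "")[[1L]]
    expect <- iso7064_mod11_2_check(as.integer(chars[1:15]))
    if (chars[16] != expect)
      return(bad(sprintf(
        "ISNI '%s' fails its ISO 7064 mod 11-2 check digit (expected %s)",
        v, expect)))
  } else if (scheme == "ROR") {
    if (!grepl("^0[a-zA-Z0-9]{8}$", v))
      return(bad(sprintf(
        "ROR '%s' is not '0' followed by 8 alphanumerics", v)))
  } else if (scheme == "RRID") {
    if (!grepl("^RRID:", v))
      return(bad(sprintf("RRID '%s' lacks the 'RRID:' prefix", v)))
  } else if (scheme == "GRID") {
    if (!grepl("^grid\\.", v))
      return(bad(sprintf("GRID '%s' lacks the 'grid.' prefix", v)))
  }
  ok
}

# ---- the validator ----------------------------------------------------------

#' Validate a metadata record against the standard
#'
#' Applies the full rule catalog (see [fault_codes()]) and returns a
#' machine-readable report. All problems are reported, never raised; a
#' field can collect several issues; ordering is deterministic (category,
#' then field, then rule-catalog order).
#'
#' Profiles: `"bil"` applies every rule; `"doi_only"` checks only the
#' DOI-supporting fields (plus creator and identifier rules), the subset
#' needed to mint a DOI; `"lenient"` downgrades the conditional-rule
#' errors (`COND_FUNDERS`, `COND_PERSONAL_ID`) to warnings.
#'
#' The Funders conditionality ("required when government-funded") has no
#' machine-readable trigger in the standard itself; this implementation
#' uses the record's explicit `funding_declared` flag (serialized as
#' top-level `fundingDeclared`, default `TRUE`).
#'
#' @param record An `mms_record`.
#' @param registry An `mms_registry`.
#' @param profile One of `"bil"`, `"doi_only"`, `"lenient"`.
#' @return An `mms_report`: list with `issues` (tibble: path, code,
#'   severity, message), `counts` (by severity), `valid` (TRUE iff zero
#'   error-severity issues) and `profile`.
#' @export
validate_record <- function(record, registry = build_default_registry(),
                            profile = c("bil", "lenient", "doi_only")) {
  stopifnot(inherits(record, "mms_record"))
  profile <- match.arg(profile)
  rules <- MMS_RULES
  if (profile == "lenient")
    rules[c("COND_FUNDERS", "COND_PERSONAL_ID")] <- "warning"

  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  emit <- function(cat_idx, entry_idx, field_idx, code, path, message) {
    acc$rows[[length(acc$rows) + 1L]] <-
      list(cat_idx = cat_idx, entry_idx = entry_idx, field_idx = field_idx,
           rule_idx = match(code, names(rules)), path = path, code = code,
           severity = unname(rules[[code]]), message = message)
  }
  cat_idx <- function(cat_) match(cat_, registry$categories)
  doi_only <- profile == "doi_only"

  # generic per-field checks over one block (scalars or one entry)
  check_fields <- function(rows, block, ci, ei, path_prefix,
                           required_code = "REQUIRED_MISSING",
                           require_all = FALSE) {
    for (k in seq_len(nrow(rows))) {
      row <- rows[k, ]
      if (doi_only && !row$doi_support) next
      fi <- match(row$name, registry$fields$name[
        registry$fields$category == row$category])
      path <- paste0(path_prefix, ".", row$name)
      v <- block[[row$name]]
      missing <- is_missing_value(v)
      needed <- row$requirement_level == "required" ||
        (require_all && row$requirement_level != "optional")
      if (missing && needed && row$condition %in% c("none",
                                                    "government_funded"))
        emit(ci, ei, fi, required_code, path,
             sprintf("required field %s is missing", row$name))
      if (missing) next
      if (length(v) > row$max_occurrences && row$scope == "record")
        emit(ci, ei, fi, "CARDINALITY", path,
             sprintf("%d values given where at most %d allowed",
                     length(v), row$max_occurrences))
      if (row$scope != "record" && is.atomic(v) && length(v) > 1L &&
          row$name != "displayColor")
        emit(ci, ei, fi, "CARDINALITY", path,
             "multiple values in a single entry field")
      # closed vocabularies (case-insensitive match canonicalizes with advice)
      voc <- row$vocabulary[[1L]]
      if (row$name == "Creator") {
        if (!is.logical(v) &&
            !(is.character(v) && tolower(v[1L]) %in% c("yes", "no")))
          emit(ci, ei, fi, "VOCAB_VIOLATION", path,
               sprintf("Creator must be Yes or No, got '%s'",
                       paste(v, collapse = ",")))
      } else if (length(voc) > 0L && is.character(v)) {
        for (one in v) {
          if (one %in% voc) next
          ili <- match(tolower(one), tolower(voc))
          if (!is.na(ili)) {
            acc$rows[[length(acc$rows) + 1L]] <- list(
              cat_idx = ci, entry_idx = ei, field_idx = fi,
              rule_idx = match("VOCAB_VIOLATION", names(rules)),
              path = path, code = "VOCAB_VIOLATION", severity = "advice",
              message = sprintf("'%s' matches '%s' up to casing", one,
                                voc[ili]))
          } else {
            emit(ci, ei, fi, "VOCAB_VIOLATION", path,
                 sprintf("'%s' is not an allowed value of %s (%s)", one,
                         row$name, paste(voc, collapse = "; ")))
          }
        }
      }
      # advisory suggested-value lists (free-text fields, never errors)
      sugg <- row$suggested_values[[1L]]
      if (!doi_only && length(sugg) > 0L && is.character(v) &&
          row$name != "rightsIdentifier" &&
          !tolower(v[1L]) %in% tolower(sugg))
        emit(ci, ei, fi, "SUGGESTED_VALUE_MISS", path,
             sprintf("'%s' is not among the suggested values for %s",
                     v[1L], row$name))
    }
  }

  ## Contributors --------------------------------------------------------
  ci <- cat_idx("Contributors")
  crows <- reg_rows(registry, "Contributors")
  if (length(record$Contributors) == 0L)
    emit(ci, 0L, 0L, "REQUIRED_MISSING", "Contributors",
         "at least one contributor entry is required")
  any_creator <- FALSE
  for (i in seq_along(record$Contributors)) {
    e <- record$Contributors[[i]]
    pp <- sprintf("Contributors[%d]", i)
    check_fields(crows, e, ci, i, pp)
    cr <- e$Creator
    if (isTRUE(cr) || (is.character(cr) && tolower(cr[1L]) == "yes"))
      any_creator <- TRUE
    # conditional: Personal names need an identifier and a scheme
    nt <- e$nameType
    if (!is_missing_value(nt) && tolower(nt[1L]) == "personal") {
      if (is_missing_value(e$nameIdentifier))
        emit(ci, i, match("nameIdentifier", crows$name), "COND_PERSONAL_ID",
             paste0(pp, ".nameIdentifier"),
             "nameIdentifier is required for Personal nameType")
      if (is_missing_value(e$nameIdentifierScheme))
        emit(ci, i, match("nameIdentifierScheme", crows$name),
             "COND_PERSONAL_ID", paste0(pp, ".nameIdentifierScheme"),
             "nameIdentifierScheme is required for Personal nameType")
    }
    check_id_pair(e$nameIdentifierScheme, e$nameIdentifier,
                  paste0(pp, ".nameIdentifier"), ci, i,
                  match("nameIdentifier", crows$name), emit)
    check_id_pair(e$affiliationIdentifierScheme, e$affiliationIdentifier,
                  paste0(pp, ".affiliationIdentifier"), ci, i,
                  match("affiliationIdentifier", crows$name), emit)
  }
  if (!any_creator)
    emit(ci, 0L, 0L, "NO_CREATOR", "Contributors",
         "no contributor is flagged as a creator; at least one is required")

  ## Funders (conditional on the government-funded profile) --------------
  ci <- cat_idx("Funders")
  frows <- reg_rows(registry, "Funders")
  declared <- isTRUE(record$funding_declared)
  if (declared && length(record$Funders) == 0L)
    emit(ci, 0L, 0L, "COND_FUNDERS", "Funders",
         "funding is declared but no funder entries are present")
  for (i in seq_along(record$Funders)) {
    e <- record$Funders[[i]]
    pp <- sprintf("Funders[%d]", i)
    if (declared) {
      for (k in seq_len(nrow(frows))) {
        if (is_missing_value(e[[frows$name[k]]]))
          emit(ci, i, k, "COND_FUNDERS", paste0(pp, ".", frows$name[k]),
               sprintf("%s is required when funding is declared",
                       frows$name[k]))
      }
    }
    check_fields(frows, e, ci, i, pp)
    check_id_pair(e$fundingReferenceIdentifierType,
                  e$fundingReferenceIdentifier,
                  paste0(pp, ".fundingReferenceIdentifier"), ci, i,
                  match("fundingReferenceIdentifier", frows$name), emit)
  }

  ## Dataset --------------------------------------------------------------
  ci <- cat_idx("Dataset")
  drows <- reg_rows(registry, "Dataset")
  check_fields(drows, record$Dataset, ci, 0L, "Dataset")
  ri <- record$Dataset$rightsIdentifier
  if (!is_missing_value(ri) &&
      !grepl("^[A-Za-z0-9][A-Za-z0-9.+-]*$", ri[1L]))
    emit(ci, 0L, match("rightsIdentifier", drows$name), "SPDX_HINT",
         "Dataset.rightsIdentifier",
         sprintf("'%s' does not look like an SPDX license token", ri[1L]))

  ## Image ----------------------------------------------------------------
  if (!doi_only) {
    ci <- cat_idx("Image")
    irows <- reg_rows(registry, "Image", "record")
    img <- record$Image
    check_fields(irows, img, ci, 0L, "Image")
    for (nm in c("stepSizeX", "stepSizeY", "stepSizeZ", "stepSizeT")) {
      v <- img[[nm]]
      if (!is_missing_value(v) && is.numeric(v) && any(v <= 0))
        emit(ci, 0L, match(nm, irows$name), "STEP_NONPOSITIVE",
             paste0("Image.", nm),
             sprintf("%s must be strictly positive, got %s", nm,
                     paste(v, collapse = ",")))
    }
    chrows <- reg_rows(registry, "Image", "channel")
    if (length(img$Channels) == 0L)
      emit(ci, 0L, 0L, "REQUIRED_MISSING", "Image.Channels",
           "at least one channel (with Number and displayColor) is required")
    for (i in seq_along(img$Channels)) {
      ch <- img$Channels[[i]]
      pp <- sprintf("Image.Channels[%d]", i)
      if (is_missing_value(ch$Number) || is_missing_value(ch$displayColor))
        emit(ci, i, 0L, "CHANNEL_MISMATCH", pp,
             "channel must carry both Number and displayColor")
      col <- ch$displayColor
      if (!is_missing_value(col)) {
        triplet <- if (is.numeric(col) && length(col) == 3L)
          as.integer(col) else parse_display_color(col)
        if (is.null(triplet) || any(triplet < 0L) || any(triplet > 255L))
          emit(ci, i, match("displayColor", chrows$name), "COLOR_FORMAT",
               paste0(pp, ".displayColor"),
               sprintf("displayColor '%s' is not an RGB triplet in 0-255",
                       format_display_color(col)))
      }
    }
  }

  ## Instrument -----------------------------------------------------------
  if (!doi_only) {
    ci <- cat_idx("Instrument")
    check_fields(reg_rows(registry, "Instrument"), record$Instrument, ci,
                 0L, "Instrument")
  }

  ## Publication ----------------------------------------------------------
  if (!doi_only) {
    ci <- cat_idx("Publication")
    prows <- reg_rows(registry, "Publication")
    for (i in seq_along(record$Publication))
      check_fields(prows, record$Publication[[i]], ci, i,
                   sprintf("Publication[%d]", i))
  }

  ## Specimen -------------------------------------------------------------
  if (!doi_only) {
    ci <- cat_idx("Specimen")
    srows <- reg_rows(registry, "Specimen")
    check_fields(srows, record$Specimen, ci, 0L, "Specimen")
    age <- record$Specimen$Age
    if (!is_missing_value(age) && is.numeric(age) && any(age < 0))
      emit(ci, 0L, match("Age", srows$name), "AGE_NEGATIVE", "Specimen.Age",
           sprintf("Age must be non-negative (or \"unknown\"), got %s",
                   paste(age, collapse = ",")))
    tax <- record$Specimen$NCBITaxonomy
    if (!is_missing_value(tax) && !grepl("^[0-9]+$", as.character(tax)[1L]))
      emit(ci, 0L, match("NCBITaxonomy", srows$name), "TAXON_SYNTAX",
           "Specimen.NCBITaxonomy",
           sprintf("NCBI taxonomy code '%s' must be all digits",
                   as.character(tax)[1L]))
  }

  build_report(acc$rows, profile)
}

# identifier (scheme, value) pair check used in three places
check_id_pair <- function(scheme, value, path, ci, ei, fi, emit) {
  if (is_missing_value(scheme) || is_missing_value(value)) return(invisible())
  schemes <- c("GRID", "ISNI", "ORCID", "ROR", "RRID")
  s <- as.character(scheme)[1L]
  # unknown schemes are a vocabulary problem, flagged elsewhere
  if (!s %in% schemes) return(invisible())
  iss <- check_identifier(s, as.character(value)[1L], path)
  if (nrow(iss) > 0L)
    emit(ci, ei, fi, "ID_SYNTAX", path, iss$message[1L])
  invisible()
}

build_report <- function(rows, profile) {
  if (length(rows) == 0L) {
    issues <- tibble::tibble(path = character(), code = character(),
                             severity = character(), message = character())
  } else {
    ord <- order(vapply(rows, `[[`, 0L, "cat_idx"),
                 vapply(rows, `[[`, 0L, "entry_idx"),
                 vapply(rows, `[[`, 0L, "field_idx"),
                 vapply(rows, `[[`, 0L, "rule_idx"))
    rows <- rows[ord]
    issues <- tibble::tibble(
      path = vapply(rows, `[[`, "", "path"),
      code = vapply(rows, `[[`, "", "code"),
      severity = vapply(rows, `[[`, "", "severity"),
      message = vapply(rows, `[[`, "", "message")
    )
  }
  counts <- vapply(c("error", "warning", "advice"),
                   function(s) sum(issues$severity == s), 0L)
  structure(list(issues = issues, counts = counts,
                 valid = counts[["error"]] == 0L, profile = profile),
            class = "mms_report")
}

#' Count issues per rule code
#'
#' @param report An `mms_report`.
#' @return Named integer vector, one element per rule code present;
#'   the sum equals the total number of issues.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "mms_report"))
  if (nrow(report$issues) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(report$issues$code)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.mms_report <- function(x, ...) {
  cat(sprintf("<mms_report> profile=%s verdict=%s (%d errors, %d warnings, %d advice)\n",
              x$profile, if (x$valid) "VALID" else "INVALID",
              x$counts[["error"]], x$counts[["warning"]],
              x$counts[["advice"]]))
  if (nrow(x$issues) > 0L) {
    show <- utils::head(x$issues, 20L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  [%s] %s %s: %s\n", show$severity[i], show$code[i],
                  show$path[i], show$message[i]))
    if (nrow(x$issues) > 20L)
      cat(sprintf("  ... and %d more\n", nrow(x$issues) - 20L))
  }
  invisible(x)
}
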