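# In-memory form of one dataset's metadata record (class `mms_record`):
#   $Contributors, $Funders, $Publication  lists of entries (named lists)
#   $Dataset, $Instrument, $Specimen       named lists of scalar values
#   $Image                                 named list of scalars plus
#                                          $Channels and $Landmarks entry lists
#   $funding_declared                      flag: the government-funded
#                                          profile applies to this record
# Value conventions: Creator is a logical flag (serialized "Yes"/"No");
# displayColor is an integer RGB triplet (serialized "R,G,B"); Age is a
# number or the sentinel string "unknown".

ENTRY_CATEGORIES <- c("Contributors", "Funders", "Publication")
SCALAR_CATEGORIES <- c("Dataset", "Instrument", "Specimen")

#' Create an empty metadata record
#'
#' @param funding_declared Whether the record declares government funding
#'   (which makes the Funders category required for submission).
#' @return An `mms_record` with all blocks empty.
#' @export
empty_record <- function(funding_declared = TRUE) {
  structure(
    list(Contributors = list(), Funders = list(),
         Dataset = list(),
         Image = list(Channels = list(), Landmarks = list()),
         Instrument = list(), Publication = list(), Specimen = list(),
         funding_declared = isTRUE(funding_declared)),
    class = "mms_record"
  )
}

# registry rows for one category/scope, in registry order
reg_rows <- function(registry, category, scope = NULL) {
  f <- registry$fields
  keep <- f$category == category
  if (!is.null(scope)) keep <- keep & f$scope %in% scope
  f[keep, ]
}

new_issues <- function() {
  tibble::tibble(path = character(), code = character(),
                 message = character())
}

add_issue <- function(issues, path, code, message) {
  tibble::add_row(issues, path = path, code = code, message = message)
}

# ---- display color dialects -------------------------------------------------

# accepts "255,0,0", "(255, 0, 0)", "[255,0,0]" and numeric triplets;
# returns an integer triplet or NULL if the text is not a triplet at all
parse_display_color <- function(raw) {
  if (is.numeric(raw) && length(raw) == 3L) return(as.integer(raw))
  if (is.list(raw) && length(raw) == 3L &&
      all(vapply(raw, is.numeric, NA))) return(as.integer(unlist(raw)))
  if (is.character(raw) && length(raw) == 1L) {
    txt <- gsub("[][()]", "", trimws(raw))
    parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1L]])
    if (length(parts) == 3L && all(grepl("^-?[0-9]+$", parts)))
      return(as.integer(parts))
  }
  NULL
}

format_display_color <- function(value) {
  if (is.numeric(value) && length(value) == 3L)
    paste(as.integer(value), collapse = ",")
  else value  # malformed values pass through untouched
}

# ---- scalar conversion ------------------------------------------------------

# convert one raw document value into the in-memory convention for `row`
# (one registry row); returns list(value=, issues=)
convert_value_in <- function(row, raw, path, issues) {
  # a JSON array where a scalar is expected: keep all values, flag it
  if (is.list(raw)) {
    if (all(vapply(raw, function(x) is.atomic(x) && length(x) == 1L, NA))) {
      raw <- unlist(raw, use.names = FALSE)
      if (length(raw) > 1L && row$scope == "record")
        issues <- add_issue(issues, path, "MULTIPLICITY",
                            sprintf("expected a single value, got %d",
                                    length(raw)))
    } else if (row$name != "displayColor") {
      issues <- add_issue(issues, path, "UNPARSEABLE",
                          "nested structure where a scalar was expected")
      return(list(value = raw, issues = issues))
    }
  }
  value <- raw
  if (row$name == "displayColor") {
    col <- parse_display_color(raw)
    value <- if (is.null(col)) {
      if (is.character(raw)) raw else
        paste(unlist(raw), collapse = ",")
    } else col
  } else if (row$name == "Creator") {
    if (is.logical(raw)) value <- raw
    else if (is.character(raw) && tolower(raw[1L]) %in% c("yes", "no"))
      value <- tolower(raw[1L]) == "yes"
    # anything else is kept verbatim for the validator to flag
  } else if (row$value_kind == "number") {
    if (is.character(raw)) {
      if (row$name == "Age" && tolower(trimws(raw[1L])) == "unknown") {
        value <- "unknown"
      } else {
        num <- suppressWarnings(as.numeric(raw))
        if (anyNA(num)) {
          issues <- add_issue(issues, path, "UNPARSEABLE",
                              sprintf("'%s' is not a number",
                                      paste(raw, collapse = ",")))
          value <- raw
        } else value <- num
      }
    } else value <- as.numeric(raw)
  } else if (is.atomic(raw)) {
    value <- as.character(raw)
  }
  list(value = value, issues = issues)
}

# serialize one in-memory value back to its document form
convert_value_out <- function(name, value) {
  if (name == "displayColor") return(format_display_color(value))
  if (name == "Creator" && is.logical(value))
    return(if (isTRUE(value)) "Yes" else "No")
  value
}

# ---- parsing ----------------------------------------------------------------

# parse one flat block (named list) against registry rows; returns
# list(block=, issues=)
parse_block <- function(rows, doc, path_prefix, issues) {
  block <- list()
  if (!is.list(doc) || is.null(names(doc)) || any(names(doc) == "")) {
    issues <- add_issue(issues, path_prefix, "MULTIPLICITY",
                        "expected an object of field values")
    return(list(block = block, issues = issues))
  }
  for (key in names(doc)) {
    hit <- which(rows$name == key)
    path <- paste0(path_prefix, ".", key)
    if (length(hit) == 0L) {
      issues <- add_issue(issues, path, "UNKNOWN_FIELD",
                          sprintf("unknown field '%s'", key))
      next
    }
    conv <- convert_value_in(rows[hit, ], doc[[key]], path, issues)
    issues <- conv$issues
    block[[key]] <- conv$value
  }
  list(block = block, issues = issues)
}

# parse a list of entries (array of objects)
parse_entries <- function(rows, doc, path_prefix, issues) {
  entries <- list()
  if (is.null(doc)) return(list(entries = entries, issues = issues))
  if (!is.list(doc)) {
    issues <- add_issue(issues, path_prefix, "MULTIPLICITY",
                        "expected a list of entries")
    return(list(entries = entries, issues = issues))
  }
  # a single object where an array was expected: wrap it, flag it
  if (!is.null(names(doc)) && any(names(doc) != "")) {
    issues <- add_issue(issues, path_prefix, "MULTIPLICITY",
                        "expected a list of entries, got a single object")
    doc <- list(doc)
  }
  for (i in seq_along(doc)) {
    res <- parse_block(rows, doc[[i]],
                       sprintf("%s[%d]", path_prefix, i), issues)
    issues <- res$issues
    entries[[i]] <- res$block
  }
  list(entries = entries, issues = issues)
}

#' Parse a tree-structured metadata document into a record
#'
#' Parsing is total: it always returns a record plus a (possibly empty)
#' list of parse issues. Unrecognized keys, wrong multiplicity and
#' unparseable scalars become issues (`UNKNOWN_FIELD`, `MULTIPLICITY`,
#' `UNPARSEABLE`), never silent drops and never errors. Rule conformance
#' (required fields, vocabularies, checksums) is the job of
#' [validate_record()], not of the parser.
#'
#' @param document A nested list keyed by category then field name, as
#'   produced by `jsonlite::fromJSON(txt, simplifyVector = FALSE)`.
#' @param registry An `mms_registry` (default: the built-in standard).
#' @return A list with elements `record` (an `mms_record`) and `issues`
#'   (a tibble with columns path, code, message).
#' @export
parse_record <- function(document, registry = build_default_registry()) {
  stopifnot(is.list(document))
  record <- empty_record()
  issues <- new_issues()
  known <- c(registry$categories, "fundingDeclared")
  for (key in names(document)) {
    if (!key %in% known) {
      issues <- add_issue(issues, key, "UNKNOWN_FIELD",
                          sprintf("unknown top-level key '%s'", key))
    }
  }
  if (!is.null(document$fundingDeclared))
    record$funding_declared <- isTRUE(document$fundingDeclared) ||
      identical(tolower(as.character(document$fundingDeclared)[1]), "true") ||
      identical(as.character(document$fundingDeclared)[1], "Yes")
  for (cat_ in ENTRY_CATEGORIES) {
    if (is.null(document[[cat_]])) next
    res <- parse_entries(reg_rows(registry, cat_), document[[cat_]],
                         cat_, issues)
    issues <- res$issues
    record[[cat_]] <- res$entries
  }
  for (cat_ in SCALAR_CATEGORIES) {
    if (is.null(document[[cat_]])) next
    res <- parse_block(reg_rows(registry, cat_), document[[cat_]],
                       cat_, issues)
    issues <- res$issues
    record[[cat_]] <- res$block
  }
  # Image: record-scoped scalars plus Channels/Landmarks entry lists
  img_doc <- document$Image
  if (!is.null(img_doc)) {
    if (!is.list(img_doc) || is.null(names(img_doc))) {
      issues <- add_issue(issues, "Image", "MULTIPLICITY",
                          "expected an object for the Image category")
    } else {
      scal <- img_doc[setdiff(names(img_doc), c("Channels", "Landmarks"))]
      res <- parse_block(reg_rows(registry, "Image", "record"), scal,
                         "Image", issues)
      issues <- res$issues
      record$Image <- res$block
      ch <- parse_entries(reg_rows(registry, "Image", "channel"),
                          img_doc$Channels, "Image.Channels", issues)
      issues <- ch$issues
      record$Image$Channels <- ch$entries
      lm <- parse_entries(reg_rows(registry, "Image", "landmark"),
                          img_doc$Landmarks, "Image.Landmarks", issues)
      issues <- lm$issues
      record$Image$Landmarks <- lm$entries
    }
  }
  list(record = record, issues = issues)
}

# ---- serialization ----------------------------------------------------------

serialize_block <- function(rows, block) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    nm <- rows$name[i]
    if (!is.null(block[[nm]]))
      out[[nm]] <- convert_value_out(nm, block[[nm]])
  }
  # unknown keys never reach the record via parse_record, but records
  # built in code may carry them; keep them after the registry fields
  extra <- setdiff(names(block), c(rows$name, "Channels", "Landmarks"))
  for (nm in extra) out[[nm]] <- block[[nm]]
  out
}

serialize_entries <- function(rows, entries) {
  lapply(entries, function(e) serialize_block(rows, e))
}

#' Serialize a record into its canonical document form
#'
#' Produces the tree-structured document with deterministic key ordering:
#' categories in the standard's order, fields in registry order within
#' each block, repeated entries as ordered lists, display colors as
#' `"R,G,B"` text and Creator flags as `"Yes"`/`"No"`. Two serializations
#' of the same record are identical; empty optional blocks are omitted.
#'
#' @param record An `mms_record` (it may still violate 3D-MMS rules).
#' @param registry An `mms_registry`.
#' @return A nested list ready for JSON rendering.
#' @seealso [record_to_json()] for the byte-deterministic JSON text.
#' @export
serialize_record <- function(record,
                             registry = build_default_registry()) {
  stopifnot(inherits(record, "mms_record"))
  doc <- list(fundingDeclared = isTRUE(record$funding_declared))
  for (cat_ in registry$categories) {
    if (cat_ %in% ENTRY_CATEGORIES) {
      if (length(record[[cat_]]) > 0L)
        doc[[cat_]] <- serialize_entries(reg_rows(registry, cat_),
                                         record[[cat_]])
    } else if (cat_ == "Image") {
      img <- serialize_block(reg_rows(registry, "Image", "record"),
                             record$Image)
      if (length(record$Image$Channels) > 0L)
        img$Channels <- serialize_entries(
          reg_rows(registry, "Image", "channel"), record$Image$Channels)
      if (length(record$Image$Landmarks) > 0L)
        img$Landmarks <- serialize_entries(
          reg_rows(registry, "Image", "landmark"), record$Image$Landmarks)
      if (length(img) > 0L) doc$Image <- img
    } else {
      blk <- serialize_block(reg_rows(registry, cat_), record[[cat_]])
      if (length(blk) > 0L) doc[[cat_]] <- blk
    }
  }
  doc
}

#' Render a record as canonical JSON text
#'
#' @param record An `mms_record`.
#' @param registry An `mms_registry`.
#' @param pretty Pretty-print the JSON.
#' @return A single JSON string; byte-identical for identical records.
#' @export
record_to_json <- function(record, registry = build_default_registry(),
                           pretty = TRUE) {
  doc <- serialize_record(record, registry)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty,
                                digits = NA, na = "null"))
}

#' Read a metadata record from a JSON file or string
#'
#' @param input Path to a JSON file, or a JSON string.
#' @param registry An `mms_registry`.
#' @return As [parse_record()]: list of `record` and `issues`.
#' @export
read_record_json <- function(input,
                             registry = build_default_registry()) {
  txt <- if (length(input) == 1L && file.exists(input))
    paste(readLines(input, warn = FALSE), collapse = "\n") else input
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  parse_record(doc, registry)
}

#' Write a record to a JSON file
#'
#' @param record An `mms_record`.
#' @param path Output file path.
#' @param registry An `mms_registry`.
#' @return `path`, invisibly.
#' @export
write_record_json <- function(record, path,
                              registry = build_default_registry()) {
  writeLines(record_to_json(record, registry), path, useBytes = TRUE)
  invisible(path)
}

# ---- shared Contributors/Funders attachment ---------------------------------

#' Attach shared Contributors/Funders metadata to a series of records
#'
#' Appends the shared entries to each record's corresponding list, so a
#' group depositing many datasets over time can declare its people and
#' grants once. An entry already present in a record (all fields equal)
#' is not appended twice, which makes the operation idempotent.
#'
#' @param records A list of `mms_record` objects.
#' @param shared A partial record: a list with elements `Contributors`
#'   and/or `Funders` only (each a list of entries), or an `mms_record`
#'   whose other blocks are empty.
#' @return A list of new `mms_record` objects.
#' @export
attach_common_metadata <- function(records, shared) {
  stopifnot(is.list(records))
  if (inherits(shared, "mms_record")) {
    other <- c(SCALAR_CATEGORIES, "Publication")
    busy <- vapply(other, function(cat_) length(shared[[cat_]]) > 0L, NA)
    img <- shared$Image
    img_busy <- length(setdiff(names(img), c("Channels", "Landmarks"))) > 0L ||
      length(img$Channels) > 0L || length(img$Landmarks) > 0L
    if (any(busy) || img_busy)
      stop("shared metadata may contain only Contributors and Funders",
           call. = FALSE)
    shared <- list(Contributors = shared$Contributors,
                   Funders = shared$Funders)
  }
  extra <- setdiff(names(shared), c("Contributors", "Funders"))
  if (length(extra) > 0L)
    stop("shared metadata may contain only Contributors and Funders, got: ",
         paste(extra, collapse = ", "), call. = FALSE)
  lapply(records, function(rec) {
    stopifnot(inherits(rec, "mms_record"))
    for (cat_ in c("Contributors", "Funders")) {
      for (entry in shared[[cat_]]) {
        dup <- any(vapply(rec[[cat_]], identical, NA, y = entry))
        if (!dup) rec[[cat_]] <- c(rec[[cat_]], list(entry))
      }
    }
    rec
  })
}

#' @export
print.mms_record <- function(x, ...) {
  n_img <- length(setdiff(names(x$Image), c("Channels", "Landmarks")))
  cat("<mms_record>",
      sprintf("%d contributor(s), %d funder(s), %d publication(s);",
              length(x$Contributors), length(x$Funders),
              length(x$Publication)),
      sprintf("%d channel(s); funding declared: %s\n",
              length(x$Image$Channels),
              if (isTRUE(x$funding_declared)) "yes" else "no"))
  if (!is.null(x$Dataset$Title))
    cat("  Title:", format_scalar(x$Dataset$Title), "\n")
  cat(sprintf("  populated: Dataset %d, Image %d(+%d ch), Instrument %d, Specimen %d fields\n",
              length(x$Dataset), n_img, length(x$Image$Channels),
              length(x$Instrument), length(x$Specimen)))
  invisible(x)
}

format_scalar <- function(x) paste(as.character(x), collapse = " / ")
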