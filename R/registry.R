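#' Build the built-in 3D-MMS v1.0.0 registry
#'
#' Constructs the versioned schema registry holding all 91 field
#' definitions of the 3D Microscopy Metadata Standards, grouped into the
#' seven categories in the standard's order (Contributors, Funders,
#' Dataset, Image, Instrument, Publication, Specimen). The registry is
#' self-checked at build time: if any structural invariant of the standard
#' is violated (category count and order, per-category field totals,
#' DOI-support flags, vocabulary consistency) the build fails loudly
#' rather than returning a partial registry.
#'
#' @return An object of class `mms_registry`: a list with elements
#'   `version` (semantic version string), `categories` (character vector
#'   of the seven category names in order) and `fields` (a tibble with
#'   one row per field; list-columns `vocabulary` and `suggested_values`).
#' @examples
#' reg <- build_default_registry()
#' count_fields(reg)                     # 91
#' get_field(reg, "Sex")$vocabulary[[1]] # Male, Female, Unknown
#' @export
build_default_registry <- function() {
  flds <- mms_field_list()
  fields <- tibble::tibble(
    name = vapply(flds, `[[`, "", "name"),
    category = vapply(flds, `[[`, "", "category"),
    definition = vapply(flds, `[[`, "", "definition"),
    value_kind = vapply(flds, `[[`, "", "value_kind"),
    vocabulary = lapply(flds, `[[`, "vocabulary"),
    suggested_values = lapply(flds, `[[`, "suggested_values"),
    requirement_level = vapply(flds, `[[`, "", "requirement_level"),
    condition = vapply(flds, `[[`, "", "condition"),
    condition_text = vapply(flds, `[[`, "", "condition_text"),
    scope = vapply(flds, `[[`, "", "scope"),
    repeatable = vapply(flds, `[[`, NA, "repeatable"),
    max_occurrences = vapply(flds, `[[`, 0, "max_occurrences"),
    doi_support = vapply(flds, `[[`, NA, "doi_support"),
    datacite_property = vapply(flds, `[[`, "", "datacite_property"),
    ome_term = vapply(flds, `[[`, "", "ome_term"),
    units = vapply(flds, `[[`, "", "units"),
    provenance = vapply(flds, `[[`, "", "provenance")
  )
  reg <- structure(
    list(version = "1.0.0", categories = mms_categories(), fields = fields),
    class = "mms_registry"
  )
  assert_registry_invariants(reg)
  reg
}

# fail loudly at build time if the encoded standard is inconsistent
assert_registry_invariants <- function(reg) {
  f <- reg$fields
  fail <- function(msg) stop("registry invariant violated: ", msg,
                             call. = FALSE)
  if (!identical(reg$categories, mms_categories()) ||
      length(reg$categories) != 7L)
    fail("seven categories in the standard's order")
  if (nrow(f) != 91L) fail(sprintf("91 fields expected, got %d", nrow(f)))
  expected_totals <- c(Contributors = 9L, Funders = 5L, Dataset = 15L,
                       Image = 33L, Instrument = 12L, Publication = 5L,
                       Specimen = 12L)
  got <- table(factor(f$category, levels = reg$categories))
  for (cat in reg$categories) {
    if (got[[cat]] != expected_totals[[cat]])
      fail(sprintf("%s must hold %d fields, got %d", cat,
                   expected_totals[[cat]], got[[cat]]))
    if (anyDuplicated(f$name[f$category == cat]))
      fail(sprintf("duplicate field names in %s", cat))
  }
  if (any(f$requirement_level[f$category == "Publication"] != "optional"))
    fail("all Publication fields are optional")
  if (!all(f$doi_support[f$category %in% c("Contributors", "Funders")]))
    fail("all Contributors and Funders fields support DOI assignment")
  has_vocab <- vapply(f$vocabulary, length, 0L) > 0L
  if (!identical(has_vocab, f$value_kind == "vocabulary"))
    fail("vocabulary non-empty iff value_kind is 'vocabulary'")
  if (any((f$requirement_level == "conditional") != (f$condition != "none")))
    fail("conditional fields carry a condition; others carry none")
  if (any(f$doi_support & is.na(f$datacite_property)))
    fail("DOI-supporting fields carry a DataCite property")
  if (!grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", reg$version))
    fail("version follows major.minor.patch")
  invisible(reg)
}

#' Field table of a registry
#'
#' @param registry An `mms_registry`.
#' @return The registry's field tibble (one row per field).
#' @export
registry_fields <- function(registry) {
  stopifnot(inherits(registry, "mms_registry"))
  registry$fields
}

#' Registry version
#'
#' @param registry An `mms_registry`.
#' @return Semantic version string, e.g. `"1.0.0"`.
#' @export
registry_version <- function(registry) {
  stopifnot(inherits(registry, "mms_registry"))
  registry$version
}

#' Count fields matching filters
#'
#' Counts the registry fields matching the conjunction of the supplied
#' filters. `requirement = "bil_required"` is shorthand for
#' "not optional", i.e. the set of fields a repository submission must
#' carry (unconditionally required fields plus fields required under a
#' condition).
#'
#' @param registry An `mms_registry`.
#' @param category Optional category name.
#' @param requirement Optional filter: one of `"required"`,
#'   `"conditional"`, `"optional"`, `"bil_required"`.
#' @param doi_support Optional logical filter on DOI support.
#' @return Integer count.
#' @examples
#' reg <- build_default_registry()
#' count_fields(reg)                                     # 91
#' count_fields(reg, requirement = "bil_required",
#'              doi_support = TRUE)                      # 19
#' @export
count_fields <- function(registry, category = NULL, requirement = NULL,
                         doi_support = NULL) {
  stopifnot(inherits(registry, "mms_registry"))
  f <- registry$fields
  keep <- rep(TRUE, nrow(f))
  if (!is.null(category)) {
    if (!category %in% registry$categories)
      stop("unknown category: ", category, call. = FALSE)
    keep <- keep & f$category == category
  }
  if (!is.null(requirement)) {
    ok <- c("required", "conditional", "optional", "bil_required")
    if (!requirement %in% ok)
      stop("unknown requirement filter: ", requirement, call. = FALSE)
    keep <- keep & if (requirement == "bil_required")
      f$requirement_level != "optional"
    else f$requirement_level == requirement
  }
  if (!is.null(doi_support)) {
    stopifnot(is.logical(doi_support), length(doi_support) == 1L)
    keep <- keep & f$doi_support == doi_support
  }
  sum(keep)
}

#' Look up one field definition
#'
#' Lookup is case-sensitive on the printed spelling, with a
#' case-insensitive fallback that emits a warning. Unknown names produce
#' an error listing near-miss suggestions; a name occurring in more than
#' one category must be disambiguated with `category`.
#'
#' @param registry An `mms_registry`.
#' @param name Field name.
#' @param category Optional category to disambiguate.
#' @return One-row field tibble (list-columns `vocabulary`,
#'   `suggested_values`).
#' @export
get_field <- function(registry, name, category = NULL) {
  stopifnot(inherits(registry, "mms_registry"), is.character(name),
            length(name) == 1L)
  f <- registry$fields
  if (!is.null(category)) {
    if (!category %in% registry$categories)
      stop("unknown category: ", category, call. = FALSE)
    f <- f[f$category == category, ]
  }
  hit <- which(f$name == name)
  if (length(hit) == 0L) {
    hit <- which(tolower(f$name) == tolower(name))
    if (length(hit) >= 1L)
      warning(sprintf("field matched case-insensitively: '%s' is spelled '%s'",
                      name, f$name[hit[1L]]), call. = FALSE)
  }
  if (length(hit) == 0L) {
    d <- utils::adist(tolower(name), tolower(f$name))[1L, ]
    sugg <- unique(f$name[order(d)][seq_len(min(3L, nrow(f)))])
    stop(sprintf("no field named '%s'%s; did you mean: %s", name,
                 if (is.null(category)) "" else paste0(" in ", category),
                 paste(sugg, collapse = ", ")), call. = FALSE)
  }
  if (length(hit) > 1L)
    stop(sprintf("field name '%s' occurs in categories %s; pass `category`",
                 name, paste(unique(f$category[hit]), collapse = ", ")),
         call. = FALSE)
  f[hit, ]
}

#' Export the registry as a machine-readable JSON dump
#'
#' Writes (or returns) a JSON document containing the registry version and
#' every field definition, suitable for documentation generation and
#' external audits.
#'
#' @param registry An `mms_registry`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
export_registry_json <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "mms_registry"))
  f <- registry$fields
  dump <- list(
    standard = "3D-MMS",
    version = registry$version,
    categories = registry$categories,
    fields = lapply(seq_len(nrow(f)), function(i) {
      row <- as.list(f[i, ])
      row$vocabulary <- f$vocabulary[[i]]
      row$suggested_values <- f$suggested_values[[i]]
      row$max_occurrences <- if (is.finite(row$max_occurrences))
        row$max_occurrences else "unbounded"
      row[c("name", "category", "definition", "value_kind", "vocabulary",
            "suggested_values", "requirement_level", "condition",
            "condition_text", "scope", "repeatable", "max_occurrences",
            "doi_support", "datacite_property", "ome_term", "units",
            "provenance")]
    })
  )
  txt <- jsonlite::toJSON(dump, auto_unbox = TRUE, pretty = TRUE,
                          digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @export
print.mms_registry <- function(x, ...) {
  f <- x$fields
  cat(sprintf("<mms_registry> 3D-MMS v%s: %d fields in %d categories\n",
              x$version, nrow(f), length(x$categories)))
  for (cat_ in x$categories) {
    sub <- f[f$category == cat_, ]
    cat(sprintf("  %-12s %2d fields (%d required for submission, %d DOI)\n",
                cat_, nrow(sub), sum(sub$requirement_level != "optional"),
                sum(sub$doi_support)))
  }
  invisible(x)
}
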