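# JSON-Schema (draft 2020-12) emission from the registry, and a generic
# evaluator for the dialect subset the emitted schemas use. The evaluator
# is deliberately independent of both the emitter and the rule validator:
# it interprets any schema document of the supported subset, so it can
# serve as a second engine when cross-checking records against the
# emitted schemas.

SCHEMA_DIALECT <- "https://json-schema.org/draft/2020-12/schema"

# property subschema for one registry field
field_prop_schema <- function(row) {
  desc <- row$definition
  if (row$name == "displayColor")
    return(list(type = "string",
                pattern = "^[0-9]{1,3},[0-9]{1,3},[0-9]{1,3}$",
                description = desc))
  if (row$name == "Creator")
    return(list(type = "string", enum = c("Yes", "No"),
                description = desc))
  if (row$name == "Age")
    return(list(anyOf = list(list(type = "number", minimum = 0),
                             list(const = "unknown")),
                description = desc))
  if (row$name %in% c("stepSizeX", "stepSizeY", "stepSizeZ", "stepSizeT"))
    return(list(type = "number", exclusiveMinimum = 0,
                description = desc))
  if (row$name == "NCBITaxonomy")
    return(list(type = "string", pattern = "^[0-9]+$",
                description = desc))
  voc <- row$vocabulary[[1L]]
  if (length(voc) > 0L)
    return(list(type = "string", enum = voc, description = desc))
  if (row$value_kind == "number")
    return(list(type = "number", description = desc))
  list(type = "string", description = desc)
}

properties_of <- function(rows) {
  props <- lapply(seq_len(nrow(rows)), function(i) field_prop_schema(rows[i, ]))
  names(props) <- rows$name
  props
}

# array-of-entries schema for Contributors / Funders / Publication
entry_array_schema <- function(registry, category, require_entries = TRUE) {
  rows <- reg_rows(registry, category)
  required <- rows$name[rows$requirement_level == "required"]
  item <- list(type = "object", properties = properties_of(rows),
               additionalProperties = FALSE)
  if (category == "Funders" && require_entries)
    required <- rows$name  # standalone schema: the government-funded case
  if (length(required) > 0L) item$required <- as.list(required)
  if (category == "Contributors") {
    # Personal names must carry an identifier and its scheme
    item$allOf <- list(list(
      `if` = list(properties = list(nameType = list(const = "Personal")),
                  required = list("nameType")),
      then = list(required = list("nameIdentifier", "nameIdentifierScheme"))
    ))
  }
  sch <- list(type = "array", items = item)
  if (category == "Contributors") {
    sch$minItems <- 1L
    # at least one creator
    sch$contains <- list(properties = list(Creator = list(const = "Yes")),
                         required = list("Creator"))
  }
  sch
}

scalar_block_schema <- function(registry, category) {
  rows <- reg_rows(registry, category)
  required <- rows$name[rows$requirement_level == "required"]
  sch <- list(type = "object", properties = properties_of(rows),
              additionalProperties = FALSE)
  if (length(required) > 0L) sch$required <- as.list(required)
  sch
}

image_schema <- function(registry) {
  rows <- reg_rows(registry, "Image", "record")
  ch_rows <- reg_rows(registry, "Image", "channel")
  lm_rows <- reg_rows(registry, "Image", "landmark")
  props <- properties_of(rows)
  props$Channels <- list(
    type = "array", minItems = 1L,
    items = list(type = "object", properties = properties_of(ch_rows),
                 required = list("Number", "displayColor"),
                 additionalProperties = FALSE))
  props$Landmarks <- list(
    type = "array",
    items = list(type = "object", properties = properties_of(lm_rows),
                 additionalProperties = FALSE))
  list(type = "object", properties = props,
       required = as.list(c(rows$name[rows$requirement_level == "required"],
                            "Channels")),
       additionalProperties = FALSE)
}

category_schema_body <- function(registry, category,
                                 require_entries = TRUE) {
  if (category %in% ENTRY_CATEGORIES)
    entry_array_schema(registry, category, require_entries)
  else if (category == "Image") image_schema(registry)
  else scalar_block_schema(registry, category)
}

schema_file_name <- function(category) {
  if (category == "all") "record_schema.json"
  else paste0(tolower(category), "_schema.json")
}

#' Emit JSON-Schema documents from the registry
#'
#' Produces draft 2020-12 JSON Schemas: one per category, and a combined
#' record schema (`scope = "all"`) that composes the seven category
#' schemas by reference under `$defs`. Vocabulary fields become `enum`s,
#' unconditionally required fields become `required` lists, repeatable
#' groups become array typing, and the standard's conditional
#' requirements (Personal names needing identifiers; Funders required
#' when funding is declared) are expressed as `if`/`then` conditionals.
#' Emission is deterministic: identical registries produce byte-identical
#' documents.
#'
#' @param registry An `mms_registry`.
#' @param scope One category name, or `"all"` for the combined schema
#'   plus all seven category schemas.
#' @return For a category: the schema as a nested list. For `"all"`: a
#'   named list of eight schemas keyed by output file name
#'   (`record_schema.json` plus `<category>_schema.json`).
#' @export
emit_json_schema <- function(registry, scope = "all") {
  stopifnot(inherits(registry, "mms_registry"))
  if (!scope %in% c("all", registry$categories))
    stop("scope must be 'all' or one of: ",
         paste(registry$categories, collapse = ", "), call. = FALSE)
  header <- function(id, title) {
    list(`$schema` = SCHEMA_DIALECT, `$id` = id,
         title = title,
         description = sprintf(
           "3D Microscopy Metadata Standards (3D-MMS) v%s",
           registry$version))
  }
  one <- function(cat_) {
    c(header(schema_file_name(cat_), paste("3D-MMS", cat_, "category")),
      category_schema_body(registry, cat_))
  }
  if (scope != "all") return(one(scope))

  defs <- lapply(registry$categories, category_schema_body,
                 registry = registry, require_entries = FALSE)
  names(defs) <- registry$categories
  frows <- reg_rows(registry, "Funders")
  combined <- c(
    header("record_schema.json", "3D-MMS metadata record"),
    list(
      type = "object",
      `$defs` = defs,
      properties = c(
        list(fundingDeclared = list(
          type = "boolean",
          description = "Whether the government-funded profile applies (makes the Funders category required).")),
        stats::setNames(lapply(registry$categories, function(cat_)
          list(`$ref` = paste0("#/$defs/", cat_))), registry$categories)
      ),
      required = as.list(c("Contributors", "Dataset", "Image",
                           "Instrument", "Specimen")),
      additionalProperties = FALSE,
      allOf = list(list(
        `if` = list(properties = list(fundingDeclared = list(const = TRUE)),
                    required = list("fundingDeclared")),
        then = list(
          required = list("Funders"),
          properties = list(Funders = list(
            type = "array", minItems = 1L,
            items = list(required = as.list(frows$name)))))
      ))
    )
  )
  out <- c(list(combined), lapply(registry$categories, one))
  names(out) <- c("record_schema.json",
                  vapply(registry$categories, schema_file_name, ""))
  out
}

#' Write the emitted JSON-Schema files to a directory
#'
#' Writes `record_schema.json` plus one `<category>_schema.json` per
#' category (lower-case file names).
#'
#' @param registry An `mms_registry`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the eight file paths, invisibly.
#' @export
write_schema_files <- function(registry, dir) {
  schemas <- emit_json_schema(registry, "all")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(schemas)) {
    path <- file.path(dir, nm)
    writeLines(schema_to_json(schemas[[nm]]), path, useBytes = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Render a schema list as JSON text
#'
#' @param schema A schema as returned by [emit_json_schema()].
#' @return JSON text.
#' @export
schema_to_json <- function(schema) {
  as.character(jsonlite::toJSON(schema, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"))
}

# ---- generic schema evaluator ----------------------------------------------

# JSON value classification for parsed documents
# (named lists are objects, unnamed lists are arrays)
json_type_of <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms) && length(x) > 0L && all(nzchar(nms))) return("object")
    return("array")
  }
  if (is.logical(x)) return("boolean")
  if (is.numeric(x)) return("number")
  if (is.character(x)) return("string")
  "unknown"
}

json_equal <- function(a, b) {
  isTRUE(all.equal(a, b, check.attributes = FALSE)) ||
    identical(as.character(a), as.character(b))
}

#' Validate a parsed JSON document against a JSON Schema
#'
#' A self-contained evaluator for the JSON-Schema subset used by the
#' emitted 3D-MMS schemas: `type`, `enum`, `const`, `pattern`,
#' `required`, `properties`, `additionalProperties`, `items`,
#' `minItems`, `maxItems`, `contains`, `allOf`, `anyOf`, `if`/`then`/
#' `else`, `minimum`, `exclusiveMinimum`, `$ref` into `$defs`. It
#' interprets the schema document generically and shares no code with
#' [emit_json_schema()] or [validate_record()], so it can serve as an
#' independent cross-check of both.
#'
#' @param document A parsed JSON value (nested list, as from
#'   `jsonlite::fromJSON(txt, simplifyVector = FALSE)`), e.g. a
#'   serialized record.
#' @param schema A schema as a nested list (emitted, or read from file).
#' @return List with `valid` (flag) and `errors` (character vector of
#'   "path: problem" messages).
#' @export
validate_against_schema <- function(document, schema) {
  errors <- schema_eval(document, schema, schema, "$")
  list(valid = length(errors) == 0L, errors = errors)
}

schema_resolve_ref <- function(ref, root) {
  if (!is.character(ref) || !startsWith(ref, "#/"))
    stop("unsupported $ref: ", ref, call. = FALSE)
  node <- root
  for (part in strsplit(sub("^#/", "", ref), "/", fixed = TRUE)[[1L]]) {
    part <- gsub("~1", "/", gsub("~0", "~", part, fixed = TRUE),
                 fixed = TRUE)
    node <- node[[part]]
    if (is.null(node)) stop("unresolvable $ref: ", ref, call. = FALSE)
  }
  node
}

schema_eval <- function(x, schema, root, path) {
  if (isTRUE(schema)) return(character(0))
  if (isFALSE(schema)) return(paste0(path, ": schema forbids any value"))
  errs <- character(0)
  say <- function(msg) errs <<- c(errs, paste0(path, ": ", msg))

  if (!is.null(schema$`$ref`))
    return(c(errs, schema_eval(x, schema_resolve_ref(schema$`$ref`, root),
                               root, path)))
  tp <- json_type_of(x)
  if (!is.null(schema$type)) {
    want <- unlist(schema$type)
    ok <- tp %in% want ||
      (tp == "number" && "integer" %in% want &&
         isTRUE(all.equal(x, round(x)))) ||
      # a length-0 list satisfies either container type
      (is.list(x) && length(x) == 0L && any(c("array", "object") %in% want))
    if (!ok) say(sprintf("expected type %s, got %s",
                         paste(want, collapse = "|"), tp))
  }
  if (!is.null(schema$const) && !json_equal(x, schema$const))
    say(sprintf("value does not equal the required constant '%s'",
                paste(as.character(schema$const), collapse = ",")))
  if (!is.null(schema$enum)) {
    vals <- schema$enum
    if (!is.list(vals)) vals <- as.list(vals)
    if (!any(vapply(vals, json_equal, NA, a = x)))
      say(sprintf("'%s' is not one of the allowed values",
                  paste(as.character(x), collapse = ",")))
  }
  if (!is.null(schema$pattern) && tp == "string" &&
      !grepl(schema$pattern, x, perl = TRUE))
    say(sprintf("'%s' does not match pattern %s", x, schema$pattern))
  if (tp == "number") {
    if (!is.null(schema$minimum) && x < schema$minimum)
      say(sprintf("%s is below minimum %s", x, schema$minimum))
    if (!is.null(schema$exclusiveMinimum) && x <= schema$exclusiveMinimum)
      say(sprintf("%s is not above %s", x, schema$exclusiveMinimum))
    if (!is.null(schema$maximum) && x > schema$maximum)
      say(sprintf("%s is above maximum %s", x, schema$maximum))
  }
  if (tp == "object" || (is.list(x) && length(x) == 0L)) {
    req <- unlist(schema$required)
    for (r in req) if (is.null(x[[r]]))
      say(sprintf("required member '%s' is missing", r))
    props <- schema$properties
    for (nm in names(x)) {
      sub <- props[[nm]]
      if (!is.null(sub)) {
        errs <- c(errs, schema_eval(x[[nm]], sub, root,
                                    paste0(path, ".", nm)))
      } else if (isFALSE(schema$additionalProperties)) {
        say(sprintf("member '%s' is not allowed here", nm))
      } else if (is.list(schema$additionalProperties)) {
        errs <- c(errs, schema_eval(x[[nm]], schema$additionalProperties,
                                    root, paste0(path, ".", nm)))
      }
    }
  }
  if (tp == "array") {
    n <- length(x)
    if (!is.null(schema$minItems) && n < schema$minItems)
      say(sprintf("array has %d items, fewer than minItems %d", n,
                  schema$minItems))
    if (!is.null(schema$maxItems) && n > schema$maxItems)
      say(sprintf("array has %d items, more than maxItems %d", n,
                  schema$maxItems))
    if (!is.null(schema$items))
      for (i in seq_len(n))
        errs <- c(errs, schema_eval(x[[i]], schema$items, root,
                                    sprintf("%s[%d]", path, i)))
    if (!is.null(schema$contains)) {
      hits <- vapply(seq_len(n), function(i)
        length(schema_eval(x[[i]], schema$contains, root, path)) == 0L, NA)
      if (n == 0L || !any(hits))
        say("no array item matches the 'contains' schema")
    }
  }
  if (!is.null(schema$allOf))
    for (sub in schema$allOf)
      errs <- c(errs, schema_eval(x, sub, root, path))
  if (!is.null(schema$anyOf)) {
    res <- lapply(schema$anyOf, function(sub)
      schema_eval(x, sub, root, path))
    if (!any(vapply(res, length, 0L) == 0L))
      say("value matches none of the anyOf alternatives")
  }
  if (!is.null(schema$`if`)) {
    cond_ok <- length(schema_eval(x, schema$`if`, root, path)) == 0L
    if (cond_ok && !is.null(schema$then))
      errs <- c(errs, schema_eval(x, schema$then, root, path))
    if (!cond_ok && !is.null(schema$`else`))
      errs <- c(errs, schema_eval(x, schema$`else`, root, path))
  }
  errs
}
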