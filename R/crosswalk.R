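# DataCite metadata-kernel export and OME Data Model correspondence.
#
# The crosswalk table contains only the mappings the standard pins per
# category: all 9 Contributors and all 5 Funders fields, 8 Dataset fields
# and 3 Publication fields map to DataCite (25 rows); all 12 Instrument
# fields and 15 Image fields map to the OME Data Model (27 rows). No
# further mappings are invented. The OME direction is a registry-level
# term mapping and per-record report only; no OME-XML instance document
# is produced, because record-level metadata lacks the pixel-data context
# OME-XML requires.

#' Crosswalk table of the registry
#'
#' @param registry An `mms_registry`.
#' @return Tibble with columns `mms_field`, `category`, `target`
#'   (`"DataCite"` or `"OME"`), `target_term`, `mapping_kind`
#'   (`"equivalent"`); `(mms_field, target)` pairs are unique.
#' @export
crosswalk_table <- function(registry = build_default_registry()) {
  f <- registry$fields
  dc <- f[!is.na(f$datacite_property), ]
  ome <- f[!is.na(f$ome_term), ]
  out <- tibble::tibble(
    mms_field = c(dc$name, ome$name),
    category = c(dc$category, ome$category),
    target = c(rep("DataCite", nrow(dc)), rep("OME", nrow(ome))),
    target_term = c(dc$datacite_property, ome$ome_term),
    mapping_kind = "equivalent"
  )
  stopifnot(!anyDuplicated(out[, c("mms_field", "target")]))
  out
}

#' Count crosswalk mappings
#'
#' @param registry An `mms_registry`.
#' @param target `"DataCite"` or `"OME"`.
#' @param category Optional category name.
#' @return Integer count of mapping rows under the filters.
#' @examples
#' reg <- build_default_registry()
#' mapping_counts(reg, "OME", "Instrument")  # 12
#' mapping_counts(reg, "DataCite")           # 25 pinned mappings
#' @export
mapping_counts <- function(registry, target = c("DataCite", "OME"),
                           category = NULL) {
  target <- match.arg(target)
  cw <- crosswalk_table(registry)
  keep <- cw$target == target
  if (!is.null(category)) {
    if (!category %in% registry$categories)
      stop("unknown category: ", category, call. = FALSE)
    keep <- keep & cw$category == category
  }
  sum(keep)
}

# ---- DataCite export --------------------------------------------------------

is_creator <- function(entry) {
  isTRUE(entry$Creator) ||
    (is.character(entry$Creator) && tolower(entry$Creator[1]) == "yes")
}

datacite_person <- function(entry) {
  out <- list(name = entry$contributorName)
  if (!is.null(entry$nameType)) out$nameType <- entry$nameType
  if (!is.null(entry$nameIdentifier)) {
    ni <- list(nameIdentifier = entry$nameIdentifier)
    if (!is.null(entry$nameIdentifierScheme))
      ni$nameIdentifierScheme <- entry$nameIdentifierScheme
    out$nameIdentifiers <- list(ni)
  }
  if (!is.null(entry$affiliation)) {
    aff <- list(name = entry$affiliation)
    if (!is.null(entry$affiliationIdentifier))
      aff$affiliationIdentifier <- entry$affiliationIdentifier
    if (!is.null(entry$affiliationIdentifierScheme))
      aff$affiliationIdentifierScheme <- entry$affiliationIdentifierScheme
    out$affiliation <- list(aff)
  }
  out
}

#' Export a record as a DataCite metadata document
#'
#' Maps the record's DOI-supporting fields onto the DataCite metadata
#' kernel (version 4 property names): contributors flagged as creators
#' become `creators` (and are also listed under `contributors` with
#' their `contributorType`), the abstract becomes a `descriptions` entry
#' of type Abstract, rights carry their URI and SPDX identifier, funders
#' become `fundingReferences` and publications become
#' `relatedIdentifiers`. The record must first pass validation under
#' profile `doi_only` with zero errors; otherwise the export refuses
#' with the validation report attached.
#'
#' @param record An `mms_record`.
#' @param registry An `mms_registry`.
#' @return The DataCite document as a nested list (render with
#'   [jsonlite::toJSON()] or [datacite_xml()]).
#' @export
export_datacite <- function(record,
                            registry = build_default_registry()) {
  report <- validate_record(record, registry, profile = "doi_only")
  if (!report$valid) {
    cond <- structure(
      class = c("mms_doi_validation_error", "error", "condition"),
      list(message = paste0(
             "record does not meet the DOI metadata profile (",
             report$counts[["error"]], " error(s), first: ",
             report$issues$code[report$issues$severity == "error"][1], ")"),
           call = NULL, report = report))
    stop(cond)
  }
  creators <- Filter(is_creator, record$Contributors)
  doc <- list(
    types = list(resourceTypeGeneral = "Dataset",
                 resourceType = "3D microscopy"),
    creators = lapply(creators, datacite_person),
    contributors = lapply(record$Contributors, function(e) {
      out <- datacite_person(e)
      if (!is.null(e$contributorType))
        out$contributorType <- e$contributorType
      out
    }),
    titles = list(list(title = record$Dataset$Title))
  )
  ds <- record$Dataset
  rights <- list()
  if (!is.null(ds$Rights)) rights$rights <- ds$Rights
  if (!is.null(ds$rightsURI)) rights$rightsUri <- ds$rightsURI
  if (!is.null(ds$rightsIdentifier)) {
    rights$rightsIdentifier <- ds$rightsIdentifier
    rights$rightsIdentifierScheme <- "SPDX"
  }
  if (length(rights) > 0L) doc$rightsList <- list(rights)
  if (!is.null(ds$Abstract))
    doc$descriptions <- list(list(description = ds$Abstract,
                                  descriptionType = "Abstract"))
  if (!is.null(ds$Keywords))
    doc$subjects <- lapply(trimws(strsplit(ds$Keywords, ";")[[1]]),
                           function(s) list(subject = s))
  if (!is.null(ds$Date))
    doc$dates <- list(list(date = ds$Date, dateType = "Collected"))
  if (!is.null(ds$datasetVersion)) doc$version <- ds$datasetVersion
  if (length(record$Funders) > 0L)
    doc$fundingReferences <- lapply(record$Funders, function(e) {
      fr <- list()
      if (!is.null(e$funderName)) fr$funderName <- e$funderName
      if (!is.null(e$fundingReferenceIdentifier))
        fr$funderIdentifier <- e$fundingReferenceIdentifier
      if (!is.null(e$fundingReferenceIdentifierType))
        fr$funderIdentifierType <- e$fundingReferenceIdentifierType
      if (!is.null(e$awardNumber)) fr$awardNumber <- e$awardNumber
      if (!is.null(e$awardTitle)) fr$awardTitle <- e$awardTitle
      fr
    })
  pubs <- Filter(function(e) !is.null(e$relatedIdentifier),
                 record$Publication)
  if (length(pubs) > 0L)
    doc$relatedIdentifiers <- lapply(pubs, function(e) {
      ri <- list(relatedIdentifier = e$relatedIdentifier)
      if (!is.null(e$relatedIdentifierType))
        ri$relatedIdentifierType <- e$relatedIdentifierType
      if (!is.null(e$relationType)) ri$relationType <- e$relationType
      ri
    })
  doc
}

#' Render a DataCite document as kernel-4-style XML
#'
#' The JSON rendering (via [jsonlite::toJSON()]) is the canonical one;
#' the XML rendering covers the same properties for consumers that
#' expect the XML kernel layout.
#'
#' @param doc A DataCite document from [export_datacite()].
#' @return An `xml2` document.
#' @export
datacite_xml <- function(doc) {
  x <- xml2::xml_new_root("resource",
                          xmlns = "http://datacite.org/schema/kernel-4")
  add_person <- function(parent, tag, p) {
    node <- xml2::xml_add_child(parent, tag)
    xml2::xml_add_child(node, paste0(tag, "Name"), p$name)
    if (!is.null(p$nameType))
      xml2::xml_set_attr(xml2::xml_child(node, paste0(tag, "Name")),
                         "nameType", p$nameType)
    for (ni in p$nameIdentifiers %||% list()) {
      id <- xml2::xml_add_child(node, "nameIdentifier", ni$nameIdentifier)
      if (!is.null(ni$nameIdentifierScheme))
        xml2::xml_set_attr(id, "nameIdentifierScheme",
                           ni$nameIdentifierScheme)
    }
    for (aff in p$affiliation %||% list()) {
      a <- xml2::xml_add_child(node, "affiliation", aff$name)
      if (!is.null(aff$affiliationIdentifier))
        xml2::xml_set_attr(a, "affiliationIdentifier",
                           aff$affiliationIdentifier)
      if (!is.null(aff$affiliationIdentifierScheme))
        xml2::xml_set_attr(a, "affiliationIdentifierScheme",
                           aff$affiliationIdentifierScheme)
    }
    node
  }
  cr <- xml2::xml_add_child(x, "creators")
  for (p in doc$creators) add_person(cr, "creator", p)
  co <- xml2::xml_add_child(x, "contributors")
  for (p in doc$contributors) {
    node <- add_person(co, "contributor", p)
    if (!is.null(p$contributorType))
      xml2::xml_set_attr(node, "contributorType", p$contributorType)
  }
  ti <- xml2::xml_add_child(x, "titles")
  for (t in doc$titles) xml2::xml_add_child(ti, "title", t$title)
  if (!is.null(doc$rightsList)) {
    rl <- xml2::xml_add_child(x, "rightsList")
    for (r in doc$rightsList) {
      node <- xml2::xml_add_child(rl, "rights", r$rights)
      if (!is.null(r$rightsUri))
        xml2::xml_set_attr(node, "rightsURI", r$rightsUri)
      if (!is.null(r$rightsIdentifier))
        xml2::xml_set_attr(node, "rightsIdentifier", r$rightsIdentifier)
    }
  }
  if (!is.null(doc$descriptions)) {
    de <- xml2::xml_add_child(x, "descriptions")
    for (d in doc$descriptions) {
      node <- xml2::xml_add_child(de, "description", d$description)
      xml2::xml_set_attr(node, "descriptionType", d$descriptionType)
    }
  }
  if (!is.null(doc$fundingReferences)) {
    fr <- xml2::xml_add_child(x, "fundingReferences")
    for (f in doc$fundingReferences) {
      node <- xml2::xml_add_child(fr, "fundingReference")
      for (nm in names(f)) xml2::xml_add_child(node, nm, f[[nm]])
    }
  }
  if (!is.null(doc$relatedIdentifiers)) {
    ri <- xml2::xml_add_child(x, "relatedIdentifiers")
    for (r in doc$relatedIdentifiers) {
      node <- xml2::xml_add_child(ri, "relatedIdentifier",
                                  r$relatedIdentifier)
      if (!is.null(r$relatedIdentifierType))
        xml2::xml_set_attr(node, "relatedIdentifierType",
                           r$relatedIdentifierType)
      if (!is.null(r$relationType))
        xml2::xml_set_attr(node, "relationType", r$relationType)
    }
  }
  x
}

#' Per-record OME correspondence report
#'
#' Lists, for a record, every populated field that has an OME Data Model
#' term, with its value and the OME term it corresponds to.
#'
#' @param record An `mms_record`.
#' @param registry An `mms_registry`.
#' @return Tibble with columns `mms_field`, `ome_term`, `value`.
#' @export
ome_report <- function(record, registry = build_default_registry()) {
  f <- registry$fields
  ome <- f[!is.na(f$ome_term), ]
  rows <- list()
  get_values <- function(row) {
    if (row$category == "Instrument") {
      v <- record$Instrument[[row$name]]
      if (is.null(v)) character(0) else as.character(v)
    } else if (row$scope == "channel") {
      unlist(lapply(record$Image$Channels, function(ch) {
        v <- ch[[row$name]]
        if (is.null(v)) NULL else
          if (row$name == "displayColor") format_display_color(v)
          else as.character(v)
      }))
    } else {
      v <- record$Image[[row$name]]
      if (is.null(v)) character(0) else as.character(v)
    }
  }
  for (i in seq_len(nrow(ome))) {
    vals <- get_values(ome[i, ])
    for (v in vals)
      rows[[length(rows) + 1L]] <- list(mms_field = ome$name[i],
                                        ome_term = ome$ome_term[i],
                                        value = v)
  }
  if (length(rows) == 0L)
    return(tibble::tibble(mms_field = character(),
                          ome_term = character(), value = character()))
  tibble::tibble(
    mms_field = vapply(rows, `[[`, "", "mms_field"),
    ome_term = vapply(rows, `[[`, "", "ome_term"),
    value = vapply(rows, `[[`, "", "value")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
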