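# The multi-table submission layout: one rectangular table per category
# (header row of registry field names, one data row per repeated entry,
# one row for scalar categories) plus a small Submission table carrying
# the fundingDeclared flag. Plain per-category CSV files (UTF-8, comma,
# quoted as needed) are the physical carrier. All tables are held as
# all-character tibbles; a blank cell is an absent value.

BUNDLE_EXTRA_TABLE <- "Submission"

# shortest decimal text that round-trips back to the same double
num2chr <- function(x) {
  vapply(x, function(v) {
    if (is.character(v)) return(v)
    s <- as.character(v)
    if (!is.na(suppressWarnings(as.numeric(s))) &&
        identical(as.numeric(s), as.numeric(v))) s
    else sprintf("%.17g", as.numeric(v))
  }, "")
}

cell_out <- function(name, value) {
  if (is.null(value)) return("")
  v <- convert_value_out(name, value)
  if (is.numeric(v)) v <- num2chr(v)
  paste(as.character(v), collapse = "|")
}

blank_table <- function(headers, n) {
  tb <- tibble::as_tibble(
    stats::setNames(replicate(length(headers),
                              rep("", n), simplify = FALSE), headers))
  tb
}

#' Convert a record to the tabular submission bundle
#'
#' Emits all seven category tables with the full registry headers in
#' registry order (template behavior: empty optional columns are
#' present), plus a `Submission` table carrying the `fundingDeclared`
#' flag. Entry categories get one row per entry; scalar categories one
#' row; the Image table one row per channel/landmark with the
#' record-scoped values on the first row. An empty record yields tables
#' with headers only.
#'
#' @param record An `mms_record`.
#' @param registry An `mms_registry`.
#' @return An `mms_bundle`: list with element `tables`, a named list of
#'   all-character tibbles.
#' @export
write_tabular <- function(record, registry = build_default_registry()) {
  stopifnot(inherits(record, "mms_record"))
  tables <- list()
  for (cat_ in registry$categories) {
    rows <- reg_rows(registry, cat_)
    headers <- rows$name
    if (cat_ %in% ENTRY_CATEGORIES) {
      entries <- record[[cat_]]
      tb <- blank_table(headers, length(entries))
      for (i in seq_along(entries))
        for (nm in headers)
          tb[i, nm] <- cell_out(nm, entries[[i]][[nm]])
    } else if (cat_ == "Image") {
      rec_rows <- reg_rows(registry, "Image", "record")
      ch <- record$Image$Channels
      lm <- record$Image$Landmarks
      has_scalar <- any(vapply(rec_rows$name, function(nm)
        !is.null(record$Image[[nm]]), NA))
      n <- max(length(ch), length(lm), as.integer(has_scalar))
      tb <- blank_table(headers, n)
      if (has_scalar)
        for (nm in rec_rows$name)
          tb[1, nm] <- cell_out(nm, record$Image[[nm]])
      ch_names <- reg_rows(registry, "Image", "channel")$name
      for (i in seq_along(ch))
        for (nm in ch_names) tb[i, nm] <- cell_out(nm, ch[[i]][[nm]])
      lm_names <- reg_rows(registry, "Image", "landmark")$name
      for (i in seq_along(lm))
        for (nm in lm_names) tb[i, nm] <- cell_out(nm, lm[[i]][[nm]])
    } else {
      block <- record[[cat_]]
      n <- as.integer(length(block) > 0L)
      tb <- blank_table(headers, n)
      if (n == 1L)
        for (nm in headers) tb[1, nm] <- cell_out(nm, block[[nm]])
    }
    tables[[cat_]] <- tb
  }
  tables[[BUNDLE_EXTRA_TABLE]] <- tibble::tibble(
    fundingDeclared = if (isTRUE(record$funding_declared)) "TRUE" else "FALSE")
  structure(list(tables = tables), class = "mms_bundle")
}

row_cells <- function(tb, i, cols) {
  vals <- lapply(cols, function(nm) {
    v <- tb[[nm]][i]
    if (is.na(v) || !nzchar(trimws(v))) NULL else v
  })
  names(vals) <- cols
  vals[!vapply(vals, is.null, NA)]
}

# convert one table row's cells into an entry via the registry
convert_cells <- function(rows, cells, path_prefix, issues) {
  entry <- list()
  for (nm in names(cells)) {
    row <- rows[rows$name == nm, ]
    raw <- cells[[nm]]
    if (grepl("|", raw, fixed = TRUE) && row$name != "displayColor")
      raw <- strsplit(raw, "|", fixed = TRUE)[[1L]]
    conv <- convert_value_in(row, raw, paste0(path_prefix, ".", nm),
                             issues)
    issues <- conv$issues
    entry[[nm]] <- conv$value
  }
  list(entry = entry, issues = issues)
}

#' Convert a tabular submission bundle to a record
#'
#' Header names are resolved against the registry: a misspelled or
#' unknown header becomes an `UNKNOWN_FIELD` issue and its column is
#' ignored. Blank cells are absent values; all anomalies are issues,
#' never exceptions.
#'
#' @param bundle An `mms_bundle` (see [write_tabular()],
#'   [read_tabular_csv()]).
#' @param registry An `mms_registry`.
#' @return A list with `record` and `issues`, as [parse_record()].
#' @export
read_tabular <- function(bundle, registry = build_default_registry()) {
  stopifnot(inherits(bundle, "mms_bundle") || is.list(bundle))
  tables <- if (inherits(bundle, "mms_bundle")) bundle$tables else bundle
  record <- empty_record()
  issues <- new_issues()
  for (nm in setdiff(names(tables),
                     c(registry$categories, BUNDLE_EXTRA_TABLE)))
    issues <- add_issue(issues, nm, "UNKNOWN_FIELD",
                        sprintf("unknown table '%s'", nm))
  sub <- tables[[BUNDLE_EXTRA_TABLE]]
  if (!is.null(sub) && "fundingDeclared" %in% names(sub) &&
      nrow(sub) >= 1L)
    record$funding_declared <-
      tolower(sub$fundingDeclared[1]) %in% c("true", "yes", "1")

  for (cat_ in registry$categories) {
    tb <- tables[[cat_]]
    if (is.null(tb)) next
    tb <- tibble::as_tibble(tb)
    tb[] <- lapply(tb, as.character)
    rows <- reg_rows(registry, cat_)
    known <- intersect(names(tb), rows$name)
    for (bad in setdiff(names(tb), rows$name))
      issues <- add_issue(issues, paste0(cat_, ".", bad), "UNKNOWN_FIELD",
                          sprintf("unknown column '%s' in %s table", bad,
                                  cat_))
    if (cat_ %in% ENTRY_CATEGORIES) {
      used <- which(vapply(seq_len(nrow(tb)), function(i)
        length(row_cells(tb, i, known)) > 0L, NA))
      k <- 0L
      for (i in used) {
        k <- k + 1L
        res <- convert_cells(rows, row_cells(tb, i, known),
                             sprintf("%s[%d]", cat_, k), issues)
        issues <- res$issues
        record[[cat_]][[k]] <- res$entry
      }
    } else if (cat_ == "Image") {
      rec_names <- intersect(known, reg_rows(registry, "Image",
                                             "record")$name)
      ch_names <- intersect(known, reg_rows(registry, "Image",
                                            "channel")$name)
      lm_names <- intersect(known, reg_rows(registry, "Image",
                                            "landmark")$name)
      if (nrow(tb) >= 1L) {
        res <- convert_cells(rows, row_cells(tb, 1L, rec_names),
                             "Image", issues)
        issues <- res$issues
        record$Image <- res$entry
        # record-scoped values on later rows are a multiplicity problem
        for (i in seq_len(nrow(tb))[-1L])
          for (nm in names(row_cells(tb, i, rec_names)))
            issues <- add_issue(issues, paste0("Image.", nm),
                                "MULTIPLICITY",
                                sprintf("value for single-occurrence %s on row %d",
                                        nm, i))
      }
      record$Image$Channels <- list()
      record$Image$Landmarks <- list()
      kc <- 0L
      for (i in seq_len(nrow(tb))) {
        cells <- row_cells(tb, i, ch_names)
        if (length(cells) == 0L) next
        kc <- kc + 1L
        res <- convert_cells(rows, cells,
                             sprintf("Image.Channels[%d]", kc), issues)
        issues <- res$issues
        record$Image$Channels[[kc]] <- res$entry
      }
      kl <- 0L
      for (i in seq_len(nrow(tb))) {
        cells <- row_cells(tb, i, lm_names)
        if (length(cells) == 0L) next
        kl <- kl + 1L
        res <- convert_cells(rows, cells,
                             sprintf("Image.Landmarks[%d]", kl), issues)
        issues <- res$issues
        record$Image$Landmarks[[kl]] <- res$entry
      }
    } else {
      if (nrow(tb) >= 1L) {
        res <- convert_cells(rows, row_cells(tb, 1L, known), cat_, issues)
        issues <- res$issues
        record[[cat_]] <- res$entry
      }
      if (nrow(tb) > 1L &&
          any(vapply(seq_len(nrow(tb))[-1L], function(i)
            length(row_cells(tb, i, known)) > 0L, NA)))
        issues <- add_issue(issues, cat_, "MULTIPLICITY",
                            sprintf("%s table has multiple data rows", cat_))
    }
  }
  list(record = record, issues = issues)
}

#' Write a tabular bundle as per-category CSV files
#'
#' One `<category>.csv` per table (lower-case file names), UTF-8,
#' comma-separated, quoted as needed; byte-deterministic for identical
#' input.
#'
#' @param x An `mms_bundle` or an `mms_record` (converted via
#'   [write_tabular()]).
#' @param dir Output directory (created if needed).
#' @param registry An `mms_registry`.
#' @return Character vector of file paths, invisibly.
#' @export
write_tabular_csv <- function(x, dir,
                              registry = build_default_registry()) {
  bundle <- if (inherits(x, "mms_record")) write_tabular(x, registry)
            else x
  stopifnot(inherits(bundle, "mms_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bundle$tables)) {
    path <- file.path(dir, paste0(tolower(nm), ".csv"))
    readr::write_csv(bundle$tables[[nm]], path, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a tabular bundle from a directory of CSV files
#'
#' Reads the `<category>.csv` files written by [write_tabular_csv()]
#' (missing files are simply absent tables).
#'
#' @param dir Directory containing the CSV files.
#' @param registry An `mms_registry`.
#' @return An `mms_bundle`.
#' @export
read_tabular_csv <- function(dir, registry = build_default_registry()) {
  stopifnot(dir.exists(dir))
  tables <- list()
  for (nm in c(registry$categories, BUNDLE_EXTRA_TABLE)) {
    path <- file.path(dir, paste0(tolower(nm), ".csv"))
    if (!file.exists(path)) next
    tb <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), na = character(),
      progress = FALSE)
    tables[[nm]] <- tb
  }
  structure(list(tables = tables), class = "mms_bundle")
}

#' @export
print.mms_bundle <- function(x, ...) {
  cat("<mms_bundle>", length(x$tables), "tables\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-12s %d x %d\n", nm, nrow(x$tables[[nm]]),
                ncol(x$tables[[nm]])))
  invisible(x)
}
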