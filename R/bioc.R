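new_table <- function(label, caption, header, rows) {
  ncol <- length(header)
  rows <- lapply(rows, function(r) {
    length(r) <- ncol                      # pad short rows
    r[is.na(r)] <- ""
    as.character(r)
  })
  structure(list(table_label = label, caption = caption,
                 header = as.character(header), rows = rows),
            class = "pm3_table")
}

#' @export
print.pm3_table <- function(x, ...) {
  cat("<pm3_table> ", x$table_label, ": ", length(x$rows), " rows x ",
      length(x$header), " cols\n", sep = "")
  invisible(x)
}

infon_map <- function(node) {
  infons <- xml2::xml_find_all(node, "./infon")
  stats::setNames(xml2::xml_text(infons), xml2::xml_attr(infons, "key"))
}

parse_table_grid <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  list(header = cells[[1]], rows = cells[-1])
}

#' Read a publication from PMC-style BioC XML
#'
#' Parses a BioC collection, keeps the first document, and separates its
#' passages into a prose stream and structured tables. A passage whose
#' `type` infon is (or starts with) `"table"` is parsed as a grid of
#' tab-separated cells, one row per line, first line the header; a
#' passage of type `"table_caption"` attaches its text to the following
#' table. Table content never enters the prose stream. Short table rows
#' are padded with empty cells to the header width.
#'
#' @param x Path to a BioC XML file, an XML string, or raw bytes.
#' @return An object of class `pm3_bundle`: list with `doc_id`,
#'   `passages` (data.frame of `section`, `text`, in document order) and
#'   `tables` (list of `pm3_table`, in document order).
#' @export
read_bioc <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    pm3_abort(paste0("malformed BioC XML: ", conditionMessage(e)), "pm3_xml_error"))
  docs <- xml2::xml_find_all(doc, "//document")
  if (!length(docs)) pm3_abort("BioC collection contains no document", "pm3_empty_document")
  d <- docs[[1]]
  doc_id <- xml2::xml_text(xml2::xml_find_first(d, "./id"))
  passages <- xml2::xml_find_all(d, "./passage")
  if (!length(passages)) pm3_abort("document contains no passages", "pm3_empty_document")

  prose_section <- character(0)
  prose_text <- character(0)
  tables <- list()
  pending_caption <- ""
  pending_label <- ""

  for (p in passages) {
    inf <- infon_map(p)
    type <- inf[["type"]] %||% "paragraph"
    text <- xml2::xml_text(xml2::xml_find_first(p, "./text"))
    if (is.na(text)) text <- ""
    if (identical(type, "table_caption")) {
      pending_caption <- text
      pending_label <- inf[["table_label"]] %||% ""
      next
    }
    if (startsWith(type, "table") || grepl("\t", text)) {
      grid <- parse_table_grid(text)
      if (is.null(grid)) next
      label <- inf[["table_label"]] %||% inf[["id"]] %||% pending_label
      if (!nzchar(label)) label <- sprintf("Table %d", length(tables) + 1L)
      tables[[length(tables) + 1L]] <-
        new_table(label, pending_caption, grid$header, grid$rows)
      pending_caption <- ""
      pending_label <- ""
      next
    }
    section <- inf[["section_type"]] %||% type
    prose_section <- c(prose_section, section)
    prose_text <- c(prose_text, text)
  }

  structure(list(
    doc_id = if (is.na(doc_id)) "" else doc_id,
    passages = data.frame(section = prose_section, text = prose_text,
                          stringsAsFactors = FALSE),
    tables = tables
  ), class = "pm3_bundle")
}

#' @export
print.pm3_bundle <- function(x, ...) {
  cat("<pm3_bundle> document ", x$doc_id, ": ", nrow(x$passages),
      " passages, ", length(x$tables), " tables\n", sep = "")
  invisible(x)
}

# concatenated prose with per-section character spans (0-based half-open)
bundle_prose <- function(bundle) {
  if (!nrow(bundle$passages))
    return(list(text = "", sections = data.frame(section = character(0),
                                                 start = integer(0), end = integer(0))))
  txt <- bundle$passages$text
  sep <- "\n\n"
  starts <- integer(length(txt))
  off <- 0L
  for (i in seq_along(txt)) {
    starts[i] <- off
    off <- off + nchar(txt[i]) + if (i < length(txt)) nchar(sep) else 0L
  }
  list(
    text = paste(txt, collapse = sep),
    sections = data.frame(section = bundle$passages$section,
                          start = starts, end = starts + nchar(txt),
                          stringsAsFactors = FALSE)
  )
}
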