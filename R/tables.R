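#' Sanitize column names for the relational store
#'
#' Lower-cases, replaces non-alphanumeric runs with underscores, names
#' empty headers `col_<i>` by their position, and disambiguates
#' duplicates with `_2`, `_3`, ... suffixes.
#'
#' @param header Character vector of original column names.
#' @return Character vector of sanitized, unique names.
#' @export
sanitize_names <- function(header) {
  nm <- tolower(trimws(header))
  nm <- gsub("[^a-z0-9]+", "_", nm)
  nm <- gsub("^_+|_+$", "", nm)
  empty <- !nzchar(nm)
  nm[empty] <- paste0("col_", which(empty))
  out <- nm
  seen <- list()
  for (i in seq_along(nm)) {
    k <- nm[i]
    cnt <- (seen[[k]] %||% 0L) + 1L
    seen[[k]] <- cnt
    if (cnt > 1L) out[i] <- paste0(k, "_", cnt)
  }
  out
}

#' Load the tables of a publication into an embedded relational store
#'
#' One all-text relation per table; every cell round-trips verbatim.
#' Original headers are kept in the relation metadata; column names are
#' sanitized with [sanitize_names()].
#'
#' @param bundle A `pm3_bundle`, or a list of `pm3_table` objects.
#' @return An object of class `pm3_store`: list of relations, each with
#'   `name`, `table_label`, `header` (original), `columns` (sanitized)
#'   and `data` (character data.frame).
#' @export
load_tables <- function(bundle) {
  tables <- if (inherits(bundle, "pm3_bundle")) bundle$tables else bundle
  relations <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    stopifnot(inherits(tb, "pm3_table"))
    cols <- sanitize_names(tb$header)
    mat <- if (length(tb$rows))
      do.call(rbind, tb$rows)
    else
      matrix(character(0), nrow = 0, ncol = length(cols))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    rownames(df) <- NULL
    list(name = sprintf("table_%d", i), table_label = tb$table_label,
         header = tb$header, columns = cols, data = df)
  })
  structure(list(relations = relations), class = "pm3_store")
}

#' @export
print.pm3_store <- function(x, ...) {
  cat("<pm3_store> ", length(x$relations), " relation(s), ",
      sum(vapply(x$relations, function(r) nrow(r$data), integer(1))),
      " rows total\n", sep = "")
  invisible(x)
}

#' Export every relation of a store as tab-separated text
#'
#' @param store A `pm3_store`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(store$relations, function(r) {
    p <- file.path(dir, paste0(r$name, ".tsv"))
    utils::write.table(r$data, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    p
  }, character(1))
  invisible(paths)
}

#' Generate a position-guided query against one relation
#'
#' The template query selects every row where any column contains one of
#' the variant coordinates as a digit substring; matched rows are then
#' cleaned up by [position_postfilter()]. When a completion backend is
#' supplied, its generated SQL is used instead — but only after
#' validation: it must be a single read-only SELECT over the known
#' relation and columns, of the same shape as the template. Anything else
#' falls back to the template.
#'
#' @param relation One relation of a `pm3_store`.
#' @param positions Integer vector of variant coordinates.
#' @param backend Optional completion backend (see [pm3_backend_mock()]).
#' @return A list of class `pm3_query`: `sql` (the query text),
#'   `clauses` (data.frame of `column`, `needle` LIKE terms) and
#'   `source` (`"template"` or `"backend"`).
#' @export
generate_position_query <- function(relation, positions, backend = NULL) {
  if (!length(relation$columns))
    pm3_abort("relation has no columns", "pm3_schema_error")
  positions <- as.integer(positions)
  template <- position_query_sql(relation$name, relation$columns, positions)
  sql <- template
  source <- "template"
  if (!is.null(backend)) {
    req <- backend_request(
      task = "sql_generation",
      context = paste0("relation ", relation$name, "(",
                       paste(relation$columns, collapse = ", "), ")"),
      variant_forms = NULL,
      extra = list(positions = positions, template = template)
    )
    ans <- complete(backend, req)
    cand <- ans$text %||% ""
    if (nzchar(cand) && is_valid_position_query(cand, relation)) {
      sql <- cand
      source <- "backend"
    }
  }
  clauses <- parse_like_clauses(sql)
  structure(list(sql = sql, clauses = clauses, source = source), class = "pm3_query")
}

position_query_sql <- function(name, columns, positions) {
  terms <- unlist(lapply(positions, function(p)
    sprintf("%s LIKE '%%%d%%'", columns, p)))
  sprintf("SELECT * FROM %s WHERE %s;", name, paste(terms, collapse = " OR "))
}

parse_like_clauses <- function(sql) {
  m <- gregexpr("([A-Za-z0-9_]+)\\s+LIKE\\s+'%([0-9]+)%'", sql, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(column = character(0), needle = character(0),
                      stringsAsFactors = FALSE))
  pieces <- regmatches(sql, gregexpr("([A-Za-z0-9_]+)\\s+LIKE\\s+'%([0-9]+)%'", sql, perl = TRUE))[[1]]
  col <- sub("\\s+LIKE.*$", "", pieces)
  needle <- sub("^.*'%([0-9]+)%'$", "\\1", pieces)
  data.frame(column = col, needle = needle, stringsAsFactors = FALSE)
}

# a backend-generated query is accepted only if it is a single read-only
# SELECT over the known relation whose LIKE clauses reference known columns
is_valid_position_query <- function(sql, relation) {
  s <- trimws(sql)
  s <- sub(";\\s*$", "", s)
  if (grepl(";", s, fixed = TRUE)) return(FALSE)          # single statement
  if (!grepl("^SELECT\\b", s, ignore.case = TRUE)) return(FALSE)
  if (grepl("\\b(INSERT|UPDATE|DELETE|DROP|ALTER|CREATE|ATTACH|PRAGMA|REPLACE)\\b",
            s, ignore.case = TRUE)) return(FALSE)
  if (!grepl(paste0("\\bFROM\\s+", relation$name, "\\b"), s, ignore.case = TRUE))
    return(FALSE)
  cl <- parse_like_clauses(s)
  if (!nrow(cl)) return(FALSE)
  all(cl$column %in% relation$columns)
}

execute_query <- function(relation, query) {
  df <- relation$data
  if (!nrow(df) || !nrow(query$clauses)) return(integer(0))
  hit <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(query$clauses))) {
    col <- query$clauses$column[i]
    if (!col %in% names(df)) next
    hit <- hit | grepl(query$clauses$needle[i], df[[col]], fixed = TRUE)
  }
  which(hit)
}

#' Digit-boundary post-filter for position matches
#'
#' A cell that matched a variant coordinate by substring is kept only if
#' the coordinate occurs as a standalone digit run — not buried inside a
#' longer number or a decimal fraction. This removes false positives such
#' as the cell `"frequency is 0.93884"` matching query position 388.
#'
#' @param cell_text The matched cell content.
#' @param position The variant coordinate.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
position_postfilter <- function(cell_text, position) {
  has_standalone_digits(cell_text, position)
}

# first-column patient identifiers with merged-cell inheritance: an empty
# cell inherits the nearest non-empty identifier above it
resolved_ids <- function(df) {
  if (!nrow(df)) return(character(0))
  ids <- trimws(df[[1]])
  for (i in seq_along(ids))
    if (!nzchar(ids[i]) && i > 1L) ids[i] <- ids[i - 1L]
  ids
}

new_hit <- function(relation, row, cell_idx, matched, confidence, ids) {
  structure(list(
    table_label = relation$table_label,
    row_index = row - 1L,                        # stored 0-based
    row_cells = as.character(unlist(relation$data[row, ], use.names = FALSE)),
    matched_cell_index = cell_idx - 1L,
    matched_text = matched,
    patient_id = ids[row],
    confidence = confidence
  ), class = "pm3_table_hit")
}

#' @export
print.pm3_table_hit <- function(x, ...) {
  cat("<pm3_table_hit> ", x$table_label, ", row ", x$row_index + 1L,
      " (", x$confidence, "): patient '", x$patient_id, "'\n", sep = "")
  invisible(x)
}

#' Find table rows carrying the query variant
#'
#' Each relation is scanned twice. Rows where a cell matches a full
#' notation pattern (tier `T0_full`) are reported with confidence
#' `"notation"`. Remaining rows are matched by the position-guided query
#' and kept only if a cell passes [position_postfilter()]; these carry
#' confidence `"position_only"`. One hit per row, ordered by (table,
#' row); the first column of the row supplies the patient identifier.
#'
#' @param store A `pm3_store`.
#' @param repset A `pm3_repset`.
#' @param backend Optional backend forwarded to
#'   [generate_position_query()].
#' @return List of `pm3_table_hit`.
#' @export
find_variant_rows <- function(store, repset, backend = NULL) {
  t0 <- compile_patterns(repset, "T0_full")
  hits <- list()
  for (rel in store$relations) {
    df <- rel$data
    if (!nrow(df)) next
    ids <- resolved_ids(df)
    notation_rows <- integer(0)
    for (row in seq_len(nrow(df))) {
      for (cell in seq_along(df)) {
        if (pm3_matches_any(df[row, cell], t0)) {
          m <- pm3_scan(df[row, cell], t0)
          hits[[length(hits) + 1L]] <-
            new_hit(rel, row, cell, m$match[1], "notation", ids)
          notation_rows <- c(notation_rows, row)
          break
        }
      }
    }
    query <- generate_position_query(rel, repset$positions, backend)
    for (row in setdiff(execute_query(rel, query), notation_rows)) {
      for (cell in seq_along(df)) {
        ok <- FALSE
        for (p in repset$positions) {
          if (grepl(as.character(p), df[row, cell], fixed = TRUE) &&
              position_postfilter(df[row, cell], p)) {
            ok <- TRUE
            matched <- as.character(p)
            break
          }
        }
        if (ok) {
          hits[[length(hits) + 1L]] <-
            new_hit(rel, row, cell, matched, "position_only", ids)
          break
        }
      }
    }
  }
  ord <- order(
    vapply(hits, function(h) h$table_label, character(1)),
    vapply(hits, function(h) h$row_index, integer(1))
  )
  hits[ord]
}

#' Expand a table hit to same-patient neighbour rows
#'
#' Genotype tables list the alleles of one patient on adjacent rows.
#' Given a hit, this returns the contiguous block of rows above and below
#' it whose first-column identifier resolves to the same patient (empty
#' cells inherit the identifier from above, the merged-cell convention),
#' excluding the hit row itself. Rows elsewhere in the table with an
#' equal identifier are not part of the block; they are attached as the
#' `"noncontiguous"` attribute so callers can surface them as
#' low-confidence candidates.
#'
#' @param store A `pm3_store`.
#' @param hit A `pm3_table_hit` from [find_variant_rows()].
#' @return List of `pm3_table_hit` (the neighbour rows, in row order).
#' @export
extract_in_trans_rows <- function(store, hit) {
  rel <- NULL
  for (r in store$relations) if (r$table_label == hit$table_label) { rel <- r; break }
  if (is.null(rel)) pm3_abort("hit does not belong to this store", "pm3_domain_error")
  df <- rel$data
  ids <- resolved_ids(df)
  row <- hit$row_index + 1L
  if (row < 1L || row > nrow(df))
    pm3_abort("hit row out of range", "pm3_domain_error")
  lo <- row
  while (lo > 1L && identical(ids[lo - 1L], ids[row])) lo <- lo - 1L
  hi <- row
  while (hi < nrow(df) && identical(ids[hi + 1L], ids[row])) hi <- hi + 1L
  block <- setdiff(lo:hi, row)
  out <- lapply(block, function(i) new_hit(rel, i, 1L, ids[i], hit$confidence, ids))
  stray <- setdiff(which(ids == ids[row]), lo:hi)
  attr(out, "noncontiguous") <-
    lapply(stray, function(i) new_hit(rel, i, 1L, ids[i], "position_only", ids))
  out
}

#' Split tables into fixed-size batches
#'
#' Documents with many tables are processed in order-preserving batches
#' of at most `max_per_batch` tables, so each pass over the store stays
#' small; results concatenated over batches equal a single pass.
#'
#' @param tables List of `pm3_table` (or a `pm3_bundle`).
#' @param max_per_batch Maximum tables per batch (default 5).
#' @return List of lists of `pm3_table`.
#' @export
batch_tables <- function(tables, max_per_batch = 5L) {
  if (inherits(tables, "pm3_bundle")) tables <- tables$tables
  max_per_batch <- as.integer(max_per_batch)
  if (max_per_batch < 1L) pm3_abort("max_per_batch must be >= 1", "pm3_domain_error")
  if (!length(tables)) return(list())
  idx <- split(seq_along(tables), (seq_along(tables) - 1L) %/% max_per_batch)
  lapply(unname(idx), function(i) tables[i])
}
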