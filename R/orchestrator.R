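render_row <- function(hit) {
  sprintf("%s, row %d: %s", hit$table_label, hit$row_index + 1L,
          paste(hit$row_cells, collapse = " | "))
}

prov_table <- function(hit, confidence = NULL) {
  list(channel = "table",
       confidence = confidence %||% if (hit$confidence == "notation") "notation" else "low",
       table_label = hit$table_label, row_index = hit$row_index,
       row_text = paste(hit$row_cells, collapse = " | "))
}

prov_text <- function(chunk_start, chunk_end, rationale, confidence) {
  list(channel = "text", confidence = confidence,
       chunk_start = chunk_start, chunk_end = chunk_end, rationale = rationale)
}

new_evidence <- function(variant_hit, in_trans, provenance, tier_used) {
  structure(list(variant_hit = variant_hit, in_trans = in_trans,
                 provenance = provenance, tier_used = tier_used),
            class = "pm3_evidence")
}

#' @export
print.pm3_evidence <- function(x, ...) {
  cat("<pm3_evidence> variant hit: ", if (x$variant_hit) "yes" else "no", "\n", sep = "")
  if (length(x$in_trans))
    cat("  in trans candidates: ", paste(x$in_trans, collapse = ", "), "\n", sep = "")
  for (p in x$provenance) {
    if (p$channel == "table")
      cat("  Source: ", p$table_label, ", row ", p$row_index + 1L,
          " [", p$confidence, "]\n", sep = "")
    else
      cat("  Source: text chars ", p$chunk_start, "-", p$chunk_end,
          " [", p$confidence, "]", if (nzchar(p$rationale %||% ""))
            paste0(" \"", p$rationale, "\""), "\n", sep = "")
  }
  invisible(x)
}

prepare_inputs <- function(bundle, variant, cds) {
  if (is.character(bundle)) bundle <- read_bioc(bundle)
  if (is.character(variant)) variant <- parse_hgvs(variant)
  if (!is.null(cds) && is_scalar_string(cds) && file.exists(cds) &&
      !grepl("^[ACGTNacgtn]+$", cds))
    cds <- read_cds(cds)
  list(bundle = bundle,
       repset = augment_variant(variant, cds = if (variant$kind == "substitution") cds else NULL))
}

# Rows matched by full notation establish the hit directly; rows matched
# by position only are fetched and put to the backend for interpretation,
# mirroring the LLM pass over fetched records in the table pipeline.
table_channel_answer <- function(store, repset, backend) {
  hits <- find_variant_rows(store, repset, backend = backend)
  notation <- any(vapply(hits, function(h) h$confidence == "notation", logical(1)))
  confirmed <- notation
  if (!confirmed && length(hits)) {
    ctx <- paste(vapply(hits, render_row, character(1)), collapse = "\n")
    ans <- complete(backend, backend_request("variant_hit", ctx, variant_forms = repset))
    confirmed <- identical(ans$verdict, "yes")
  }
  list(hits = hits, hit = confirmed)
}

text_channel_answer <- function(bundle, repset, backend, config, task) {
  chunks <- chunk_bundle(bundle, config$chunk_size, config$overlap)
  ret <- retrieve(chunks, repset, config)
  if (!nrow(ret$chunks))
    return(list(answer = NULL, retrieval = ret, provenance = list()))
  context <- paste(ret$chunks$text, collapse = "\n\n")
  ans <- complete(backend, backend_request(task, context, variant_forms = repset))
  conf <- if (ret$tier_used == "T0_full") "notation" else "low"
  prov <- lapply(seq_len(nrow(ret$chunks)), function(i) {
    rat <- ans$rationale_span %||% ""
    if (nzchar(rat) && !grepl(rat, ret$chunks$text[i], fixed = TRUE)) rat <- ""
    prov_text(ret$chunks$start[i], ret$chunks$end[i], rat, conf)
  })
  list(answer = ans, retrieval = ret, provenance = prov)
}

#' Answer the variant-hit question for one publication
#'
#' Runs both evidence channels for the query variant: the table channel
#' (relational store + position-guided queries + digit post-filter) and
#' the text channel (chunking + tiered retrieval + completion backend).
#' The publication is called a hit when either channel finds the variant
#' — tables and prose each contribute true positives that the other
#' channel can miss.
#'
#' @param bundle A `pm3_bundle` (or path to a BioC XML file).
#' @param variant A `pm3_variant` or HGVS string.
#' @param cds Optional coding sequence (string or FASTA path) enabling
#'   protein-level representations.
#' @param backend Completion backend (default [pm3_backend_mock()]).
#' @param config A [pm3_config()].
#' @return A `pm3_evidence` object; `in_trans` is always empty here.
#' @export
answer_variant_hit <- function(bundle, variant, cds = NULL,
                               backend = pm3_backend_mock(),
                               config = pm3_config()) {
  inp <- prepare_inputs(bundle, variant, cds)
  provenance <- list()
  table_hit <- FALSE
  if (config$table_channel) {
    store <- load_tables(inp$bundle)
    tc <- table_channel_answer(store, inp$repset, backend)
    table_hit <- tc$hit
    if (tc$hit) provenance <- c(provenance, lapply(tc$hits, prov_table))
  }
  text_hit <- FALSE
  tier <- NA_character_
  if (config$text_channel) {
    tc <- text_channel_answer(inp$bundle, inp$repset, backend, config, "variant_hit")
    tier <- tc$retrieval$tier_used
    if (!is.null(tc$answer) && identical(tc$answer$verdict, "yes")) {
      text_hit <- TRUE
      provenance <- c(provenance, tc$provenance)
    }
  }
  new_evidence(table_hit || text_hit, character(0), provenance, tier)
}

#' Identify in trans partner variants for one publication
#'
#' Table channel: the rows carrying the query variant are expanded to
#' same-patient neighbour rows and the completion backend extracts the
#' other variants mentioned there. Text channel: variant-bearing chunks
#' are retrieved and the backend extracts co-occurring variant mentions.
#' Candidates from both channels are merged and deduplicated by
#' [variant_equivalent()]. If the query variant is not a hit at all, the
#' candidate list is empty by construction.
#'
#' @inheritParams answer_variant_hit
#' @return A `pm3_evidence` object with per-candidate provenance.
#' @export
answer_in_trans <- function(bundle, variant, cds = NULL,
                            backend = pm3_backend_mock(),
                            config = pm3_config()) {
  inp <- prepare_inputs(bundle, variant, cds)
  candidates <- character(0)
  provenance <- list()
  table_hit <- FALSE

  if (config$table_channel) {
    store <- load_tables(inp$bundle)
    tc <- table_channel_answer(store, inp$repset, backend)
    qhits <- tc$hits
    table_hit <- tc$hit
    for (qh in qhits) {
      sib <- extract_in_trans_rows(store, qh)
      blocks <- list(
        list(rows = c(list(qh), sib), confidence = qh$confidence),
        list(rows = attr(sib, "noncontiguous") %||% list(), confidence = "position_only")
      )
      for (bl in blocks) {
        if (!length(bl$rows)) next
        context <- paste(vapply(bl$rows, render_row, character(1)), collapse = "\n")
        ans <- complete(backend, backend_request("in_trans", context,
                                                 variant_forms = inp$repset))
        for (v in ans$extracted_variants) {
          if (any(vapply(candidates, variant_equivalent, logical(1), b = v))) next
          candidates <- c(candidates, v)
          si <- which(vapply(bl$rows, function(h)
            grepl(v, paste(h$row_cells, collapse = " | "), fixed = TRUE),
            logical(1)))
          src <- bl$rows[[if (length(si)) si[1] else 1L]]
          conf <- if (bl$confidence == "notation") "notation" else "low"
          provenance <- c(provenance, list(prov_table(src, conf)))
        }
      }
    }
  }

  text_hit <- FALSE
  tier <- NA_character_
  if (config$text_channel) {
    tc <- text_channel_answer(inp$bundle, inp$repset, backend, config, "in_trans")
    tier <- tc$retrieval$tier_used
    if (!is.null(tc$answer)) {
      vh <- complete(backend, backend_request(
        "variant_hit", paste(tc$retrieval$chunks$text, collapse = "\n\n"),
        variant_forms = inp$repset))
      text_hit <- identical(vh$verdict, "yes")
      if (text_hit) {
        conf <- if (tc$retrieval$tier_used == "T0_full") "notation" else "low"
        for (v in tc$answer$extracted_variants) {
          if (any(vapply(candidates, variant_equivalent, logical(1), b = v))) next
          candidates <- c(candidates, v)
          ci <- which(vapply(seq_len(nrow(tc$retrieval$chunks)), function(i)
            grepl(v, tc$retrieval$chunks$text[i], fixed = TRUE), logical(1)))
          ci <- if (length(ci)) ci[1] else 1L
          provenance <- c(provenance, list(prov_text(
            tc$retrieval$chunks$start[ci], tc$retrieval$chunks$end[ci], v, conf)))
        }
      }
    }
  }

  if (!(table_hit || text_hit))
    return(new_evidence(FALSE, character(0), list(), tier))
  new_evidence(TRUE, candidates, provenance, tier)
}

#' Run the full evidence-extraction flow for one (variant, publication) pair
#'
#' Composes [answer_variant_hit()] and [answer_in_trans()], adds a
#' free-text digest of the evidence context per channel (backend task
#' `"summarize"`), and returns a schema-versioned report that serialises
#' to JSON. With the mock backend the report is fully deterministic.
#'
#' @inheritParams answer_variant_hit
#' @param out Optional path; when given the JSON report is written there.
#' @return A list of class `pm3_report` (invisibly when `out` is given).
#' @export
run_pair <- function(bundle, variant, cds = NULL,
                     backend = pm3_backend_mock(), config = pm3_config(),
                     out = NULL) {
  if (is.character(bundle)) {
    if (!file.exists(bundle))
      pm3_abort(sprintf("BioC file not found: '%s'", bundle), "pm3_file_not_found")
    bundle <- read_bioc(bundle)
  }
  if (is.character(variant)) variant <- parse_hgvs(variant)
  vh <- answer_variant_hit(bundle, variant, cds, backend, config)
  it <- answer_in_trans(bundle, variant, cds, backend, config)

  summaries <- list()
  tbl_rows <- Filter(function(p) p$channel == "table", it$provenance)
  if (length(tbl_rows)) {
    ctx <- paste(vapply(tbl_rows, function(p)
      sprintf("%s, row %d: %s", p$table_label, p$row_index + 1L, p$row_text),
      character(1)), collapse = "\n")
    summaries$table <- complete(backend, backend_request("summarize", ctx))$text
  }

  report <- structure(list(
    schema_version = "pm3-report/1.0",
    doc_id = bundle$doc_id,
    query_variant = variant$raw,
    variant_hit = vh$variant_hit,
    in_trans = as.list(it$in_trans),
    provenance = list(variant_hit = vh$provenance, in_trans = it$provenance),
    summaries = summaries
  ), class = "pm3_report")

  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Validate the structure of a pipeline report
#'
#' @param report A `pm3_report` or a list parsed from report JSON.
#' @return `TRUE` invisibly; otherwise a `pm3_schema_error` naming the
#'   missing or ill-typed field.
#' @export
validate_report <- function(report) {
  required <- c("schema_version", "doc_id", "query_variant", "variant_hit",
                "in_trans", "provenance")
  for (f in required)
    if (is.null(report[[f]]))
      pm3_abort(sprintf("report is missing field '%s'", f), "pm3_schema_error")
  if (!is.logical(report$variant_hit) && !is.logical(unlist(report$variant_hit)))
    pm3_abort("report field 'variant_hit' must be logical", "pm3_schema_error")
  if (!isTRUE(unlist(report$variant_hit)) && length(report$in_trans))
    pm3_abort("report lists in trans candidates without a variant hit",
              "pm3_schema_error")
  invisible(TRUE)
}
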