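#' Retriever and pipeline configuration
#'
#' @param max_chunks Maximum number of chunks returned (default 5).
#' @param min_chunks_before_relax Relax to the next pattern tier when
#'   fewer than this many chunks match (default 1: relax only when
#'   nothing matched).
#' @param tolerance Numeric tolerance of the most relaxed tier (default 2).
#' @param chunk_size,overlap Chunking geometry in characters.
#' @param max_tables_per_batch Tables processed per batch (default 5).
#' @param table_channel,text_channel Enable/disable evidence channels.
#' @return A list of class `pm3_config`.
#' @export
pm3_config <- function(max_chunks = 5L, min_chunks_before_relax = 1L,
                       tolerance = 2L, chunk_size = 1500L, overlap = 100L,
                       max_tables_per_batch = 5L,
                       table_channel = TRUE, text_channel = TRUE) {
  if (max_chunks < 1L) pm3_abort("max_chunks must be >= 1", "pm3_domain_error")
  if (chunk_size <= overlap) pm3_abort("need chunk_size > overlap", "pm3_domain_error")
  structure(list(
    max_chunks = as.integer(max_chunks),
    min_chunks_before_relax = as.integer(min_chunks_before_relax),
    tolerance = as.integer(tolerance),
    chunk_size = as.integer(chunk_size),
    overlap = as.integer(overlap),
    max_tables_per_batch = as.integer(max_tables_per_batch),
    table_channel = isTRUE(table_channel),
    text_channel = isTRUE(text_channel)
  ), class = "pm3_config")
}

#' Retrieve variant-bearing chunks with a tiered pattern cascade
#'
#' Scans the chunks with the strict notation patterns first (`T0_full`).
#' Only when fewer than `min_chunks_before_relax` chunks match is the
#' cascade relaxed to standalone digit matching (`T1_digits`), and then
#' to the tolerant digit window (`T2_tolerant`). At most
#' `config$max_chunks` chunks are returned, earliest in the document
#' first; the cascade never ranks chunks. Matches found at the digit
#' tiers are positional-only evidence and are flagged low-confidence.
#'
#' @param chunks A `pm3_chunks` data.frame (see [split_text()]).
#' @param repset A `pm3_repset` from [augment_variant()].
#' @param config A [pm3_config()].
#' @return An object of class `pm3_retrieval`: list with `chunks` (the
#'   retained rows), `tier_used`, `matches` (per-chunk data.frames of
#'   offsets within the chunk), `low_confidence` (TRUE when a digit tier
#'   was used) and `tiers_scanned` (the tiers actually consulted).
#' @export
retrieve <- function(chunks, repset, config = pm3_config()) {
  stopifnot(inherits(repset, "pm3_repset"))
  tiers_scanned <- character(0)
  matched_idx <- integer(0)
  matches <- list()
  tier_used <- "T2_tolerant"

  for (tier in PM3_TIERS) {
    patset <- compile_patterns(repset, tier, tolerance = config$tolerance)
    tiers_scanned <- c(tiers_scanned, tier)
    matched_idx <- integer(0)
    matches <- list()
    if (nrow(chunks)) {
      for (i in seq_len(nrow(chunks))) {
        m <- pm3_scan(chunks$text[i], patset)
        if (nrow(m)) {
          matched_idx <- c(matched_idx, i)
          matches[[length(matches) + 1L]] <- m
        }
      }
    }
    tier_used <- tier
    if (length(matched_idx) >= config$min_chunks_before_relax) break
  }

  keep <- order(chunks$start[matched_idx])       # document order
  keep <- keep[seq_len(min(length(keep), config$max_chunks))]
  structure(list(
    chunks = chunks[matched_idx[keep], , drop = FALSE],
    tier_used = tier_used,
    matches = matches[keep],
    low_confidence = tier_used != "T0_full" && length(matched_idx) > 0L,
    tiers_scanned = tiers_scanned
  ), class = "pm3_retrieval")
}

#' @export
print.pm3_retrieval <- function(x, ...) {
  cat("<pm3_retrieval> ", nrow(x$chunks), " chunk(s) at tier ", x$tier_used,
      if (isTRUE(x$low_confidence)) " (positional-only, low confidence)",
      "\n", sep = "")
  invisible(x)
}
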