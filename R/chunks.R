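#' Split text into fixed-length overlapping chunks
#'
#' Splits a prose stream into chunks of at most `chunk_size` characters
#' for retrieval. Chunk boundaries prefer natural separators — paragraph
#' break, line break, sentence end, whitespace, in that order — searched
#' backwards from the size limit; when none is available the text is cut
#' hard at `chunk_size`. Consecutive chunks share `overlap` characters so
#' a mention falling on a boundary is still seen whole in one chunk.
#'
#' @param text A single string.
#' @param chunk_size Maximum chunk length in characters (default 1500).
#' @param overlap Characters shared by consecutive chunks (default 100).
#' @param sections Optional data.frame (`section`, `start`, `end`) giving
#'   0-based half-open spans, used to label each chunk with the section
#'   containing its start.
#' @return A data.frame of class `pm3_chunks`: `start`, `end` (0-based
#'   half-open offsets into `text`), `text`, `source_passage`.
#' @export
split_text <- function(text, chunk_size = 1500L, overlap = 100L, sections = NULL) {
  stopifnot(is_scalar_string(text) || identical(text, ""))
  chunk_size <- as.integer(chunk_size)
  overlap <- as.integer(overlap)
  if (!(chunk_size > overlap && overlap >= 0L))
    pm3_abort("need chunk_size > overlap >= 0", "pm3_domain_error")
  n <- nchar(text)
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), source_passage = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pm3_chunks", "data.frame")
  if (n == 0L) return(empty)

  separators <- c("\n\n", "\n", ". ", " ")
  starts <- integer(0)
  ends <- integer(0)
  start <- 1L                                    # 1-based while slicing
  repeat {
    end <- min(start + chunk_size - 1L, n)
    if (end < n) {
      window <- substr(text, start, end)
      for (sep in separators) {
        hits <- gregexpr(sep, window, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        cand <- start + hits + nchar(sep) - 2L   # chunk ends after the separator
        cand <- cand[cand >= start + overlap]    # guarantee forward progress
        if (length(cand)) { end <- max(cand); break }
      }
    }
    starts <- c(starts, start)
    ends <- c(ends, end)
    if (end >= n) break
    start <- end - overlap + 1L
  }

  labels <- rep("", length(starts))
  if (!is.null(sections) && nrow(sections)) {
    for (i in seq_along(starts)) {
      s0 <- starts[i] - 1L                       # 0-based chunk start
      j <- which(sections$start <= s0 & s0 < pmax(sections$end, sections$start + 1L))
      if (!length(j)) j <- max(which(sections$start <= s0))
      labels[i] <- sections$section[j[1]]
    }
  }

  out <- data.frame(start = starts - 1L, end = ends,
                    text = substring(text, starts, ends),
                    source_passage = labels, stringsAsFactors = FALSE)
  class(out) <- c("pm3_chunks", "data.frame")
  out
}

#' Chunk the prose of a parsed publication
#'
#' Concatenates the prose passages of a bundle (tables excluded) and
#' applies [split_text()], labelling each chunk with the section that
#' contains its start offset.
#'
#' @param bundle A `pm3_bundle` from [read_bioc()].
#' @inheritParams split_text
#' @return A `pm3_chunks` data.frame.
#' @export
chunk_bundle <- function(bundle, chunk_size = 1500L, overlap = 100L) {
  stopifnot(inherits(bundle, "pm3_bundle"))
  pr <- bundle_prose(bundle)
  split_text(pr$text, chunk_size, overlap, sections = pr$sections)
}
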