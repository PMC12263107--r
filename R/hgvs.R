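#' Parse an HGVS coding-level variant description
#'
#' Accepts the `<transcript>: c.<change>` form used in clinical variant
#' curation, e.g. `"NM_004004.5: c.71G>A"`, with or without the transcript
#' accession and with arbitrary whitespace around the colon. Substitutions
#' are parsed fully (position, reference and alternate base); duplications,
#' deletions, insertions and deletion-insertions are parsed positionally so
#' they can still be matched by coordinate.
#'
#' Genomic (`g.`), chromosome-prefixed, intronic-offset (`c.123+4`) and
#' UTR (`c.-12`, `c.*33`) descriptions are rejected with an
#' `pm3_unsupported_notation` error: such inputs cannot enter the
#' coding-coordinate pipeline.
#'
#' @param text A single HGVS string.
#' @return An object of class `pm3_variant`: a list with fields
#'   `transcript` (accession or `NA`), `cds_position` (1-based coding
#'   nucleotide), `end_position` (for ranged changes, else `NA`),
#'   `ref_base`, `alt_base`, `kind` (one of `"substitution"`,
#'   `"duplication"`, `"deletion"`, `"insertion"`, `"delins"`) and `raw`
#'   (the input, whitespace-normalised).
#' @examples
#' parse_hgvs("NM_004004.5: c.71G>A")
#' parse_hgvs("c.1813dup")
#' @export
parse_hgvs <- function(text) {
  if (!is_scalar_string(text) || !nzchar(trimws(text)))
    pm3_abort("variant description must be a non-empty string", "pm3_parse_error")
  raw <- trimws(text)

  if (grepl("(^|[:\\s])g\\.", raw, perl = TRUE) || grepl("^chr", raw, ignore.case = TRUE))
    pm3_abort(
      sprintf("unsupported notation (genomic/chromosome coordinates): '%s'", raw),
      "pm3_unsupported_notation"
    )

  transcript <- NA_character_
  body <- raw
  m <- regexec("^([A-Z]{2}_[0-9]+(?:\\.[0-9]+)?)\\s*:\\s*(.*)$", raw, perl = TRUE)
  g <- regmatches(raw, m)[[1]]
  if (length(g)) {
    transcript <- g[2]
    body <- g[3]
  }
  body <- gsub("\\s+", "", body)

  if (grepl("^c\\.[-*]", body, perl = TRUE) || grepl("^c\\.[0-9]+[+-][0-9]", body, perl = TRUE))
    pm3_abort(
      sprintf("unsupported notation (UTR/intronic coordinates): '%s'", raw),
      "pm3_unsupported_notation"
    )

  pats <- list(
    substitution = "^c\\.([0-9]+)([ACGT])>([ACGT])$",
    delins       = "^c\\.([0-9]+)(?:_([0-9]+))?delins([ACGT]+)$",
    duplication  = "^c\\.([0-9]+)(?:_([0-9]+))?dup([ACGT]*)$",
    deletion     = "^c\\.([0-9]+)(?:_([0-9]+))?del([ACGT]*)$",
    insertion    = "^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$"
  )

  for (kind in names(pats)) {
    g <- regmatches(body, regexec(pats[[kind]], body, perl = TRUE))[[1]]
    if (!length(g)) next
    pos <- as.integer(g[2])
    if (is.na(pos) || pos < 1L)
      pm3_abort("coding position must be a positive integer", "pm3_parse_error")
    v <- structure(list(
      transcript   = transcript,
      cds_position = pos,
      end_position = NA_integer_,
      ref_base     = NA_character_,
      alt_base     = NA_character_,
      kind         = kind,
      raw          = if (is.na(transcript)) body else paste0(transcript, ":", body)
    ), class = "pm3_variant")
    if (kind == "substitution") {
      if (g[3] == g[4])
        pm3_abort("substitution reference and alternate base are identical", "pm3_parse_error")
      v$ref_base <- g[3]
      v$alt_base <- g[4]
    } else {
      if (length(g) >= 3 && nzchar(g[3]) && grepl("^[0-9]+$", g[3]))
        v$end_position <- as.integer(g[3])
      if (kind %in% c("insertion", "delins")) v$alt_base <- g[length(g)]
      if (kind %in% c("deletion", "duplication") && nzchar(g[length(g)]))
        v$ref_base <- g[length(g)]
    }
    return(v)
  }
  pm3_abort(sprintf("cannot parse variant description: '%s'", raw), "pm3_unsupported_notation")
}

#' @export
print.pm3_variant <- function(x, ...) {
  cat("<pm3_variant> ", x$raw, "\n", sep = "")
  cat("  kind: ", x$kind, ", coding position: ", x$cds_position, sep = "")
  if (!is.na(x$ref_base) && !is.na(x$alt_base) && x$kind == "substitution")
    cat(" (", x$ref_base, ">", x$alt_base, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Map a coding nucleotide position to its codon
#'
#' @param cds_position 1-based coding nucleotide position.
#' @return A list with `codon` (1-based codon index, `ceiling(pos/3)`) and
#'   `offset` (1, 2 or 3: position of the nucleotide within the codon).
#' @examples
#' codon_index(274) # codon 92, first base
#' @export
codon_index <- function(cds_position) {
  if (!is.numeric(cds_position) || length(cds_position) != 1L ||
      is.na(cds_position) || cds_position < 1 || cds_position != floor(cds_position))
    pm3_abort("cds_position must be a positive integer", "pm3_domain_error")
  pos <- as.integer(cds_position)
  codon <- (pos - 1L) %/% 3L + 1L
  list(codon = codon, offset = pos - 3L * (codon - 1L))
}

# one-letter -> three-letter amino-acid codes; "*" renders as Ter
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) pm3_abort(sprintf("not a DNA codon: '%s'", codon), "pm3_domain_error")
  aa
}

#' Derive the protein-level consequence of a coding substitution
#'
#' Reads the affected codon from a user-supplied coding sequence (which must
#' start at coding position 1), applies the substitution at the in-codon
#' offset, and translates both codons with the standard genetic code. A stop
#' codon renders as `Ter` (three-letter) / `*` (one-letter).
#'
#' @param v A `pm3_variant` of kind `"substitution"`.
#' @param cds Coding DNA sequence as a single string (or anything
#'   coercible via `as.character`), beginning at coding position 1.
#' @return An object of class `pm3_protein_change`: list with
#'   `codon_index`, `ref_aa3`, `alt_aa3`, `ref_aa1`, `alt_aa1`.
#' @export
translate_protein_change <- function(v, cds) {
  stopifnot(inherits(v, "pm3_variant"))
  if (v$kind != "substitution")
    pm3_abort("protein translation is only defined for substitutions", "pm3_domain_error")
  cds <- toupper(as.character(cds))
  ci <- codon_index(v$cds_position)
  codon_end <- 3L * ci$codon
  if (nchar(cds) < codon_end)
    pm3_abort(
      sprintf("coding sequence too short (%d nt) for position %d", nchar(cds), v$cds_position),
      "pm3_out_of_range"
    )
  have <- substr(cds, v$cds_position, v$cds_position)
  if (have != v$ref_base)
    pm3_abort(
      sprintf("reference mismatch at c.%d: CDS has '%s', variant expects '%s'",
              v$cds_position, have, v$ref_base),
      "pm3_reference_mismatch"
    )
  ref_codon <- substr(cds, codon_end - 2L, codon_end)
  alt_codon <- ref_codon
  substr(alt_codon, ci$offset, ci$offset) <- v$alt_base
  ref1 <- translate_codon(ref_codon)
  alt1 <- translate_codon(alt_codon)
  structure(list(
    codon_index = ci$codon,
    ref_aa3 = AA_THREE[[ref1]], alt_aa3 = AA_THREE[[alt1]],
    ref_aa1 = ref1, alt_aa1 = alt1
  ), class = "pm3_protein_change")
}

#' @export
print.pm3_protein_change <- function(x, ...) {
  cat("<pm3_protein_change> p.", x$ref_aa3, x$codon_index, x$alt_aa3,
      " (", x$ref_aa1, x$codon_index, x$alt_aa1, ")\n", sep = "")
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' The file must contain a single record; its sequence is taken as the
#' coding sequence starting at coding position 1.
#'
#' @param path Path to a FASTA file.
#' @return The coding sequence as a single uppercase string.
#' @export
read_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    pm3_abort("CDS FASTA must contain exactly one record", "pm3_parse_error")
  toupper(as.character(seqs[[1]]))
}
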