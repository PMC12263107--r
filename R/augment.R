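variant_body <- function(v) sub("^.*:", "", v$raw)

#' Expand a variant into all of its textual representations
#'
#' Publications describe the same variant in many ways: the coding DNA
#' notation (`c.274G>T`), with or without a transcript prefix, the
#' protein change (`Asp92Tyr`, `p.(Asp92Tyr)`) and its one-letter
#' shorthand (`D92Y`). This function generates the full representation
#' set for a query variant so that downstream matching covers all of
#' them. Protein-level forms require a coding sequence and are generated
#' for substitutions only; stop gains are spelled with both `*` and `X`
#' (`W24*` / `W24X`), as journals use either.
#'
#' @param v A `pm3_variant` (see [parse_hgvs()]) or an HGVS string.
#' @param cds Optional coding sequence (string or FASTA path via
#'   [read_cds()]) starting at coding position 1.
#' @return An object of class `pm3_repset`: list with `variant`,
#'   `dna_forms`, `protein_forms` (empty without a CDS), `positions`
#'   (coding position plus, when protein forms exist, the codon index)
#'   and `protein` (the `pm3_protein_change`, or `NULL`).
#' @examples
#' augment_variant(parse_hgvs("c.1813dup"))
#' @export
augment_variant <- function(v, cds = NULL) {
  if (is.character(v)) v <- parse_hgvs(v)
  stopifnot(inherits(v, "pm3_variant"))
  body <- variant_body(v)

  dna <- body
  if (!is.na(v$transcript)) dna <- c(dna, paste0(v$transcript, ":", body))
  if (v$kind == "substitution")
    dna <- c(dna, sprintf("%d%s>%s", v$cds_position, v$ref_base, v$alt_base))

  protein_forms <- character(0)
  pc <- NULL
  if (!is.null(cds) && v$kind == "substitution") {
    if (is_scalar_string(cds) && file.exists(cds) && !grepl("^[ACGTNacgtn]+$", cds))
      cds <- read_cds(cds)
    pc <- translate_protein_change(v, cds)
    long3 <- paste0(pc$ref_aa3, pc$codon_index, pc$alt_aa3)
    short1 <- paste0(pc$ref_aa1, pc$codon_index, pc$alt_aa1)
    protein_forms <- c(
      paste0("p.(", long3, ")"), paste0("p.", long3), long3, short1
    )
    # every "*" spelling gets its "X" twin and vice versa
    starred <- grepl("*", protein_forms, fixed = TRUE)
    if (any(starred))
      protein_forms <- c(protein_forms, gsub("*", "X", protein_forms[starred], fixed = TRUE))
  }

  positions <- v$cds_position
  if (length(protein_forms)) positions <- c(positions, pc$codon_index)

  structure(list(
    variant = v,
    dna_forms = unique(dna),
    protein_forms = unique(protein_forms),
    positions = unique(as.integer(positions)),
    protein = pc
  ), class = "pm3_repset")
}

#' @export
print.pm3_repset <- function(x, ...) {
  cat("<pm3_repset> for ", x$variant$raw, "\n", sep = "")
  cat("  DNA forms:     ", paste(x$dna_forms, collapse = ", "), "\n", sep = "")
  if (length(x$protein_forms))
    cat("  protein forms: ", paste(x$protein_forms, collapse = ", "), "\n", sep = "")
  cat("  positions:     ", paste(x$positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

all_forms <- function(r) c(r$dna_forms, r$protein_forms)
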