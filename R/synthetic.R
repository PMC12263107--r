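xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Generate a random coding sequence with pinned codons
#'
#' Produces a seeded random CDS that starts with ATG, ends with a stop
#' codon, contains no premature stop outside pinned sites, and honours
#' `pins`: a named list mapping codon index to the exact codon required
#' there (e.g. `list("92" = "GAC")` so that coding position 274 is `G`).
#'
#' @param n_codons Total number of codons including start and stop.
#' @param pins Named list of codon pins; conflicting duplicate pins are
#'   an error.
#' @param seed Integer seed; the same seed yields the same sequence.
#' @return The CDS as a single uppercase string of length `3 * n_codons`.
#' @export
generate_cds <- function(n_codons, pins = list(), seed = 1L) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 2L) pm3_abort("need at least start and stop codons", "pm3_domain_error")
  if (length(pins)) {
    idx <- as.integer(names(pins))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_codons))
      pm3_abort("pin indices must be codon numbers within the CDS", "pm3_domain_error")
    vals <- toupper(unlist(pins))
    if (!all(grepl("^[ACGT]{3}$", vals)))
      pm3_abort("pinned codons must be DNA triplets", "pm3_domain_error")
    for (d in unique(idx[duplicated(idx)])) {
      if (length(unique(vals[idx == d])) > 1L)
        pm3_abort(sprintf("conflicting pins for codon %d", d), "pm3_pin_conflict")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  if (length(pins))
    codons[as.integer(names(pins))] <- toupper(unlist(pins))
  paste(codons, collapse = "")
}

#' Specification of a synthetic publication
#'
#' Describes one emulated case-report publication: how many patients it
#' reports, which variant the affected patient carries (optionally with
#' an in trans partner on the other allele), whether the variant is
#' mentioned in prose, in a genotype table, or both, and whether
#' decimal-fraction decoys embedding the variant position are planted.
#'
#' @param query_variant HGVS string of the query variant.
#' @param in_trans_variant Optional HGVS string of the in trans partner.
#' @param n_patients Number of patients reported (default 4).
#' @param mention_channels Subset of `c("text", "table")`; empty means
#'   the variant is absent from the publication.
#' @param trap_decimals Plant frequency-style cells/sentences embedding
#'   the query position inside a decimal (e.g. `0.93884` for 388).
#' @param table_layout `"one_row_per_patient"` (allele columns) or
#'   `"one_row_per_allele"` (adjacent rows per patient).
#' @param seed Integer seed driving all randomised choices.
#' @return A list of class `pm3_fixture_spec`.
#' @export
fixture_spec <- function(query_variant, in_trans_variant = NULL, n_patients = 4L,
                         mention_channels = c("text", "table"),
                         trap_decimals = FALSE,
                         table_layout = c("one_row_per_patient", "one_row_per_allele"),
                         seed = 1L) {
  table_layout <- match.arg(table_layout)
  if (length(mention_channels))
    mention_channels <- match.arg(mention_channels, c("text", "table"), several.ok = TRUE)
  structure(list(
    query_variant = query_variant,
    in_trans_variant = in_trans_variant,
    n_patients = as.integer(n_patients),
    mention_channels = mention_channels,
    trap_decimals = isTRUE(trap_decimals),
    table_layout = table_layout,
    seed = as.integer(seed)
  ), class = "pm3_fixture_spec")
}

ID_STYLES <- list(
  function(i) paste0("P", i),
  function(i) paste0("II-", i),
  function(i) sprintf("Family %d, Pt 1", i)
)

ALLELE_HEADERS <- list(
  c("Allele 1", "Allele 2"),
  c("Nucleotide change 1", "Nucleotide change 2"),
  c("Maternal allele", "Paternal allele")
)

GENE_POOL <- c("GJB2", "BRCA2", "CFTR", "MYO7A", "USH2A", "ABCA4")

random_filler_variant <- function(excluded) {
  repeat {
    pos <- sample(30:1950, 1)
    if (!any(abs(pos - excluded) <= 3)) break
  }
  bases <- sample(c("A", "C", "G", "T"), 2, replace = FALSE)
  sprintf("c.%d%s>%s", pos, bases[1], bases[2])
}

#' Generate a synthetic BioC publication with known ground truth
#'
#' Emits a BioC XML document emulating a rare-disease case report:
#' title, introduction and results prose, and (per the spec) a genotype
#' table keyed by patient identifiers in its first column. Patient-ID
#' styles and allele column names are drawn per seed from pools of
#' conventions seen in genotype tables, so the table engine is not tuned
#' to one dialect. The returned truth record states exactly what was
#' planted; with the same spec and seed the XML is byte-identical.
#'
#' @param spec A [fixture_spec()].
#' @return List with `xml` (BioC XML string) and `truth` (list:
#'   `variant_hit`, `in_trans`, `patient_ids`).
#' @export
generate_publication <- function(spec) {
  stopifnot(inherits(spec, "pm3_fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  qv <- parse_hgvs(spec$query_variant)
  itv <- if (!is.null(spec$in_trans_variant)) parse_hgvs(spec$in_trans_variant)
  q_body <- variant_body(qv)
  it_body <- if (!is.null(itv)) variant_body(itv)

  excluded <- c(qv$cds_position, codon_index(qv$cds_position)$codon)
  if (!is.null(itv))
    excluded <- c(excluded, itv$cds_position, codon_index(itv$cds_position)$codon)

  gene <- sample(GENE_POOL, 1)
  id_of <- ID_STYLES[[sample(length(ID_STYLES), 1)]]
  allele_cols <- ALLELE_HEADERS[[sample(length(ALLELE_HEADERS), 1)]]
  aff <- sample(spec$n_patients, 1)
  ids <- vapply(seq_len(spec$n_patients), id_of, character(1))
  fillers <- lapply(seq_len(spec$n_patients), function(i)
    c(random_filler_variant(excluded), random_filler_variant(excluded)))

  has_text <- "text" %in% spec$mention_channels
  has_table <- "table" %in% spec$mention_channels
  hit <- has_text || has_table
  allele2 <- if (!is.null(it_body)) it_body else q_body

  title <- sprintf("Novel biallelic %s variants in a cohort of %d patients with hereditary disease",
                   gene, spec$n_patients)
  intro <- sprintf(paste0(
    "We ascertained %d unrelated patients with a clinical presentation ",
    "consistent with an autosomal recessive disorder. Genomic DNA was ",
    "extracted from peripheral blood and the coding exons of %s were ",
    "sequenced in all probands. Segregation of candidate variants was ",
    "confirmed in available parents."), spec$n_patients, gene)

  results_parts <- character(0)
  if (has_text) {
    results_parts <- if (!is.null(it_body))
      sprintf(paste0("Patient %s was compound heterozygous for %s and %s; ",
                     "the %s variant was found in trans with %s by parental testing."),
              ids[aff], spec$query_variant, it_body, q_body, it_body)
    else
      sprintf("Patient %s carried the %s variant in the homozygous state.",
              ids[aff], spec$query_variant)
  } else {
    results_parts <- sprintf(paste0("Sequencing identified biallelic candidate ",
                                    "variants in all %d patients; per-patient ",
                                    "genotypes are summarized in Table 1."),
                             spec$n_patients)
  }
  if (spec$trap_decimals)
    results_parts <- c(results_parts,
                       sprintf("The cumulative minor allele frequency in controls was 0.9%d4.",
                               qv$cds_position))
  results <- paste(results_parts, collapse = " ")

  tables <- list()
  if (has_table) {
    if (spec$table_layout == "one_row_per_patient") {
      header <- c("Patient", allele_cols, "Zygosity")
      rows <- lapply(seq_len(spec$n_patients), function(i) {
        if (i == aff)
          c(ids[i], q_body, allele2,
            if (is.null(it_body)) "homozygous" else "compound heterozygous")
        else c(ids[i], fillers[[i]][1], fillers[[i]][2], "compound heterozygous")
      })
    } else {
      header <- c("Patient", "Nucleotide change", "Status")
      repeat_id <- sample(c(TRUE, FALSE), 1)
      rows <- list()
      for (i in seq_len(spec$n_patients)) {
        a <- if (i == aff) c(q_body, allele2) else fillers[[i]]
        rows[[length(rows) + 1L]] <- c(ids[i], a[1], "affected")
        rows[[length(rows) + 1L]] <- c(if (repeat_id) ids[i] else "", a[2], "affected")
      }
    }
    tables[[1]] <- list(label = "Table 1", caption = "Genotypes of the study patients",
                        header = header, rows = rows)
  }
  if (spec$trap_decimals) {
    freq <- sprintf("0.9%d4", qv$cds_position)
    tables[[length(tables) + 1L]] <- list(
      label = sprintf("Table %d", length(tables) + 1L),
      caption = "Allele frequencies in reference populations",
      header = c("Population", "Frequency"),
      rows = list(c("European", freq), c("East Asian", sprintf("0.00%d1", qv$cds_position)))
    )
  }

  doc_id <- sprintf("SYN%07d", spec$seed %% 10000000L)
  passage <- function(type, section, text) {
    sprintf(paste0("  <passage><infon key=\"type\">%s</infon>",
                   "<infon key=\"section_type\">%s</infon>",
                   "<offset>0</offset><text>%s</text></passage>"),
            type, section, xml_escape(text))
  }
  body <- c(
    passage("front", "TITLE", title),
    passage("paragraph", "INTRO", intro),
    passage("paragraph", "RESULTS", results)
  )
  for (tb in tables) {
    grid <- paste(c(paste(tb$header, collapse = "\t"),
                    vapply(tb$rows, paste, character(1), collapse = "\t")),
                  collapse = "\n")
    body <- c(body,
      sprintf(paste0("  <passage><infon key=\"type\">table_caption</infon>",
                     "<infon key=\"table_label\">%s</infon>",
                     "<offset>0</offset><text>%s</text></passage>"),
              tb$label, xml_escape(tb$caption)),
      sprintf(paste0("  <passage><infon key=\"type\">table</infon>",
                     "<infon key=\"table_label\">%s</infon>",
                     "<offset>0</offset><text>%s</text></passage>"),
              tb$label, xml_escape(grid)))
  }
  xml <- paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<collection><source>pm3miner-synthetic</source>",
    sprintf("<document><id>%s</id>", doc_id),
    body,
    "</document></collection>"
  ), collapse = "\n")

  truth <- list(
    variant_hit = hit,
    in_trans = if (hit && !is.null(it_body)) it_body else character(0),
    patient_ids = if (hit) ids[aff] else character(0)
  )
  list(xml = xml, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits `doc.xml` (BioC), `truth.json` and, when `cds` is given,
#' `cds.fa` under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param cds Optional coding sequence string to write as FASTA.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(spec, dir, cds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_publication(spec)
  xml_path <- file.path(dir, "doc.xml")
  writeLines(gen$xml, xml_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(gen$truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(xml_path, truth_path)
  if (!is.null(cds)) {
    fa <- file.path(dir, "cds.fa")
    writeLines(c(">synthetic_cds", cds), fa)
    paths <- c(paths, fa)
  }
  invisible(paths)
}
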