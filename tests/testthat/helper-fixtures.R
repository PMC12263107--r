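# CDS whose codon 92 is GAC, so c.274G>T is Asp92Tyr / D92Y
fixture_cds <- function(pins = list("92" = "GAC"), n_codons = 120L, seed = 1L) {
  generate_cds(n_codons, pins = pins, seed = seed)
}

# CDS whose codon 24 is TGG, so c.71G>A is Trp24Ter / W24*
fixture_cds_stop <- function() {
  generate_cds(60L, pins = list("24" = "TGG"), seed = 3L)
}

# hand-built BioC document: 3 prose passages, 2 tables (the second with a
# short row, for the padding rule)
fixture_bioc_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<collection><source>fixture</source>\n",
    "<document><id>PMC0000001</id>\n",
    '<passage><infon key="type">front</infon><infon key="section_type">TITLE</infon>',
    "<offset>0</offset><text>Biallelic variants in a deafness cohort</text></passage>\n",
    '<passage><infon key="type">paragraph</infon><infon key="section_type">INTRO</infon>',
    "<offset>0</offset><text>We studied three families with hearing loss.</text></passage>\n",
    '<passage><infon key="type">paragraph</infon><infon key="section_type">RESULTS</infon>',
    "<offset>0</offset><text>Patient P1 carried c.71G&gt;A in trans with c.35delG.</text></passage>\n",
    '<passage><infon key="type">table_caption</infon><infon key="table_label">Table 1</infon>',
    "<offset>0</offset><text>Genotypes</text></passage>\n",
    '<passage><infon key="type">table</infon><infon key="table_label">Table 1</infon>',
    "<offset>0</offset><text>Patient\tAllele 1\tAllele 2\n",
    "P1\tc.71G&gt;A\tc.35delG\nP2\tc.167delT\tc.167delT</text></passage>\n",
    '<passage><infon key="type">table</infon><infon key="table_label">Table 2</infon>',
    "<offset>0</offset><text>Patient\tVariant\tFrequency\tNote\n",
    "P1\tc.9999A&gt;G\t0.93884</text></passage>\n",
    "</document></collection>\n"
  )
}

# a genotype-style pm3_table built directly
make_table <- function(label, header, rows) {
  xml <- paste0(
    '<collection><document><id>T</id>',
    '<passage><infon key="type">table</infon><infon key="table_label">', label,
    "</infon><offset>0</offset><text>",
    paste(c(paste(header, collapse = "\t"),
            vapply(rows, paste, character(1), collapse = "\t")), collapse = "\n"),
    "</text></passage></document></collection>"
  )
  read_bioc(xml)$tables[[1]]
}

# benchmark fixture: five synthetic publications matching
# inst/extdata/bench-example.json (doc_id SYN00001xx <- seed 1xx)
bench_specs <- function() {
  list(
    list(seed = 101L, query = "NM_004004.5: c.71G>A", it = "c.35delG",
         channels = c("text", "table"), layout = "one_row_per_patient", trap = FALSE),
    list(seed = 102L, query = "c.274G>T", it = "c.1813dup",
         channels = "table", layout = "one_row_per_allele", trap = FALSE),
    list(seed = 103L, query = "NM_000059.4: c.7796A>G", it = "c.1813dup",
         channels = "text", layout = "one_row_per_patient", trap = FALSE),
    list(seed = 104L, query = "c.1520T>C", it = NULL,
         channels = c("text", "table"), layout = "one_row_per_patient", trap = TRUE),
    list(seed = 105L, query = "c.902A>T", it = "c.101G>C",
         channels = c("text", "table"), layout = "one_row_per_allele", trap = FALSE)
  )
}

bench_corpus <- function() {
  out <- list()
  for (s in bench_specs()) {
    sp <- fixture_spec(s$query, s$it, mention_channels = s$channels,
                       trap_decimals = s$trap, table_layout = s$layout,
                       seed = s$seed)
    b <- read_bioc(generate_publication(sp)$xml)
    out[[b$doc_id]] <- b
  }
  out
}

bench_file <- function() {
  system.file("extdata", "bench-example.json", package = "pm3miner")
}

# brute-force oracle for standalone digit runs: enumerate maximal digit
# runs and compare them as strings to the queried number
brute_standalone <- function(text, n) {
  m <- gregexpr("[0-9]+", text)[[1]]
  if (m[1] == -1L) return(FALSE)
  len <- attr(m, "match.length")
  runs <- substring(text, m, m + len - 1L)
  prev1 <- ifelse(m > 1L, substring(text, m - 1L, m - 1L), "")
  prev2 <- ifelse(m > 2L, substring(text, m - 2L, m - 2L), "")
  decimal_tail <- prev1 == "." & grepl("^[0-9]$", prev2)
  any(runs == as.character(n) & !decimal_tail)
}

random_text <- function(len, seed) {
  set.seed(seed)
  paste(sample(c(letters, " ", ".", ",", as.character(0:9), "c", ">", "("),
               len, replace = TRUE), collapse = "")
}
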