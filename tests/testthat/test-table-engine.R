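genotype_table <- function() {
  make_table("Table 1", c("Patient", "Allele 1", "Allele 2"),
             list(c("P1", "c.274G>T", "c.35delG"),
                  c("P2", "c.167delT", "c.167delT"),
                  c("P3", "c.1520T>C", "c.101G>C")))
}

allele_rows_table <- function() {
  make_table("Table 1", c("Patient", "Nucleotide change", "Status"),
             list(c("P1", "c.900A>G", "affected"),
                  c("",  "c.35delG", "affected"),
                  c("P2", "c.274G>T", "affected"),
                  c("",  "c.1813dup", "affected"),
                  c("P3", "c.101G>C", "affected")))
}

test_that("the store keeps every row and round-trips cells verbatim", {
  tb1 <- genotype_table()
  tb2 <- make_table("Table 2", c("Population", "Frequency", "Note", "Extra"),
                    list(c("EUR", "0.93884", "x", "y"),
                         c("EAS", "0.00021", "", ""),
                         c("AFR", "1e-4", "", ""),
                         c("SAS", "0", "", "")))
  store <- load_tables(list(tb1, tb2))
  expect_length(store$relations, 2)
  expect_equal(sum(vapply(store$relations, function(r) nrow(r$data), integer(1))), 7)
  expect_identical(store$relations[[1]]$data[[2]][1], "c.274G>T")

  tb3 <- make_table("Table 3", c("A"), list(c("c.71G>A;c.35delG")))
  s3 <- load_tables(list(tb3))
  expect_identical(s3$relations[[1]]$data[[1]][1], "c.71G>A;c.35delG")

  d <- tempfile()
  paths <- export_store(store, d)
  expect_true(all(file.exists(paths)))
  back <- utils::read.table(paths[1], sep = "\t", header = TRUE,
                            colClasses = "character")
  expect_identical(back[[2]], store$relations[[1]]$data[[2]])
})

test_that("headers sanitize to unique lower-case column names", {
  expect_identical(sanitize_names(c("", "Allele 1", "Allele 1")),
                   c("col_1", "allele_1", "allele_1_2"))
  expect_identical(sanitize_names(c("Patient ID", "HGVS (cDNA)")),
                   c("patient_id", "hgvs_cdna"))
})

test_that("position-guided queries are generated and unsafe SQL falls back", {
  store <- load_tables(list(genotype_table()))
  rel <- store$relations[[1]]
  q <- generate_position_query(rel, c(274L, 92L))
  expect_equal(q$source, "template")
  expect_true(grepl("SELECT \\* FROM table_1 WHERE", q$sql))
  expect_true(all(c("274", "92") %in% q$clauses$needle))

  # a backend emitting a write statement is rejected in favour of the template
  assign("complete.canned_sql",
         function(backend, request)
           structure(list(verdict = "n/a", extracted_variants = character(0),
                          rationale_span = "", text = backend$sql),
                     class = "pm3_answer"),
         envir = globalenv())
  withr::defer(rm("complete.canned_sql", envir = globalenv()))
  canned_sql_backend <- function(sql)
    structure(list(sql = sql), class = c("canned_sql", "pm3_backend"))
  qb <- generate_position_query(rel, 274L, backend = canned_sql_backend("DROP TABLE table_1"))
  expect_equal(qb$source, "template")
  qg <- generate_position_query(rel, 274L, backend = canned_sql_backend(
    "SELECT * FROM table_1 WHERE allele_1 LIKE '%274%'"))
  expect_equal(qg$source, "backend")
  expect_equal(qg$clauses$column, "allele_1")

  expect_false(pm3miner:::is_valid_position_query("DROP TABLE table_1", rel))
  expect_false(pm3miner:::is_valid_position_query(
    "SELECT * FROM table_1 WHERE patient LIKE '%274%'; DELETE FROM table_1", rel))
  expect_false(pm3miner:::is_valid_position_query(
    "SELECT * FROM other WHERE patient LIKE '%274%'", rel))
  expect_true(pm3miner:::is_valid_position_query(
    "SELECT * FROM table_1 WHERE allele_1 LIKE '%274%' OR allele_2 LIKE '%274%'", rel))

  one_col <- load_tables(list(make_table("Table 9", c("Variant"),
                                         list(c("c.71G>A")))))$relations[[1]]
  q2 <- generate_position_query(one_col, 71L)
  expect_equal(nrow(q2$clauses), 1)
  expect_equal(q2$clauses$column, "variant")
})

test_that("the digit post-filter separates notation from statistical digits", {
  expect_false(position_postfilter("frequency is 0.93884", 388))
  expect_true(position_postfilter("c.388A>G", 388))
  expect_false(position_postfilter("rs3885", 388))
})

test_that("variant rows are found with notation or position-only confidence", {
  rs <- augment_variant(parse_hgvs("c.274G>T"), fixture_cds())
  store <- load_tables(list(genotype_table()))
  hits <- find_variant_rows(store, rs)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$confidence, "notation")
  expect_equal(hits[[1]]$row_index, 0L)
  expect_equal(hits[[1]]$patient_id, "P1")

  pos_tab <- make_table("Table 1", c("Patient", "Position", "Effect"),
                        list(c("P1", "274", "missense"),
                             c("P2", "0.92744", "")))
  hits2 <- find_variant_rows(load_tables(list(pos_tab)), rs)
  expect_length(hits2, 1)
  expect_equal(hits2[[1]]$confidence, "position_only")
  expect_equal(hits2[[1]]$patient_id, "P1")

  trap_tab <- make_table("Table 1", c("Population", "Frequency"),
                         list(c("EUR", "0.93884")))
  rs388 <- augment_variant(parse_hgvs("c.388A>G"))
  expect_length(find_variant_rows(load_tables(list(trap_tab)), rs388), 0)
})

test_that("same-patient neighbour rows are extracted as the contiguous ID block", {
  rs <- augment_variant(parse_hgvs("c.274G>T"))
  store <- load_tables(list(allele_rows_table()))
  hits <- find_variant_rows(store, rs)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$row_index, 2L)
  sib <- extract_in_trans_rows(store, hits[[1]])
  expect_length(sib, 1)
  expect_equal(sib[[1]]$row_index, 3L)
  expect_true(grepl("c.1813dup", paste(sib[[1]]$row_cells, collapse = " ")))

  # singleton patient row: empty block
  store2 <- load_tables(list(genotype_table()))
  h2 <- find_variant_rows(store2, rs)
  expect_length(extract_in_trans_rows(store2, h2[[1]]), 0)

  # hit in the middle of a three-row block returns both sides
  tb <- make_table("Table 1", c("ID", "Variant"),
                   list(c("F1", "c.10A>G"), c("P1", "c.1A>G"), c("P1", "c.274G>T"),
                        c("P1", "c.35delG"), c("F2", "c.20A>G")))
  st <- load_tables(list(tb))
  h <- find_variant_rows(st, rs)
  expect_length(h, 1)
  sib3 <- extract_in_trans_rows(st, h[[1]])
  expect_equal(vapply(sib3, function(x) x$row_index, integer(1)), c(1L, 3L))
})

test_that("ID blocks respect the merged-cell convention and flag stray equal IDs", {
  tb <- make_table("Table 1", c("ID", "Variant"),
                   list(c("P1", "c.274G>T"), c("", "c.35delG"),
                        c("P2", "c.10A>G"), c("P1", "c.999A>G")))
  st <- load_tables(list(tb))
  h <- find_variant_rows(st, augment_variant(parse_hgvs("c.274G>T")))
  sib <- extract_in_trans_rows(st, h[[1]])
  expect_equal(vapply(sib, function(x) x$row_index, integer(1)), 1L)
  stray <- attr(sib, "noncontiguous")
  expect_length(stray, 1)
  expect_equal(stray[[1]]$row_index, 3L)
})

test_that("batching preserves order, size caps, and result equivalence", {
  mk <- function(i) make_table(sprintf("Table %02d", i), c("ID", "Variant"),
                               list(c(paste0("P", i),
                                      if (i %% 3 == 0) "c.274G>T" else sprintf("c.%dA>G", 500 + i))))
  tables7 <- lapply(1:7, mk)
  expect_equal(lengths(batch_tables(tables7, 5)), c(5L, 2L))
  expect_equal(lengths(batch_tables(lapply(1:5, mk), 5)), 5L)
  expect_equal(lengths(batch_tables(lapply(1:12, mk), 5)), c(5L, 5L, 2L))

  rs <- augment_variant(parse_hgvs("c.274G>T"))
  whole <- find_variant_rows(load_tables(tables7), rs)
  batched <- unlist(lapply(batch_tables(tables7, 5), function(b)
    find_variant_rows(load_tables(b), rs)), recursive = FALSE)
  key <- function(h) paste(h$table_label, h$row_index, h$confidence)
  expect_setequal(vapply(whole, key, character(1)),
                  vapply(batched, key, character(1)))
})

test_that("batching equivalence holds on randomized table sets", {
  for (rep in 1:5) {
    set.seed(300 + rep)
    n <- sample(6:11, 1)
    tables <- lapply(seq_len(n), function(i) {
      rows <- lapply(seq_len(sample(1:4, 1)), function(j)
        c(sprintf("P%d", j),
          sprintf("c.%d%s>%s", sample(c(274, 500:520), 1), "A", "G"),
          sprintf("0.9%d4", 274)))
      make_table(sprintf("Table %02d", i), c("ID", "Variant", "Freq"), rows)
    })
    rs <- augment_variant(parse_hgvs("c.274A>G"))
    key <- function(h) paste(h$table_label, h$row_index, h$confidence)
    whole <- vapply(find_variant_rows(load_tables(tables), rs), key, character(1))
    batched <- vapply(unlist(lapply(batch_tables(tables, 5), function(b)
      find_variant_rows(load_tables(b), rs)), recursive = FALSE), key, character(1))
    expect_setequal(whole, batched)
  }
})
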