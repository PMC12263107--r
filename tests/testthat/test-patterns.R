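test_that("augmentation generates DNA, protein and shorthand representations", {
  rs <- augment_variant(parse_hgvs("c.274G>T"), fixture_cds())
  expect_true(all(c("c.274G>T", "Asp92Tyr", "D92Y") %in%
                    c(rs$dna_forms, rs$protein_forms)))
  expect_true("c.274G>T" %in% rs$dna_forms)
  expect_setequal(rs$positions, c(274L, 92L))

  # stop gain is spelled with both the asterisk and X
  rs2 <- augment_variant(parse_hgvs("c.71G>A"), fixture_cds_stop())
  expect_true(all(c("W24*", "W24X") %in% rs2$protein_forms))

  # transcript-prefixed form is kept when a transcript is given
  rs3 <- augment_variant(parse_hgvs("NM_004004.5: c.71G>A"))
  expect_true("NM_004004.5:c.71G>A" %in% rs3$dna_forms)

  # no CDS: DNA forms only
  rs4 <- augment_variant(parse_hgvs("c.1813dup"))
  expect_length(rs4$protein_forms, 0)
  expect_true("c.1813dup" %in% rs4$dna_forms)
  expect_true(1813L %in% rs4$positions)
})

test_that("X and asterisk protein forms come in matched pairs", {
  rs <- augment_variant(parse_hgvs("c.71G>A"), fixture_cds_stop())
  with_x <- grep("X", rs$protein_forms, fixed = TRUE, value = TRUE)
  for (f in with_x)
    expect_true(gsub("X", "*", f, fixed = TRUE) %in% rs$protein_forms, label = f)
  with_star <- grep("*", rs$protein_forms, fixed = TRUE, value = TRUE)
  for (f in with_star)
    expect_true(gsub("*", "X", f, fixed = TRUE) %in% rs$protein_forms, label = f)
})

test_that("full-notation patterns tolerate whitespace, parentheses and X/*", {
  rs <- augment_variant(parse_hgvs("c.274G>T"), fixture_cds())
  t0 <- compile_patterns(rs, "T0_full")
  expect_gt(nrow(pm3_scan("we found c. 274 G>T in the proband", t0)), 0)
  expect_gt(nrow(pm3_scan("the p.Asp92Tyr change", t0)), 0)    # parentheses omitted
  expect_gt(nrow(pm3_scan("p.(Asp92Tyr)", t0)), 0)
  expect_gt(nrow(pm3_scan("C.274g>t", t0)), 0)                 # bases case-insensitive
  expect_equal(nrow(pm3_scan("d92y", t0)), 0)                  # shorthand case-sensitive

  rs2 <- augment_variant(parse_hgvs("c.71G>A"), fixture_cds_stop())
  t02 <- compile_patterns(rs2, "T0_full")
  expect_gt(nrow(pm3_scan("carried W24X", t02)), 0)
  expect_gt(nrow(pm3_scan("carried W24*", t02)), 0)
  expect_gt(nrow(pm3_scan("p.(Trp24*)", t02)), 0)              # Ter <-> * interchange
})

test_that("digit-tier patterns match standalone runs only", {
  rs <- augment_variant(parse_hgvs("c.274G>T"))
  t1 <- compile_patterns(rs, "T1_digits")
  expect_gt(nrow(pm3_scan("c.274G>T", t1)), 0)
  expect_gt(nrow(pm3_scan("position 274 of the gene", t1)), 0)
  expect_equal(nrow(pm3_scan("rs27456", t1)), 0)
  rs388 <- augment_variant(parse_hgvs("c.388A>G"))
  t1b <- compile_patterns(rs388, "T1_digits")
  expect_equal(nrow(pm3_scan("frequency is 0.93884", t1b)), 0)
  expect_gt(nrow(pm3_scan("c.388A>G", t1b)), 0)
})

test_that("tolerant tier covers the +/- 2 window and no more", {
  rs <- augment_variant(parse_hgvs("c.274G>T"))
  t2 <- compile_patterns(rs, "T2_tolerant", tolerance = 2)
  for (good in 272:276)
    expect_gt(nrow(pm3_scan(paste("at", good, "here"), t2)), 0, label = good)
  expect_equal(nrow(pm3_scan("at 271 here", t2)), 0)
  expect_equal(nrow(pm3_scan("at 277 here", t2)), 0)
})

test_that("self-match closure: every representation matches its own T0 patterns", {
  descriptors <- list(
    augment_variant(parse_hgvs("c.274G>T"), fixture_cds()),
    augment_variant(parse_hgvs("NM_004004.5: c.71G>A"), fixture_cds_stop()),
    augment_variant(parse_hgvs("c.1813dup")),
    augment_variant(parse_hgvs("c.35delG"))
  )
  for (rs in descriptors) {
    t0 <- compile_patterns(rs, "T0_full")
    for (f in c(rs$dna_forms, rs$protein_forms))
      expect_gt(nrow(pm3_scan(f, t0)), 0, label = f)
  }
})

test_that("tier relaxation never loses matched offsets", {
  rs <- augment_variant(parse_hgvs("c.274G>T"), fixture_cds())
  texts <- c("c.274G>T near 276 and D92Y", "only 92 here", "nothing at all",
             random_text(300, 11), "0.92744 then c.274G>T")
  offsets <- function(text, tiers) {
    out <- integer(0)
    for (tier in tiers) {
      m <- pm3_scan(text, compile_patterns(rs, tier))
      if (nrow(m)) out <- union(out, unlist(Map(seq, m$start, m$end - 1L)))
    }
    sort(out)
  }
  for (tx in texts) {
    o0 <- offsets(tx, "T0_full")
    o01 <- offsets(tx, c("T0_full", "T1_digits"))
    o012 <- offsets(tx, c("T0_full", "T1_digits", "T2_tolerant"))
    expect_true(all(o0 %in% o01), label = tx)
    expect_true(all(o01 %in% o012), label = tx)
  }
})

test_that("standalone digit matching agrees with the brute-force run scanner", {
  positions <- c(7, 92, 274, 388, 1520)
  for (i in 1:200) {
    tx <- random_text(80, 500 + i)
    for (p in positions) {
      expect_identical(has_standalone_digits(tx, p), brute_standalone(tx, p),
                       label = sprintf("pos %d in '%s'", p, tx))
    }
  }
})
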