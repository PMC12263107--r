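test_that("benchmark records read in order and schema violations are named", {
  recs <- read_bench(bench_file())
  expect_length(recs, 5)
  expect_equal(recs[[1]]$variant, "NM_004004.5: c.71G>A")
  expect_equal(recs[[2]]$truth_in_trans, "c.1813dup")
  expect_length(recs[[4]]$truth_in_trans, 0)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(doc_id = "X")), bad, auto_unbox = TRUE)
  err <- tryCatch(read_bench(bad), error = function(e) e)
  expect_s3_class(err, "pm3_schema_error")
  expect_match(conditionMessage(err), "record 1")
  expect_match(conditionMessage(err), "variant")
})

test_that("shuffled negatives form a seeded derangement with no notation leakage", {
  recs <- read_bench(bench_file())
  corpus <- bench_corpus()
  neg <- make_negatives(recs, corpus, seed = 17)
  expect_length(neg, 5)
  for (i in seq_along(neg)) {
    expect_equal(neg[[i]]$doc_id, recs[[i]]$doc_id)
    expect_false(identical(neg[[i]]$variant, recs[[i]]$variant))
    expect_equal(neg[[i]]$label, "negative")
    # leakage check: no full-notation match anywhere in the paired document
    rs <- augment_variant(parse_hgvs(neg[[i]]$variant))
    ch <- chunk_bundle(corpus[[neg[[i]]$doc_id]])
    res <- retrieve(ch, rs, pm3_config())
    expect_false(res$tier_used == "T0_full" && nrow(res$chunks) > 0)
  }
  neg2 <- make_negatives(recs, corpus, seed = 17)
  expect_identical(neg, neg2)

  # impossible case: both documents mention both variants
  sp_a <- fixture_spec("c.274G>T", "c.35delG", seed = 61L)
  sp_b <- fixture_spec("c.35delG", "c.274G>T", seed = 62L)
  corp2 <- list()
  for (sp in list(sp_a, sp_b)) {
    b <- read_bioc(generate_publication(sp)$xml)
    corp2[[b$doc_id]] <- b
  }
  recs2 <- list(
    structure(list(variant = "c.274G>T", doc_id = names(corp2)[1],
                   truth_in_trans = character(0), n_probands = 1L,
                   label = "positive"), class = "pm3_bench_record"),
    structure(list(variant = "c.35delG", doc_id = names(corp2)[2],
                   truth_in_trans = character(0), n_probands = 1L,
                   label = "positive"), class = "pm3_bench_record")
  )
  expect_error(make_negatives(recs2, corp2, seed = 1, max_tries = 50),
               class = "pm3_exhaustion")
})

test_that("variant equivalence ignores transcripts and crosses notation levels", {
  expect_true(variant_equivalent("NM_004004.5:c.71G>A", "c.71G>A"))
  expect_true(variant_equivalent("NM_004004.5: c.71G>A", "c.71G>A"))
  expect_false(variant_equivalent("c.71G>A", "c.71G>C"))
  expect_false(variant_equivalent("c.71G>A", "c.72G>A"))
  expect_true(variant_equivalent("c.274G>T", "D92Y", cds = fixture_cds()))
  expect_true(variant_equivalent("Asp92Tyr", "c.274G>T", cds = fixture_cds()))
  expect_false(variant_equivalent("c.274G>T", "D92Y"))     # no CDS: no protein link
  expect_true(variant_equivalent("c.1813dup", "c.1813dup"))
  expect_true(variant_equivalent("some text", " SOME TEXT"))
})

test_that("confusion counts and derived metrics match hand-computed values", {
  m <- score_variant_hit(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(m$TP, 1); expect_equal(m$FP, 1)
  expect_equal(m$TN, 1); expect_equal(m$FN, 1)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- score_variant_hit(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)

  allneg <- score_variant_hit(c(0, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)

  expect_error(score_variant_hit(c(1, 0), c(1)), class = "pm3_length_mismatch")
})

test_that("metric identities hold on randomized confusion outcomes", {
  for (i in 1:50) {
    set.seed(700 + i)
    n <- sample(4:60, 1)
    preds <- sample(c(TRUE, FALSE), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m <- score_variant_hit(preds, labels)
    tp <- sum(preds & labels); fp <- sum(preds & !labels)
    tn <- sum(!preds & !labels); fn <- sum(!preds & labels)
    expect_equal(m$accuracy, (tp + tn) / n)
    if (2 * tp + fp + fn > 0) expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
  }
})

test_that("in trans recall counts truth variants recovered by equivalence", {
  expect_equal(score_in_trans(list(c("c.71G>A")),
                              list(c("c.71G>A", "c.35delG"))), 0.5)
  expect_equal(score_in_trans(list(c("NM_004004.5:c.71G>A"), character(0)),
                              list(c("c.71G>A"), c("c.35delG"))), 0.5)
  expect_true(is.na(score_in_trans(list(character(0)), list(character(0)))))
  # macro averaging differs from micro when truth sizes are unbalanced
  preds <- list(c("a1"), c("b1"))
  truths <- list(c("a1"), c("b1", "b2", "b3"))
  expect_equal(score_in_trans(preds, truths), 2 / 4)
  expect_equal(score_in_trans(preds, truths, macro = TRUE), (1 + 1 / 3) / 2)
  expect_error(score_in_trans(list(), list("x")), class = "pm3_length_mismatch")
})

test_that("the benchmark harness scores the mock pipeline on the synthetic corpus", {
  recs <- read_bench(bench_file())
  res <- evaluate_bench(recs, bench_corpus(), seed = 5)
  expect_equal(res$metrics$accuracy, 1.0)
  expect_equal(res$in_trans_recall, 1.0)
  expect_equal(nrow(res$per_record), 10)
})
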