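#' Read benchmark records from JSON
#'
#' Each record describes one (variant, publication) evidence pair:
#' `variant` (HGVS string), `doc_id` (PMID/PMCID), `truth_in_trans`
#' (possibly empty list of HGVS strings), `n_probands` (non-negative
#' integer) and `label` (`"positive"` or `"negative"`). The shipped
#' schema lives at `inst/extdata/bench-schema.json`.
#'
#' @param json_file Path to a JSON array of records.
#' @return List of records (class `pm3_bench_record`), in file order.
#' @export
read_bench <- function(json_file) {
  recs <- jsonlite::fromJSON(json_file, simplifyVector = FALSE)
  if (!is.list(recs)) pm3_abort("benchmark file must be a JSON array", "pm3_schema_error")
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    fail <- function(msg) pm3_abort(sprintf("record %d: %s", i, msg), "pm3_schema_error")
    if (!is_scalar_string(r$variant %||% NULL)) fail("missing or invalid field 'variant'")
    if (!is_scalar_string(r$doc_id %||% NULL)) fail("missing or invalid field 'doc_id'")
    if (is.null(r$truth_in_trans)) r$truth_in_trans <- list()
    if (!is.list(r$truth_in_trans)) fail("'truth_in_trans' must be a list")
    np <- r$n_probands %||% 0L
    if (!is.numeric(np) || length(np) != 1L || np < 0) fail("'n_probands' must be a non-negative integer")
    lab <- r$label %||% "positive"
    if (!lab %in% c("positive", "negative")) fail("'label' must be 'positive' or 'negative'")
    if (lab == "positive" && !nzchar(r$doc_id)) fail("positive record lacks document linkage")
    structure(list(variant = r$variant, doc_id = r$doc_id,
                   truth_in_trans = vapply(r$truth_in_trans, as.character, character(1)),
                   n_probands = as.integer(np), label = lab),
              class = "pm3_bench_record")
  })
}

# full searchable text of a bundle: prose plus every table cell
bundle_full_text <- function(bundle) {
  cells <- unlist(lapply(bundle$tables, function(tb)
    c(tb$header, unlist(tb$rows))), use.names = FALSE)
  paste(c(bundle$passages$text, cells), collapse = "\n")
}

#' Construct shuffled-negative benchmark records
#'
#' Builds an equal-sized negative set by assigning to every document a
#' query variant drawn from a different record (a seeded derangement of
#' the positive queries) — real-world variants that are not reported in
#' that publication. Any pairing whose assigned variant still matches
#' the document at any pattern tier is re-drawn; in `strict` mode a
#' digit-tier collision also triggers a re-draw, otherwise only a
#' full-notation (T0) collision does.
#'
#' @param records List of positive `pm3_bench_record`s (length >= 2).
#' @param corpus Named list mapping `doc_id` to `pm3_bundle`.
#' @param seed Integer seed; the same seed reproduces the same pairing.
#' @param strict Forbid digit-tier collisions too (default `FALSE`).
#' @param max_tries Bounded number of shuffle attempts before an
#'   exhaustion error.
#' @return List of `pm3_bench_record`s labelled `"negative"`.
#' @export
make_negatives <- function(records, corpus, seed, strict = FALSE, max_tries = 1000L) {
  n <- length(records)
  if (n < 2L) pm3_abort("need at least two records to shuffle", "pm3_domain_error")
  variants <- vapply(records, function(r) r$variant, character(1))
  docs <- vapply(records, function(r) r$doc_id, character(1))
  texts <- lapply(docs, function(d) {
    b <- corpus[[d]]
    if (is.null(b)) pm3_abort(sprintf("corpus lacks document '%s'", d), "pm3_domain_error")
    bundle_full_text(b)
  })
  repsets <- lapply(variants, function(v) augment_variant(parse_hgvs(v)))
  tiers <- if (strict) PM3_TIERS else "T0_full"

  collides <- function(i, j) {              # variant j against document i
    for (tier in tiers) {
      ps <- compile_patterns(repsets[[j]], tier)
      if (pm3_matches_any(texts[[i]], ps)) return(TRUE)
    }
    FALSE
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    perm <- sample.int(n)
    if (any(perm == seq_len(n))) next       # must be a derangement
    bad <- FALSE
    for (i in seq_len(n)) if (collides(i, perm[i])) { bad <- TRUE; break }
    if (bad) next
    return(lapply(seq_len(n), function(i) {
      structure(list(variant = variants[perm[i]], doc_id = docs[i],
                     truth_in_trans = character(0), n_probands = 0L,
                     label = "negative"),
                class = "pm3_bench_record")
    }))
  }
  pm3_abort(sprintf("no valid negative assignment found in %d tries", max_tries),
            "pm3_exhaustion")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Are two variant descriptions the same variant?
#'
#' True when both parse to the same (position, kind, reference,
#' alternate) ignoring the transcript accession, or when either string
#' occurs verbatim in the other's augmented representation set (which,
#' given a shared coding sequence, links DNA notation to protein
#' shorthand). Unparseable strings are compared after whitespace and
#' case normalisation.
#'
#' @param a,b Variant descriptions.
#' @param cds Optional shared coding sequence used for augmentation.
#' @return `TRUE` or `FALSE`.
#' @export
variant_equivalent <- function(a, b, cds = NULL) {
  norm <- function(x) toupper(gsub("\\s+", "", x))
  pa <- tryCatch(parse_hgvs(a), error = function(e) NULL)
  pb <- tryCatch(parse_hgvs(b), error = function(e) NULL)
  if (!is.null(pa) && !is.null(pb)) {
    return(pa$cds_position == pb$cds_position && pa$kind == pb$kind &&
             identical(pa$ref_base, pb$ref_base) &&
             identical(pa$alt_base, pb$alt_base))
  }
  contains <- function(p, s) {
    r <- tryCatch(augment_variant(p, cds = cds), error = function(e)
      augment_variant(p, cds = NULL))
    if (norm(s) %in% norm(all_forms(r))) return(TRUE)
    m <- pm3_scan(s, compile_patterns(r, "T0_full"))
    nrow(m) > 0 && any(m$start == 0L & m$end == nchar(s))
  }
  if (!is.null(pa)) return(contains(pa, b))
  if (!is.null(pb)) return(contains(pb, a))
  norm(a) == norm(b)
}

#' Score variant-hit predictions as a binary classification
#'
#' The positive class is "the variant is reported in the publication".
#'
#' @param predictions,labels Logical (or 0/1) vectors of equal length.
#' @return A list of class `pm3_metrics`: TP/FP/TN/FN counts plus
#'   `accuracy`, `f1`, `sensitivity`, `specificity`.
#' @export
score_variant_hit <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    pm3_abort("predictions and labels differ in length", "pm3_length_mismatch")
  p <- as.logical(predictions)
  l <- as.logical(labels)
  tp <- sum(p & l); fp <- sum(p & !l); tn <- sum(!p & !l); fn <- sum(!p & l)
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / length(p),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  ), class = "pm3_metrics")
}

#' @export
print.pm3_metrics <- function(x, ...) {
  cat(sprintf("<pm3_metrics> TP=%d FP=%d TN=%d FN=%d | acc=%.3f f1=%.3f sens=%.3f spec=%.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$accuracy, x$f1, x$sensitivity, x$specificity))
  invisible(x)
}

#' Recall of in trans variant detection
#'
#' A truth variant counts as recovered when any prediction for the same
#' pair is [variant_equivalent()] to it. Recall is micro-averaged over
#' all truth variants by default; `macro = TRUE` averages per-pair
#' recalls instead. Pairs with empty truth contribute nothing; if every
#' truth list is empty the recall is undefined and `NA` is returned.
#'
#' @param pred_lists,truth_lists Aligned lists of character vectors.
#' @param macro Average per-pair instead of over all truth variants.
#' @param cds Optional shared coding sequence for equivalence.
#' @return Recall in `[0, 1]`, or `NA` when undefined.
#' @export
score_in_trans <- function(pred_lists, truth_lists, macro = FALSE, cds = NULL) {
  if (length(pred_lists) != length(truth_lists))
    pm3_abort("prediction and truth lists differ in length", "pm3_length_mismatch")
  per_pair <- lapply(seq_along(truth_lists), function(i) {
    truth <- truth_lists[[i]]
    if (!length(truth)) return(NULL)
    hit <- vapply(truth, function(t)
      any(vapply(pred_lists[[i]], variant_equivalent, logical(1), b = t, cds = cds)),
      logical(1))
    c(sum(hit), length(truth))
  })
  per_pair <- Filter(Negate(is.null), per_pair)
  if (!length(per_pair)) return(NA_real_)
  if (macro)
    mean(vapply(per_pair, function(x) x[1] / x[2], numeric(1)))
  else {
    tot <- Reduce(`+`, per_pair)
    tot[1] / tot[2]
  }
}

#' Run the benchmark harness over records and a document corpus
#'
#' Executes the pipeline for every positive record, builds
#' shuffled negatives with [make_negatives()], scores variant-hit
#' classification over positives plus negatives, and in trans recall
#' over the positives.
#'
#' @param records Positive `pm3_bench_record`s.
#' @param corpus Named list mapping `doc_id` to `pm3_bundle`.
#' @param seed Seed for negative construction.
#' @param backend,config Forwarded to the pipeline.
#' @param cds_map Optional named list mapping variant string to coding
#'   sequence.
#' @return List with `metrics` (a `pm3_metrics`), `in_trans_recall`,
#'   and `per_record` (data.frame of predictions).
#' @export
evaluate_bench <- function(records, corpus, seed,
                           backend = pm3_backend_mock(), config = pm3_config(),
                           cds_map = NULL) {
  negatives <- make_negatives(records, corpus, seed)
  all_recs <- c(records, negatives)
  preds <- logical(length(all_recs))
  pred_lists <- vector("list", length(records))
  for (i in seq_along(all_recs)) {
    r <- all_recs[[i]]
    cds <- if (!is.null(cds_map)) cds_map[[r$variant]] else NULL
    vh <- answer_variant_hit(corpus[[r$doc_id]], r$variant, cds = cds,
                             backend = backend, config = config)
    preds[i] <- vh$variant_hit
    if (i <= length(records)) {
      it <- answer_in_trans(corpus[[r$doc_id]], r$variant, cds = cds,
                            backend = backend, config = config)
      pred_lists[[i]] <- it$in_trans
    }
  }
  labels <- vapply(all_recs, function(r) r$label == "positive", logical(1))
  list(
    metrics = score_variant_hit(preds, labels),
    in_trans_recall = score_in_trans(
      pred_lists, lapply(records, function(r) r$truth_in_trans)),
    per_record = data.frame(
      variant = vapply(all_recs, function(r) r$variant, character(1)),
      doc_id = vapply(all_recs, function(r) r$doc_id, character(1)),
      label = vapply(all_recs, function(r) r$label, character(1)),
      predicted_hit = preds, stringsAsFactors = FALSE)
  )
}
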