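---
title: "Extracting PM3 evidence from full-text publications: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting PM3 evidence from full-text publications: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm3miner)
```

## The extraction problem

The PM3 criterion of the ACMG/AMP framework supports recessive pathogenicity
when the query variant is observed *in trans* with a known pathogenic variant
in an affected individual. In publications this evidence lives in two very
different places: prose case descriptions ("Patient II-3 was compound
heterozygous for …") and genotype tables with one patient — or one allele —
per row. `pm3miner` treats these as two independent evidence channels with a
shared front end (variant augmentation) and a shared back end (a completion
backend that interprets the retrieved material), and merges their answers.

The pipeline answers two questions per (variant, publication) pair: whether
the publication reports the query variant at all (*variant hit*, a binary
decision), and which partner variants it reports on the other allele
(*in trans* candidates, a list with provenance).

## Variant augmentation

A query arrives in HGVS coding notation, optionally transcript-prefixed.
Substitutions are parsed fully; duplications, deletions, insertions and
deletion-insertions are parsed positionally, enough to match them by
coordinate. Intronic offsets, UTR coordinates and genomic (`g.`) notation are
rejected up front: the pipeline works in coding coordinates and cannot place
such inputs without a transcript model.

Protein-level representations require a coding sequence, supplied by the user
as a single-record FASTA starting at coding position 1. Augmentation is local
and self-contained: the affected codon is `ceil(c / 3)` for coding position
`c`, the codon is mutated at the in-codon offset and translated with the
standard genetic code, and the resulting change is rendered in every spelling
journals use — `p.(Asp92Tyr)`, `p.Asp92Tyr`, `Asp92Tyr`, `D92Y`, and for stop
gains both `W24X` and `W24*`. Only the supplied transcript's coordinates are
used; legacy or alternative transcript numbering is deliberately not guessed,
because a silently wrong coordinate is worse than a missed match.

## The pattern cascade

All matching is driven by three tiers compiled from the representation set:

* **T0 (full notation).** Each representation becomes a pattern tolerating
  whitespace between tokens, omitted parentheses, and `X`/`*` interchange
  (`Ter` in three-letter forms also matches either symbol). DNA notation and
  three-letter protein forms are matched case-insensitively, since journals
  typeset variants inconsistently; one-letter shorthand such as `D92Y` stays
  case-sensitive and word-bounded to limit false hits.
* **T1 (digits only).** Each coordinate of the variant (coding position, and
  codon index when protein forms exist) is matched as a *standalone digit
  run*: a maximal run of digits not preceded by a digit or by `<digit>.` and
  not followed by a digit. This single definition both accepts `274` inside
  `c.274G>T` and rejects `388` inside `0.93884` or `rs3885`, and it is shared
  verbatim by the retriever and the table post-filter.
* **T2 (tolerant).** As T1 for every integer within a tolerance (default
  `2`, configurable) of each coordinate, absorbing the small coordinate
  shifts seen between reference sequences; values are clamped at 1.

Relaxation is one-way and lazy: a stricter tier that finds at least
`min_chunks_before_relax` chunks (default `1`) ends the cascade, so digit
tiers are consulted only when notation matching fails. Digit-tier evidence is
flagged low-confidence in every downstream answer, because a bare coordinate
is positional evidence, not a variant mention.

## Prose channel

Prose passages (tables removed) are concatenated with blank lines and split
into chunks of at most 1500 characters overlapping by 100 — large enough to
hold a case description, small enough for a completion model's context. Cut
points prefer, in order, paragraph breaks, line breaks, sentence ends and
spaces, searched backwards from the limit; a separator-free stretch is cut
hard. Consecutive chunks always share the overlap, so a mention on a boundary
is seen whole in at least one chunk. Offsets are 0-based half-open
throughout, and each chunk is labelled with the section containing its start.

The retriever returns at most five chunks in document order (no ranking —
the cascade has no notion of chunk quality, and document order keeps results
deterministic); the same cap applies at every tier. The chunks become the
context of the predefined variant-hit and in-trans questions to the backend.

## Table channel

Tables are loaded into an embedded in-memory relational store: one all-text
relation per table, sanitized unique column names, original headers kept in
metadata, and byte-identical cell round-trips (no type inference — a
genotype cell like `c.71G>A;c.35delG` must survive verbatim). Each relation
can be exported as tab-separated text for inspection.

Row finding is a two-pass scheme. Full-notation (T0) matches yield
`notation`-confidence hits directly. Remaining rows are matched with a
position-guided query — a generated single-statement `SELECT` with
`LIKE '%<coordinate>%'` terms — and kept only if a cell passes the
standalone-digit post-filter; these are `position_only` hits. When a real
backend generates the SQL, the generation is validated (read-only, single
statement, known relation and columns, template shape) and anything invalid
falls back to the template; malformed model output must never reach the
store. Position-only hits alone do not decide the variant-hit question:
the fetched rows are put to the backend for interpretation, which with the
mock backend means a position collision in a genotype table cannot create a
false positive.

The *in trans* expansion takes the hit row's first-column value as the
patient identifier — empty cells inherit the identifier from above, the
merged-cell convention of genotype tables — and returns the contiguous block
of same-identifier rows around the hit. Contiguity is a deliberate
restriction: biallelic genotype rows are adjacent in practice, and expanding
to equal identifiers anywhere in the table risks pulling in other families
that happen to reuse `P1`. Non-contiguous equal-identifier rows are still
reported, but separately and flagged low-confidence. Documents with more
than five tables are processed in order-preserving batches of five; batching
is exactly result-preserving, which the test suite asserts on randomized
table sets.

## Completion backend

The backend contract is a single total operation: a task (`variant_hit`,
`in_trans`, `sql_generation`, `summarize`), a context, and the query's
representation set go in; a verdict, extracted variants, and a rationale
span that must occur verbatim in the context come out. The shipped mock is
rule-based and deterministic: variant-hit answers yes only on a full-notation
match in the context; in-trans extraction scans the context with generic
HGVS-shaped patterns and removes every mention matching the query's own
representation set, keeping first-occurrence order. The mock encodes the
behavioural contract the pipeline needs from a model — short answers, no
claims without verbatim evidence — so orchestration and scoring are fully
exercisable offline. An HTTP adapter for an Ollama-style local server is
provided (deterministic decoding, temperature 0, prompt templates shipped as
versioned text resources and sent unmodified); it is optional and nothing in
the package depends on it being reachable.

## Evaluation harness

Variant-hit is scored as binary classification. Negatives are built by a
seeded derangement of the positive queries over the documents — real
variants, wrong publication — re-drawn (boundedly, then failing loudly) while
an assigned variant still matches its document; by default a full-notation
match disqualifies a pairing, and a strict mode also forbids digit-tier
collisions. The positive class for F1 is "variant reported". In trans recall
is micro-averaged over truth variants, with a macro option; matches use
cross-notation variant equivalence (transcript-insensitive descriptor
comparison, falling back to representation-set containment, so `c.274G>T`
and `D92Y` unify when a shared coding sequence is available). A benchmark
with no truth variants has undefined recall and is reported as `NA`, never
as a perfect score.

## Synthetic publications

The generator emits BioC-dialect documents (passages with `type` infons;
tables as tab-separated grids in `table` passages, the dialect the reader
also accepts from PMC-style exports) with title, introduction and results
prose, and a genotype table in one of two layouts: one row per patient with
allele columns, or one row per allele with adjacent rows per patient.
Patient-identifier styles (`P1`, `II-3`, `Family 2, Pt 1`) and allele column
headers are drawn per seed from pools of conventions found in rare-disease
genotype tables, so the engine is not tuned to a single dialect. Defaults —
four patients, one affected carrier of the query variant, filler variants at
coordinates kept at least 3 away from any query coordinate — reflect the
scale of typical case-report cohorts. Decimal traps plant the query position
inside frequency-style decimals (`0.93884`-shaped cells and sentences) to
exercise the post-filter. Every document is byte-identical for a fixed spec
and seed, and the truth record states exactly what was planted.

What passing on synthetic data does and does not show: the generator
produces clean XML, consistent identifiers and well-formed HGVS strings. It
does not emulate OCR noise, multi-level headers, merged header cells,
footnote markers inside cells, or evidence confined to figures and
supplementary files — real-publication performance on those is out of reach
of this test bed, and the last category is unsupported by design.

## Numerical and degenerate-input choices

Chunking requires `chunk_size > overlap ≥ 0`; empty text yields zero chunks,
and a boundary candidate is accepted only if it leaves more than `overlap`
characters of progress, which guarantees strictly increasing chunk starts.
Short table rows are padded with empty cells to the header width. Ties among
more than five matching chunks break by document order. The tolerant tier
clamps its window at coordinate 1. Degenerate scoring inputs (no truth
variants, empty prediction sets) return `NA` rather than inventing a value.
Seeds: every randomized component (CDS generation, fixture generation,
negative shuffling) takes an explicit integer seed and restores the caller's
RNG state, so library use never perturbs a session's random stream.

Problem sizes in the shipped tests were chosen to keep the full suite
comfortably under a few minutes on one CPU while still exercising every
rule: 100 random CDS/substitution pairs for the translation property, 1000
random texts for the digit-run oracle, 200 seeded synthetic publications
(mixed channels, layouts and traps) for end-to-end parameter recovery, and a
five-record benchmark corpus for the harness.

## Known limitations

* Only coding-coordinate HGVS is supported; intronic, UTR and genomic
  descriptions are rejected rather than approximated.
* Protein-level matching needs a user-supplied CDS; without one, a
  publication that mentions a substitution only as `D92Y` can only be found through the
  digit tiers.
* The mock backend is a contract fixture, not a language model: it cannot
  paraphrase, resolve anaphora ("the second variant"), or read genotypes
  described without HGVS notation.
* Table understanding assumes the first column identifies the patient;
  tables keyed by family with patient sub-columns will group at family
  granularity.
* PDF input, figures and supplementary files are out of scope.
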