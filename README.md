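# pm3miner

Literature evidence for the ACMG/AMP **PM3** criterion — a variant observed
*in trans* with a pathogenic variant in a patient with recessive disease — is
scattered across case reports and genotype tables in full-text publications,
and collecting it is one of the slowest steps of clinical variant curation.
`pm3miner` automates the two questions a curator asks of one publication:

1. **Variant hit** — does this publication report the query variant at all?
2. **In trans partners** — which other variants are reported on the other
   allele of the same patient?

The package is aimed at variant curators and at developers of
literature-mining pipelines who need a fully deterministic, offline-testable
reference implementation of this extraction flow.

## How it works

Given a query variant in HGVS coding notation (e.g.
`NM_004004.5: c.71G>A`) and a publication in PMC BioC XML, the pipeline:

* **Augments** the variant into all of its textual representations: the DNA
  notation `c.274G>T`, the transcript-prefixed form, and — when a coding
  sequence is supplied — the protein change `p.(Asp92Tyr)` and its shorthand
  `D92Y`, with stop gains spelled both `W24X` and `W24*`. The protein
  coordinate is the codon index `ceil(c / 3)` of the coding position `c`.
* **Separates tables from prose.** Tables go into an embedded all-text
  relational store and are searched with position-guided queries
  (`... LIKE '%274%'`) followed by a digit-boundary post-filter that accepts a
  coordinate only as a *standalone digit run* — `c.388A>G` matches query
  position 388, the cell `frequency is 0.93884` does not. Rows carrying the
  query variant are expanded to same-patient neighbour rows (first-column
  identifier, merged-cell convention) to recover the other allele. Documents
  with more than five tables are processed in batches.
* **Chunks the prose** into 1500-character pieces overlapping by 100, then
  retrieves at most five variant-bearing chunks with a three-tier pattern
  cascade: full notation (whitespace-, parenthesis- and `X`/`*`-tolerant),
  falling back to digits only, then to a ±2 window around the coordinate —
  relaxing only when a stricter tier finds too little.
* **Asks a completion backend** the two predefined questions over the
  retrieved evidence and merges both channels into one answer with per-item
  provenance (`Table 2, row 3` or chunk offsets plus a verbatim rationale
  span). A deterministic rule-based mock backend ships with the package;
  an HTTP adapter can talk to a local model server instead.

An evaluation harness scores variant-hit classification (accuracy, F1,
sensitivity, specificity) against shuffled-negative pairings and in trans
recall by cross-notation variant equivalence, and a seeded generator emits
synthetic BioC publications with known ground truth for end-to-end testing.

## Worked example

```r
library(pm3miner)

cds <- generate_cds(120, pins = list("92" = "GAC"), seed = 1)
augment_variant(parse_hgvs("c.274G>T"), cds)
#> <pm3_repset> for c.274G>T
#>   DNA forms:     c.274G>T, 274G>T
#>   protein forms: p.(Asp92Tyr), p.Asp92Tyr, Asp92Tyr, D92Y
#>   positions:     274, 92

sp <- fixture_spec("NM_004004.5: c.71G>A", "c.35delG", seed = 42)
bundle <- read_bioc(generate_publication(sp)$xml)
bundle
#> <pm3_bundle> document SYN0000042: 3 passages, 1 tables

answer_in_trans(bundle, "NM_004004.5: c.71G>A")
#> <pm3_evidence> variant hit: yes
#>   in trans candidates: c.35delG
#>   Source: Table 1, row 1 [notation]
```

The representation set shows the augmentation step: position 274 falls in
codon 92 (`274, 92` under `positions`), producing the `Asp92Tyr`/`D92Y`
protein forms alongside the DNA notation. The evidence answer says the
publication reports the query variant, that the same patient carries
`c.35delG` on the other allele, and exactly which table row supports it —
`[notation]` marks a full-notation match rather than a positional-only one.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/pm3.R run --variant "NM_004004.5:c.71G>A" --bioc doc.xml --out report.json
Rscript inst/cli/pm3.R eval --bench records.json --docs docs/ --seed 7
Rscript inst/cli/pm3.R synth --spec spec.json --seed 7 --out fixture/
```

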