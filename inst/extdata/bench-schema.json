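{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pm3miner benchmark record",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["variant", "doc_id"],
    "properties": {
      "variant": {
        "type": "string",
        "description": "Query variant in HGVS coding notation, optionally transcript-prefixed"
      },
      "doc_id": {
        "type": "string",
        "description": "PMID/PMCID (or synthetic document id) of the publication"
      },
      "truth_in_trans": {
        "type": "array",
        "items": {"type": "string"},
        "description": "Curated in trans partner variants; may be empty"
      },
      "n_probands": {
        "type": "integer",
        "minimum": 0,
        "description": "Number of probands supporting the evidence"
      },
      "label": {
        "type": "string",
        "enum": ["positive", "negative"],
        "description": "Whether the variant is reported in the publication"
      }
    }
  }
}
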