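[
  {
    "variant": "NM_004004.5: c.71G>A",
    "doc_id": "SYN0000101",
    "truth_in_trans": ["c.35delG"],
    "n_probands": 1,
    "label": "positive"
  },
  {
    "variant": "c.274G>T",
    "doc_id": "SYN0000102",
    "truth_in_trans": ["c.1813dup"],
    "n_probands": 1,
    "label": "positive"
  },
  {
    "variant": "NM_000059.4: c.7796A>G",
    "doc_id": "SYN0000103",
    "truth_in_trans": ["c.1813dup"],
    "n_probands": 1,
    "label": "positive"
  },
  {
    "variant": "c.1520T>C",
    "doc_id": "SYN0000104",
    "truth_in_trans": [],
    "n_probands": 1,
    "label": "positive"
  },
  {
    "variant": "c.902A>T",
    "doc_id": "SYN0000105",
    "truth_in_trans": ["c.101G>C"],
    "n_probands": 1,
    "label": "positive"
  }
]
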