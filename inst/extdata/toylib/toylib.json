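{
  "library_id": "TOY",
  "library_tag": "ACGTACGTAC",
  "error_correction_mode": "none",
  "barcode_schema": [
    {"name": "primer5", "kind": "constant", "length": 8, "sequence": "ACACACAC"},
    {"name": "library", "kind": "constant", "length": 10, "sequence": "ACGTACGTAC"},
    {"name": "bb_A", "kind": "bb_tag", "length": 5, "cycle": "A"},
    {"name": "bb_B", "kind": "bb_tag", "length": 5, "cycle": "B"},
    {"name": "umi", "kind": "umi", "length": 6},
    {"name": "primer3", "kind": "constant", "length": 8, "sequence": "TGTGTGTG"}
  ],
  "building_blocks": [
    {"cycle": "A", "file": "bb_A.csv"},
    {"cycle": "B", "file": "bb_B.csv"}
  ],
  "reaction_scheme": ["[C:1](=[O:2])[OH].[NX3;H2,H1:3]>>[C:1](=[O:2])[N:3]"]
}
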