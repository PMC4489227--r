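{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "FvModeler model summary",
  "type": "object",
  "required": ["receptor", "chains", "cs_assignments", "framework",
               "loops", "scores", "clashes", "minimized"],
  "properties": {
    "receptor": {"type": "string", "enum": ["BCR", "TCR"]},
    "chains": {
      "type": "array", "minItems": 2, "maxItems": 2,
      "items": {
        "type": "object",
        "required": ["id", "chain_type", "n_residues", "n_repack"],
        "properties": {
          "id": {"type": "string"},
          "chain_type": {"type": "string"},
          "n_residues": {"type": "integer"},
          "n_repack": {"type": "integer"}
        }
      }
    },
    "cs_assignments": {"type": "object"},
    "framework": {
      "type": "object",
      "required": ["chain1", "chain2", "same_crystal", "rationale"]
    },
    "loops": {"type": "object"},
    "scores": {"type": "object"},
    "pack_scaffold": {"type": ["array", "null"]},
    "clashes": {"type": "integer"},
    "warnings": {"type": ["array", "string", "null"]},
    "minimized": {"type": "boolean", "const": false}
  }
}
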