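{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "epivote pipeline report",
  "type": "object",
  "required": ["sequence", "parameters", "seed"],
  "properties": {
    "sequence": {
      "type": "object",
      "required": ["id", "length"],
      "properties": {
        "id": {"type": "string"},
        "length": {"type": "integer", "minimum": 1}
      }
    },
    "parameters": {"type": "object"},
    "seed": {"type": "integer"},
    "physchem": {
      "type": "object",
      "required": ["length", "molecular_weight", "theoretical_pI", "gravy",
                   "aliphatic_index", "instability_index", "stability_class"],
      "properties": {
        "molecular_weight": {"type": "number", "exclusiveMinimum": 0},
        "theoretical_pI": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 14},
        "gravy": {"type": "number"},
        "aliphatic_index": {"type": "number", "minimum": 0},
        "instability_index": {"type": "number"},
        "stability_class": {"enum": ["stable", "unstable"]}
      }
    },
    "motifscan": {"type": "array", "items": {"$ref": "#/$defs/region"}},
    "bcell_propensity": {"type": "object"},
    "bcell_consensus": {"$ref": "#/$defs/consensus"},
    "dr_consensus": {"$ref": "#/$defs/consensus"},
    "dq_consensus": {"$ref": "#/$defs/consensus"},
    "tcell_combined": {"$ref": "#/$defs/consensus"},
    "epitope_classification": {"type": "array"}
  },
  "$defs": {
    "region": {
      "type": "object",
      "required": ["start", "end"],
      "properties": {
        "start": {"type": "integer", "minimum": 1},
        "end": {"type": "integer", "minimum": 1}
      }
    },
    "consensus": {
      "type": "object",
      "required": ["params", "regions", "support"],
      "properties": {
        "params": {
          "type": "object",
          "required": ["k", "min_len", "merge_gap"]
        },
        "regions": {
          "type": "array",
          "items": {
            "allOf": [{"$ref": "#/$defs/region"}],
            "required": ["length", "min_support"]
          }
        },
        "support": {"type": "array", "items": {"type": "integer", "minimum": 0}}
      }
    }
  }
}
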