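{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "DDI assessment report",
  "type": "object",
  "required": ["drug_a", "drug_b", "verdict", "threshold",
               "pharmacological_effects", "biomedical_features",
               "shared_level_count", "mechanism_match_count",
               "rationale", "proofs"],
  "properties": {
    "drug_a": {"type": "string"},
    "drug_b": {"type": "string"},
    "verdict": {"enum": ["POTENTIAL_DDI", "NO_EVIDENCE"]},
    "threshold": {"type": "number", "minimum": 0},
    "pharmacological_effects": {
      "type": "object",
      "required": ["metabolizing_enzymes", "transporters"],
      "properties": {
        "metabolizing_enzymes": {"$ref": "#/definitions/mechRows"},
        "transporters": {"$ref": "#/definitions/mechRows"}
      }
    },
    "biomedical_features": {
      "type": "object",
      "required": ["pharmacological", "biomolecular", "physiological",
                   "genetic", "substructure", "contraindication"],
      "additionalProperties": {"$ref": "#/definitions/featureRow"}
    },
    "shared_level_count": {"type": "integer", "minimum": 0},
    "mechanism_match_count": {"type": "integer", "minimum": 0},
    "rationale": {"type": "array", "items": {"type": "string"}},
    "proofs": {"type": "array"}
  },
  "definitions": {
    "mechRows": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["target", "target_kind", "perpetrator",
                     "perpetrator_role", "victim", "rule"],
        "properties": {
          "target": {"type": "string"},
          "target_kind": {"enum": ["metabolizing_enzyme", "transporter"]},
          "perpetrator": {"type": "string"},
          "perpetrator_role": {"enum": ["inhibitor", "inducer"]},
          "victim": {"type": "string"},
          "rule": {"type": "string"}
        }
      }
    },
    "featureRow": {
      "oneOf": [
        {"const": "NA"},
        {"type": "array", "items": {"type": "string"}}
      ]
    }
  }
}
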