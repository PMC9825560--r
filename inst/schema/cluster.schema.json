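{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "megasynth/cluster.schema.json",
  "title": "Megasynthase cluster",
  "description": "Interchange format for a type I modular PKS/NRPS/hybrid cluster: ordered subunits of ordered modules of ordered, attributed domains (N-to-C order throughout; module indices are implicit, 0-based, loading module first).",
  "type": "object",
  "required": ["id", "name", "reviewed", "subunits"],
  "additionalProperties": false,
  "properties": {
    "id": {"type": "string"},
    "name": {"type": "string"},
    "reviewed": {"type": "boolean"},
    "notes": {"type": ["string", "null"]},
    "subunits": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "modules"],
        "additionalProperties": false,
        "properties": {
          "name": {"type": "string"},
          "description": {"type": ["string", "null"]},
          "modules": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["is_loading", "domains"],
              "additionalProperties": false,
              "properties": {
                "is_loading": {"type": "boolean"},
                "domains": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["kind", "active"],
                    "additionalProperties": false,
                    "properties": {
                      "kind": {"enum": ["KS", "AT", "KR", "DH", "ER", "MT", "ACP", "PCP", "CAL", "C", "A", "E", "F", "nMT", "Cy", "AOX", "R", "TE", "X"]},
                      "active": {"type": "boolean"},
                      "attributes": {
                        "type": "object",
                        "properties": {
                          "substrate_code": {"type": "string"},
                          "is_loading": {"type": "boolean"},
                          "kr_type": {"enum": ["A1", "A2", "B1", "B2", "C1", "C2", "U"]},
                          "c_type": {"enum": ["Starter", "LCL", "DCL", "Glycopeptide", "Dual"]},
                          "modification": {"enum": ["oxidation", "reduction", "none"]},
                          "release_mode": {"enum": ["hydrolysis", "lactone", "lactam"]},
                          "ring_site": {"type": "integer", "minimum": 0},
                          "product_level": {"enum": ["aldehyde", "alcohol"]},
                          "starter_code": {"type": "string"},
                          "starter_smiles": {"type": "string"}
                        },
                        "additionalProperties": false
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
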