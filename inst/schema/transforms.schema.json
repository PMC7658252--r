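{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "synthforge reaction rule file",
  "type": "object",
  "required": ["transforms"],
  "properties": {
    "transforms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "ring_forming", "role_a", "role_b",
                     "product_smirks", "leaving_groups", "clauses"],
        "properties": {
          "id": {"type": "integer", "description": "unique rule identifier"},
          "name": {"type": "string"},
          "ring_forming": {"type": "boolean"},
          "role_a": {"$ref": "#/definitions/role"},
          "role_b": {"$ref": "#/definitions/role"},
          "product_smirks": {
            "type": "string",
            "description": "two-component reaction SMIRKS; reactant sides must subsume the role patterns"
          },
          "leaving_groups": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["formula", "heavy_atoms"],
              "properties": {
                "formula": {"type": "string"},
                "heavy_atoms": {"type": "integer", "minimum": 0}
              }
            }
          },
          "clauses": {
            "type": "array",
            "items": {"$ref": "#/definitions/clause"}
          },
          "metadata": {
            "type": "object",
            "description": "opaque free-text annotations (conditions, typical yield, ...)"
          }
        }
      }
    }
  },
  "definitions": {
    "role": {
      "type": "object",
      "required": ["name", "smarts"],
      "properties": {
        "name": {"type": "string"},
        "smarts": {"type": "string", "description": "substructure pattern defining the role"},
        "example": {"type": "string", "description": "SMILES matching the role exactly once; used by rule validation"}
      }
    },
    "clause": {
      "type": "object",
      "required": ["scope", "action"],
      "properties": {
        "scope": {"enum": ["reactant_a", "reactant_b", "product"]},
        "action": {"enum": ["ADD", "SUBTRACT", "KILL"]},
        "value": {
          "type": "integer",
          "multipleOf": 5,
          "minimum": 5,
          "maximum": 30,
          "description": "required for ADD/SUBTRACT, forbidden for KILL"
        },
        "smarts": {"type": "string", "description": "substructure predicate"},
        "property": {
          "enum": ["heavy_atoms", "ring_count", "net_charge"],
          "description": "named property predicate (alternative to smarts)"
        },
        "op": {"enum": ["<", "<=", ">", ">=", "=="]},
        "threshold": {"type": "number"},
        "note": {"type": "string"}
      }
    }
  }
}
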