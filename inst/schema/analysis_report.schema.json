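{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "xknet analysis report",
  "type": "object",
  "required": ["provenance", "conditions", "warnings"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package_version", "config_hash", "seed"]
    },
    "conditions": {
      "type": "object",
      "additionalProperties": { "$ref": "#/definitions/condition" }
    },
    "warnings": { "type": "array" }
  },
  "definitions": {
    "condition": {
      "type": "object",
      "required": ["networks"],
      "properties": {
        "networks": { "type": "object" },
        "centrality_shift": { "type": "object" },
        "nestedness": { "type": "object" }
      }
    }
  }
}
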