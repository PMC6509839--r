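{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cellgate corpus summary",
  "type": "object",
  "required": [
    "rows_processed",
    "conflict_rows",
    "total_gate_occurrences",
    "occurrences_by_provenance",
    "occurrence_pct_by_provenance",
    "distinct_gate_names",
    "distinct_by_provenance",
    "distinct_pct_by_provenance"
  ],
  "properties": {
    "rows_processed": { "type": "integer", "minimum": 0 },
    "conflict_rows": { "type": "integer", "minimum": 0 },
    "total_gate_occurrences": { "type": "integer", "minimum": 0 },
    "occurrences_by_provenance": { "$ref": "#/definitions/by_provenance" },
    "occurrence_pct_by_provenance": { "$ref": "#/definitions/by_provenance" },
    "distinct_gate_names": { "type": "integer", "minimum": 0 },
    "distinct_by_provenance": { "$ref": "#/definitions/by_provenance" },
    "distinct_pct_by_provenance": { "$ref": "#/definitions/by_provenance" }
  },
  "definitions": {
    "by_provenance": {
      "type": "object",
      "required": ["pro_short_label", "exact_synonym", "manual", "not_matched"],
      "properties": {
        "pro_short_label": { "type": "number" },
        "exact_synonym": { "type": "number" },
        "manual": { "type": "number" },
        "not_matched": { "type": "number" }
      }
    }
  }
}
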