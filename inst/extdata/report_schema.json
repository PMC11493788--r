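{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pfasval validation report",
  "type": "object",
  "required": ["analytes", "config", "n_analytes", "n_errored", "all_pass"],
  "properties": {
    "analytes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["analyte_id"],
        "properties": {
          "analyte_id": {"type": "string"},
          "error": {"type": "string"},
          "weighting": {"enum": ["none", "1/x", "1/x^2"]},
          "heteroscedastic": {"type": "boolean"},
          "variance_power": {"type": "number"},
          "order": {"enum": ["linear", "quadratic"]},
          "coefficients": {"type": "object"},
          "lod_hubaux_vos_ng_ml": {"type": "number"},
          "loq_ng_ml": {"type": ["number", "null"]},
          "accuracy_precision": {"type": "object"},
          "pass": {"type": "boolean"},
          "matrix_effect": {"type": "object"},
          "stability": {"type": "object"},
          "stable": {"type": "boolean"}
        }
      }
    },
    "config": {"type": "object"},
    "n_analytes": {"type": "integer"},
    "n_errored": {"type": "integer"},
    "all_pass": {"type": "boolean"}
  }
}
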