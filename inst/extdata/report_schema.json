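{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "btbquant end-to-end report",
  "version": "1.0",
  "type": "object",
  "required": ["schema_version", "package_version", "seed", "gaps",
               "calibration", "kinetics", "efflux", "imaging", "config"],
  "properties": {
    "schema_version": {"type": "string"},
    "package_version": {"type": "string"},
    "seed": {"type": ["integer", "number", "null"]},
    "gaps": {"type": "array", "items": {"type": "string"}},
    "calibration": {
      "type": ["object", "null"],
      "required": ["slope", "intercept", "r_squared", "n_points"]
    },
    "kinetics": {
      "type": ["object", "null"],
      "required": ["v0", "multipoint", "groups", "inhibitor_folds",
                   "dunnett", "bdt_vs_btb_t"]
    },
    "efflux": {
      "type": ["object", "null"],
      "required": ["line", "deviations"]
    },
    "imaging": {
      "type": ["object", "null"],
      "required": ["n_vessels", "expression_summary", "bbb_vs_btb_t",
                   "registration", "lesions", "correlations"]
    },
    "config": {"type": ["object", "null"]}
  }
}
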