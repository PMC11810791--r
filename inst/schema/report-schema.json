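{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "polyCTC pipeline report",
  "type": "object",
  "required": ["config", "seed"],
  "properties": {
    "config": {"type": "object"},
    "seed": {"type": "integer"},
    "cohort": {
      "type": "object",
      "required": ["blood_percent", "marrow_percent", "n_matched"],
      "properties": {
        "blood_percent": {"type": "number"},
        "marrow_percent": {"type": "number"},
        "n_matched": {"type": "integer"},
        "n_patients": {"type": "integer"},
        "marrow_positive_detected": {"type": "integer"},
        "logrank_p": {"type": ["number", "null"]}
      }
    },
    "rna": {
      "type": "object",
      "required": ["line_set_sizes", "survivor_set_size", "biotype_percent"],
      "properties": {
        "line_set_sizes": {"type": "object"},
        "survivor_set_size": {"type": "integer"},
        "biotype_percent": {"type": "object"}
      }
    },
    "cn": {
      "type": "object",
      "required": ["medians"],
      "properties": {
        "medians": {"type": "object"},
        "chr1_mean_ratio": {"type": "number"},
        "chr10_mean_ratio": {"type": "number"}
      }
    }
  }
}
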