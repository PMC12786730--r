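{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "evocquant pipeline configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "seed": { "type": "integer" },
    "output_dir": { "type": "string" },
    "days": { "type": "array", "items": { "type": "integer" } },
    "white_point": { "type": "number", "exclusiveMinimum": 0 },
    "detection": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "pixel_size_um": { "type": "number", "exclusiveMinimum": 0 },
        "min_radius_um": { "type": "number", "exclusiveMinimum": 0 },
        "max_radius_um": { "type": "number", "exclusiveMinimum": 0 },
        "splitting_threshold": { "type": "number", "minimum": 0 },
        "cell_expansion_um": { "type": "number", "minimum": 0 },
        "dab_od_threshold": { "type": "number", "minimum": 0 },
        "smoothing_sigma_um": { "type": "number", "minimum": 0 },
        "h_od_threshold": { "type": "number", "minimum": 0 }
      }
    },
    "stains": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "name": { "type": "string" },
        "h": { "type": "array", "items": { "type": "number" },
               "minItems": 3, "maxItems": 3 },
        "dab": { "type": "array", "items": { "type": "number" },
                 "minItems": 3, "maxItems": 3 },
        "residual": { "type": ["array", "null"],
                      "items": { "type": "number" },
                      "minItems": 3, "maxItems": 3 }
      }
    },
    "statistics": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "posthoc_method": {
          "enum": ["bonferroni_paired_t", "tukey_hsd"] },
        "sphericity_alpha": { "type": "number",
                              "exclusiveMinimum": 0, "maximum": 1 }
      }
    }
  }
}
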