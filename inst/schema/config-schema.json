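{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pregsim run configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["n_women", "age"],
  "properties": {
    "n_women": {"type": "integer", "minimum": 0},
    "age": {
      "type": "object",
      "required": ["type"],
      "properties": {
        "type": {"enum": ["uniform", "point", "bands"]},
        "min": {"type": "number"},
        "max": {"type": "number"},
        "age": {"type": "number"},
        "ages": {"type": "array", "items": {"type": "number"}},
        "weights": {"type": "array", "items": {"type": "number"}}
      }
    },
    "duration_days": {"type": "integer", "minimum": 0, "default": 365},
    "scenario": {
      "enum": ["none", "population_mix", "highly_effective_only"],
      "default": "population_mix"
    },
    "schedule": {
      "type": "object",
      "properties": {
        "type": {"enum": ["screening_only", "periodic"]},
        "interval_days": {"type": "integer", "exclusiveMinimum": 0}
      },
      "default": {"type": "periodic", "interval_days": 91}
    },
    "timing_policy": {
      "enum": ["random", "timed_to_expected_menses", "post_LH"],
      "default": "random"
    },
    "assay": {"type": "string", "default": "serum_quantitative"},
    "assays": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["matrix", "mode", "analytic_sensitivity", "positive_cutoff"],
        "properties": {
          "name": {"type": "string"},
          "matrix": {"enum": ["urine", "serum"]},
          "mode": {"enum": ["qualitative", "quantitative"]},
          "analytic_sensitivity": {"type": "number", "exclusiveMinimum": 0},
          "positive_cutoff": {"type": "number", "exclusiveMinimum": 0},
          "indeterminate_band": {
            "type": "array", "items": {"type": "number"},
            "minItems": 2, "maxItems": 2
          },
          "cv": {"type": "number", "minimum": 0}
        }
      }
    },
    "mode": {"enum": ["mc", "expected"], "default": "mc"},
    "n_reps": {"type": "integer", "minimum": 1, "default": 200},
    "seed": {"type": "integer"},
    "parameter_table": {"type": "string", "default": "bundled-default"},
    "out_dir": {"type": "string", "default": "."}
  }
}
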