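{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "activprofile profile report",
  "type": "object",
  "required": ["software", "thresholds", "profile", "pal_status", "attainment"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "thresholds": {
      "type": "object",
      "required": ["sedentary_lt", "light_lt", "moderate_lt", "vigorous_lt"],
      "additionalProperties": {"type": "number"}
    },
    "targets": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["dimension", "target", "direction"],
        "properties": {
          "dimension": {"type": "string"},
          "target": {"type": "number", "exclusiveMinimum": 0},
          "direction": {"enum": ["at_least", "at_most"]}
        }
      }
    },
    "profile": {
      "type": "object",
      "required": ["pal", "sedentary_pct_waking", "daily_moderate_min",
                   "weekly_bout_min", "weekly_vigorous_min"],
      "properties": {
        "pal": {"type": "number", "exclusiveMinimum": 0},
        "sedentary_pct_waking": {"type": "number", "minimum": 0, "maximum": 100},
        "daily_moderate_min": {"type": "number", "minimum": 0, "maximum": 1440},
        "weekly_bout_min": {"type": "number", "minimum": 0},
        "weekly_vigorous_min": {"type": "number", "minimum": 0}
      }
    },
    "pal_status": {"enum": ["sedentary", "moderately_active", "highly_active"]},
    "attainment": {
      "type": "array",
      "minItems": 5,
      "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["dimension", "value", "target", "direction", "status",
                     "relative_attainment"],
        "properties": {
          "status": {"enum": ["hit", "near", "missed"]},
          "relative_attainment": {"type": "number", "minimum": 0}
        }
      }
    }
  }
}
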