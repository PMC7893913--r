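{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mbcoud patient trajectory",
  "description": "One treatment episode: a week-0 baseline symptom-checklist administration plus follow-up visits with checklist, adherence questionnaire, and the prescription in effect at each visit. Weeks are weeks since buprenorphine initiation; calendar mapping is the caller's concern.",
  "type": "object",
  "required": ["schema_version", "patient_id", "baseline", "visits"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "patient_id": {"type": "string", "minLength": 1},
    "latent_class": {
      "type": "string",
      "enum": ["full_responder", "partial_responder", "nonresponder"],
      "description": "Simulator ground-truth label; absent for real records."
    },
    "baseline": {
      "type": "object",
      "required": ["week", "items", "use_2wk", "dose_mg", "frequency"],
      "properties": {
        "week": {"const": 0},
        "items": {
          "type": "array",
          "minItems": 11,
          "maxItems": 11,
          "items": {"type": "integer", "enum": [0, 1]}
        },
        "use_2wk": {"type": "boolean"},
        "dose_mg": {"type": "number", "exclusiveMinimum": 0},
        "frequency": {"type": "string", "enum": ["once_daily", "twice_daily"]}
      }
    },
    "visits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["week", "items", "use_2wk", "days_missed",
                     "over_taking", "reasons", "dose_mg", "frequency"],
        "properties": {
          "week": {"type": "number", "exclusiveMinimum": 0},
          "items": {
            "type": "array",
            "minItems": 11,
            "maxItems": 11,
            "items": {"type": "integer", "enum": [0, 1]}
          },
          "use_2wk": {"type": "boolean"},
          "days_missed": {"type": "integer", "minimum": 0, "maximum": 7},
          "over_taking": {"type": "boolean"},
          "reasons": {
            "type": "array",
            "items": {
              "type": "string",
              "enum": ["side_effects", "cost", "craving", "withdrawal",
                       "forgot", "felt_better", "felt_worse", "ran_out",
                       "stigma", "dosing_inconvenient", "other"]
            }
          },
          "dose_mg": {"type": "number", "exclusiveMinimum": 0},
          "frequency": {"type": "string", "enum": ["once_daily", "twice_daily"]},
          "applied_action": {
            "type": "string",
            "description": "Optional log of the clinician's (or simulator's) choice applied since the previous visit."
          }
        }
      },
      "description": "Strictly increasing weeks."
    }
  }
}
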