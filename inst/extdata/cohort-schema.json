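{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "robndd-cohort-1.0",
  "title": "robndd cohort file",
  "type": "object",
  "required": ["schema_version", "studies"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "studies": {
      "type": "array",
      "items": { "$ref": "#/definitions/study" }
    }
  },
  "definitions": {
    "answer3": { "enum": ["yes", "no", "cant_tell"] },
    "study": {
      "type": "object",
      "required": ["study_id", "groups", "outcomes", "instruments",
                   "overlaps", "items_available", "criteria_available"],
      "properties": {
        "study_id": { "type": "string", "minLength": 1 },
        "citation": { "type": "string" },
        "items_available": { "type": "boolean" },
        "criteria_available": { "type": "boolean" },
        "groups": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/definitions/group" }
        },
        "outcomes": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/definitions/outcome" }
        },
        "instruments": {
          "type": "array",
          "items": { "$ref": "#/definitions/instrument" }
        },
        "overlaps": {
          "type": "array",
          "items": { "$ref": "#/definitions/overlap" }
        }
      }
    },
    "group": {
      "type": "object",
      "required": ["diagnosis_label", "n", "functioning"],
      "properties": {
        "diagnosis_label": { "type": "string" },
        "n": { "type": "integer", "minimum": 1 },
        "percent_female": { "type": ["number", "null"], "minimum": 0, "maximum": 100 },
        "first_wave_mean_age": { "type": ["number", "null"], "minimum": 0 },
        "followup_length": { "type": ["number", "null"], "minimum": 0 },
        "n_waves": { "type": ["integer", "null"], "minimum": 1 },
        "wave_mean_ages": {
          "type": ["array", "null"],
          "items": { "type": "number", "minimum": 0 }
        },
        "functioning": {
          "type": "object",
          "required": ["category"],
          "properties": {
            "category": {
              "enum": ["no_id", "mild_id", "moderate_severe_id", "unknown"]
            },
            "mean_iq": { "type": ["number", "null"] }
          }
        }
      }
    },
    "outcome": {
      "type": "object",
      "required": ["instrument_name", "score_label", "score_level",
                   "informants"],
      "properties": {
        "instrument_name": { "type": "string", "minLength": 1 },
        "score_label": { "type": "string", "minLength": 1 },
        "score_level": { "enum": ["total", "broadband", "subscale"] },
        "construct": { "type": "string" },
        "informants": {
          "type": "array",
          "items": { "enum": ["parent", "teacher", "child", "observation"] }
        },
        "child_rated": { "type": ["boolean", "null"] }
      }
    },
    "instrument": {
      "type": "object",
      "required": ["name", "designed_for_ndd", "adapted_for_ndd"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "designed_for_ndd": { "$ref": "#/definitions/answer3" },
        "adapted_for_ndd": { "$ref": "#/definitions/answer3" },
        "adaptation_note": { "type": ["string", "null"] }
      }
    },
    "overlap": {
      "type": "object",
      "required": ["outcome_ref", "item_text", "criterion_text",
                   "match_code", "addressed"],
      "properties": {
        "outcome_ref": { "type": "string", "minLength": 1 },
        "item_text": { "type": "string", "minLength": 1 },
        "criterion_text": { "type": "string", "minLength": 1 },
        "criterion_code": { "type": "string" },
        "match_code": { "enum": ["verbatim", "synonym", "concretisation"] },
        "addressed": { "$ref": "#/definitions/answer3" }
      }
    }
  }
}
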