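{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "segmap-cohort",
  "description": "Interchange format for symptom-drawing cohorts: patient records with polygon drawings of distributed findings in normalized body-template coordinates, lateralized finding/side pairs, segmental symptom flags and the final single-organ diagnosis.",
  "type": "object",
  "required": ["format", "patients"],
  "properties": {
    "format": { "const": "segmap-cohort" },
    "version": { "type": "integer" },
    "meta": { "type": "object" },
    "patients": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "organ"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "organ": {
            "enum": ["heart", "lungs", "stomach", "liver_gallbladder",
                     "kidneys_ureters", "other", "multi", "undiagnosed"]
          },
          "age": { "type": "number", "minimum": 0 },
          "sex": { "enum": ["female", "male"] },
          "drawings_lost": { "type": "boolean" },
          "drawings": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["sign", "view", "polygons"],
              "properties": {
                "sign": {
                  "enum": ["spontaneous_pain", "allodynia",
                           "superficial_hyperalgesia", "deep_hyperalgesia",
                           "superficial_skin_resistance", "muscle_resistance",
                           "defense", "asymmetric_hyperhidrosis",
                           "piloerection", "vasomotor_changes", "zoster",
                           "passive_movement_resistance"]
                },
                "view": { "enum": ["front", "back"] },
                "polygons": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["vertices"],
                    "properties": {
                      "closed": { "type": "boolean" },
                      "vertices": {
                        "type": "array",
                        "minItems": 3,
                        "items": {
                          "type": "array",
                          "minItems": 2,
                          "maxItems": 2,
                          "items": { "type": "number",
                                     "minimum": 0, "maximum": 1 }
                        }
                      }
                    }
                  }
                }
              }
            }
          },
          "lateralized": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["finding", "side"],
              "properties": {
                "finding": {
                  "enum": ["mydriasis", "glossy_eye", "eyelid_separation",
                           "tense_facial_muscles", "asymmetric_posture",
                           "reduced_respiration"]
                },
                "side": { "enum": ["left", "right"] }
              }
            }
          },
          "symptoms": {
            "type": "array",
            "uniqueItems": true,
            "items": {
              "enum": ["nausea", "vomiting", "constipation", "diarrhea",
                       "meteorism", "urinary_retention"]
            }
          }
        }
      }
    }
  }
}
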