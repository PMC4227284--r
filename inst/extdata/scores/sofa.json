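{
  "name": "SOFA",
  "version": "1.0",
  "provenance": "Sequential Organ Failure Assessment. Transcribed from the original consensus description (Vincent et al., Intensive Care Med 1996;22:707-710). Respiration scored on PaO2/FiO2 alone (3-4 point bands applied without the ventilatory-support requirement; ward cohort is unventilated). Cardiovascular scored on mean arterial pressure with a vasopressor escalation hook that is inert for ward patients; urine-output criterion of the renal component omitted (not charted on wards), creatinine bands only.",
  "total_range": [0, 24],
  "components": [
    {
      "name": "pf_ratio", "unit": "mm Hg", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 100, "points": 4},
        {"lo": 100, "hi": 200, "points": 3},
        {"lo": 200, "hi": 300, "points": 2},
        {"lo": 300, "hi": 400, "points": 1},
        {"lo": 400, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "platelets", "unit": "10^9/L", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 20, "points": 4},
        {"lo": 20, "hi": 50, "points": 3},
        {"lo": 50, "hi": 100, "points": 2},
        {"lo": 100, "hi": 150, "points": 1},
        {"lo": 150, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "bilirubin", "unit": "mg/dL", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 1.2, "points": 0},
        {"lo": 1.2, "hi": 2.0, "points": 1},
        {"lo": 2.0, "hi": 6.0, "points": 2},
        {"lo": 6.0, "hi": 12.0, "points": 3},
        {"lo": 12.0, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "map", "unit": "mm Hg", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 70, "points": 1},
        {"lo": 70, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "gcs", "unit": "points", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 6, "points": 4},
        {"lo": 6, "hi": 10, "points": 3},
        {"lo": 10, "hi": 13, "points": 2},
        {"lo": 13, "hi": 15, "points": 1},
        {"lo": 15, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "creatinine", "unit": "mg/dL", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 1.2, "points": 0},
        {"lo": 1.2, "hi": 2.0, "points": 1},
        {"lo": 2.0, "hi": 3.5, "points": 2},
        {"lo": 3.5, "hi": 5.0, "points": 3},
        {"lo": 5.0, "hi": "inf", "points": 4}
      ]
    }
  ],
  "special_terms": [
    {"type": "hook", "name": "sofa_vasopressors"}
  ]
}
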