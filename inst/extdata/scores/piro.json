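{
  "name": "PIRO",
  "version": "1.0",
  "provenance": "Predisposition / Infection / Response / Organ dysfunction staging for emergency-department patients with suspected infection, after Howell et al., Crit Care Med 2011;39:322-327. Best-effort transcription (assumed source; original article unavailable for re-verification when this fixture was authored). Predisposition: age, nursing home, malignancy, COPD, chronic liver disease. Infection: pneumonia. Response: tachypnea, tachycardia, bandemia. Organ dysfunction: hypotension, azotemia, lactate, thrombocytopenia.",
  "total_range": [0, 19],
  "components": [
    {
      "name": "age", "unit": "years", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 65, "points": 0},
        {"lo": 65, "hi": 80, "points": 1},
        {"lo": 80, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "respiratory_rate", "unit": "breaths/min", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 21, "points": 0},
        {"lo": 21, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 121, "points": 0},
        {"lo": 121, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "band_fraction", "unit": "%", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 5, "points": 0},
        {"lo": 5, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "systolic_bp", "unit": "mm Hg", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 90, "points": 2},
        {"lo": 90, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "bun", "unit": "mg/dL", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 21, "points": 0},
        {"lo": 21, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "lactate", "unit": "mmol/L", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 4, "points": 0},
        {"lo": 4, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "platelets", "unit": "10^9/L", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 150, "points": 1},
        {"lo": 150, "hi": "inf", "points": 0}
      ]
    }
  ],
  "special_terms": [
    {"type": "flag", "component": "nursing_home", "points": 1},
    {"type": "flag", "component": "malignancy", "points": 2},
    {"type": "flag", "component": "copd", "points": 1},
    {"type": "flag", "component": "liver_disease", "points": 2},
    {"type": "flag", "component": "pneumonia", "points": 2}
  ]
}
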