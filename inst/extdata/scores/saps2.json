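{
  "name": "SAPS2",
  "version": "1.0",
  "provenance": "Simplified Acute Physiology Score II. Transcribed from Le Gall et al., JAMA 1993;270:2957-2963. Serum urea bands expressed as BUN in mg/dL. PaO2/FiO2 term applies only under mechanical ventilation or CPAP (hook; inert on the wards). Urine output is not charted on the wards and is scored from its normal default. Chronic-disease and admission-type terms via hooks.",
  "total_range": [0, 163],
  "components": [
    {
      "name": "age", "unit": "years", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 40, "points": 0},
        {"lo": 40, "hi": 60, "points": 7},
        {"lo": 60, "hi": 70, "points": 12},
        {"lo": 70, "hi": 75, "points": 15},
        {"lo": 75, "hi": 80, "points": 16},
        {"lo": 80, "hi": "inf", "points": 18}
      ]
    },
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 40, "points": 11},
        {"lo": 40, "hi": 70, "points": 2},
        {"lo": 70, "hi": 120, "points": 0},
        {"lo": 120, "hi": 160, "points": 4},
        {"lo": 160, "hi": "inf", "points": 7}
      ]
    },
    {
      "name": "systolic_bp", "unit": "mm Hg", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 70, "points": 13},
        {"lo": 70, "hi": 100, "points": 5},
        {"lo": 100, "hi": 200, "points": 0},
        {"lo": 200, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "temperature", "unit": "degC", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 39, "points": 0},
        {"lo": 39, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "bun", "unit": "mg/dL", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 28, "points": 0},
        {"lo": 28, "hi": 84, "points": 6},
        {"lo": 84, "hi": "inf", "points": 10}
      ]
    },
    {
      "name": "wbc", "unit": "10^9/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 1, "points": 12},
        {"lo": 1, "hi": 20, "points": 0},
        {"lo": 20, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "potassium", "unit": "mmol/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 3, "points": 3},
        {"lo": 3, "hi": 5, "points": 0},
        {"lo": 5, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "sodium", "unit": "mmol/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 125, "points": 5},
        {"lo": 125, "hi": 145, "points": 0},
        {"lo": 145, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "bicarbonate", "unit": "mmol/L", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 15, "points": 6},
        {"lo": 15, "hi": 20, "points": 3},
        {"lo": 20, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "bilirubin", "unit": "mg/dL", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 4, "points": 0},
        {"lo": 4, "hi": 6, "points": 4},
        {"lo": 6, "hi": "inf", "points": 9}
      ]
    },
    {
      "name": "gcs", "unit": "points", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 6, "points": 26},
        {"lo": 6, "hi": 9, "points": 13},
        {"lo": 9, "hi": 11, "points": 7},
        {"lo": 11, "hi": 14, "points": 5},
        {"lo": 14, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "urine_output", "unit": "L/day", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 0.5, "points": 11},
        {"lo": 0.5, "hi": 1.0, "points": 4},
        {"lo": 1.0, "hi": "inf", "points": 0}
      ]
    }
  ],
  "special_terms": [
    {"type": "hook", "name": "saps2_ventilated_pf"},
    {"type": "hook", "name": "saps2_chronic_disease"},
    {"type": "hook", "name": "saps2_admission_type"}
  ]
}
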