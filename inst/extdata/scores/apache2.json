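{
  "name": "APACHE2",
  "version": "1.0",
  "provenance": "Acute Physiology and Chronic Health Evaluation II. Transcribed from Knaus et al., Crit Care Med 1985;13:818-829. Acute-physiology bands for 11 variables plus Glasgow Coma Scale hook (15 minus GCS); oxygenation hook selects A-aDO2 bands at FiO2 >= 0.5 and PaO2 bands below; chronic-health points via the severe-organ-insufficiency flag (nonoperative admission, +5). Acute-renal-failure doubling of creatinine points not applied (renal-failure timing not charted).",
  "total_range": [0, 71],
  "components": [
    {
      "name": "temperature", "unit": "degC", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 30, "points": 4},
        {"lo": 30, "hi": 32, "points": 3},
        {"lo": 32, "hi": 34, "points": 2},
        {"lo": 34, "hi": 36, "points": 1},
        {"lo": 36, "hi": 38.5, "points": 0},
        {"lo": 38.5, "hi": 39, "points": 1},
        {"lo": 39, "hi": 41, "points": 3},
        {"lo": 41, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "map", "unit": "mm Hg", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 50, "points": 4},
        {"lo": 50, "hi": 70, "points": 2},
        {"lo": 70, "hi": 110, "points": 0},
        {"lo": 110, "hi": 130, "points": 2},
        {"lo": 130, "hi": 160, "points": 3},
        {"lo": 160, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 40, "points": 4},
        {"lo": 40, "hi": 55, "points": 3},
        {"lo": 55, "hi": 70, "points": 2},
        {"lo": 70, "hi": 110, "points": 0},
        {"lo": 110, "hi": 140, "points": 2},
        {"lo": 140, "hi": 180, "points": 3},
        {"lo": 180, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "respiratory_rate", "unit": "breaths/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 6, "points": 4},
        {"lo": 6, "hi": 10, "points": 2},
        {"lo": 10, "hi": 12, "points": 1},
        {"lo": 12, "hi": 25, "points": 0},
        {"lo": 25, "hi": 35, "points": 1},
        {"lo": 35, "hi": 50, "points": 3},
        {"lo": 50, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "ph", "unit": "pH units", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 7.15, "points": 4},
        {"lo": 7.15, "hi": 7.25, "points": 3},
        {"lo": 7.25, "hi": 7.33, "points": 2},
        {"lo": 7.33, "hi": 7.5, "points": 0},
        {"lo": 7.5, "hi": 7.6, "points": 1},
        {"lo": 7.6, "hi": 7.7, "points": 3},
        {"lo": 7.7, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "sodium", "unit": "mmol/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 111, "points": 4},
        {"lo": 111, "hi": 120, "points": 3},
        {"lo": 120, "hi": 130, "points": 2},
        {"lo": 130, "hi": 150, "points": 0},
        {"lo": 150, "hi": 155, "points": 1},
        {"lo": 155, "hi": 160, "points": 2},
        {"lo": 160, "hi": 180, "points": 3},
        {"lo": 180, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "potassium", "unit": "mmol/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 2.5, "points": 4},
        {"lo": 2.5, "hi": 3.0, "points": 2},
        {"lo": 3.0, "hi": 3.5, "points": 1},
        {"lo": 3.5, "hi": 5.5, "points": 0},
        {"lo": 5.5, "hi": 6.0, "points": 1},
        {"lo": 6.0, "hi": 7.0, "points": 3},
        {"lo": 7.0, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "creatinine", "unit": "mg/dL", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 0.6, "points": 2},
        {"lo": 0.6, "hi": 1.5, "points": 0},
        {"lo": 1.5, "hi": 2.0, "points": 2},
        {"lo": 2.0, "hi": 3.5, "points": 3},
        {"lo": 3.5, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "hematocrit", "unit": "%", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 20, "points": 4},
        {"lo": 20, "hi": 30, "points": 2},
        {"lo": 30, "hi": 46, "points": 0},
        {"lo": 46, "hi": 50, "points": 1},
        {"lo": 50, "hi": 60, "points": 2},
        {"lo": 60, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "wbc", "unit": "10^9/L", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 1, "points": 4},
        {"lo": 1, "hi": 3, "points": 2},
        {"lo": 3, "hi": 15, "points": 0},
        {"lo": 15, "hi": 20, "points": 1},
        {"lo": 20, "hi": 40, "points": 2},
        {"lo": 40, "hi": "inf", "points": 4}
      ]
    },
    {
      "name": "age", "unit": "years", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 45, "points": 0},
        {"lo": 45, "hi": 55, "points": 2},
        {"lo": 55, "hi": 65, "points": 3},
        {"lo": 65, "hi": 75, "points": 5},
        {"lo": 75, "hi": "inf", "points": 6}
      ]
    }
  ],
  "special_terms": [
    {"type": "hook", "name": "apache2_gcs"},
    {"type": "hook", "name": "apache2_oxygenation"},
    {"type": "flag", "component": "chronic_organ_insufficiency", "points": 5}
  ]
}
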