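{
  "name": "MEWS",
  "version": "1.0",
  "provenance": "Modified Early Warning Score. Transcribed from Subbe et al., QJM 2001;94:521-526. Consciousness item scored from the AVPU scale via its near-equivalent GCS value (A=15, V=13, P=8, U=3), so the GCS bands below reproduce the A/V/P/U point ladder 0/1/2/3.",
  "total_range": [0, 14],
  "components": [
    {
      "name": "systolic_bp", "unit": "mm Hg", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 71, "points": 3},
        {"lo": 71, "hi": 81, "points": 2},
        {"lo": 81, "hi": 101, "points": 1},
        {"lo": 101, "hi": 200, "points": 0},
        {"lo": 200, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 40, "points": 2},
        {"lo": 40, "hi": 51, "points": 1},
        {"lo": 51, "hi": 101, "points": 0},
        {"lo": 101, "hi": 111, "points": 1},
        {"lo": 111, "hi": 130, "points": 2},
        {"lo": 130, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "respiratory_rate", "unit": "breaths/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 9, "points": 2},
        {"lo": 9, "hi": 15, "points": 0},
        {"lo": 15, "hi": 21, "points": 1},
        {"lo": 21, "hi": 30, "points": 2},
        {"lo": 30, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "temperature", "unit": "degC", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 35, "points": 2},
        {"lo": 35, "hi": 38.5, "points": 0},
        {"lo": 38.5, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "gcs", "unit": "points", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 4, "points": 3},
        {"lo": 4, "hi": 9, "points": 2},
        {"lo": 9, "hi": 15, "points": 1},
        {"lo": 15, "hi": "inf", "points": 0}
      ]
    }
  ],
  "special_terms": []
}
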