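{
  "name": "SCS",
  "version": "1.0",
  "provenance": "Simple Clinical Score for acutely ill medical admissions, after Kellett & Deane, QJM 2006;99:771-781. Best-effort transcription (assumed source; original article unavailable for re-verification when this fixture was authored). Functional-status items (breathless on presentation, unable to stand unaided, abnormal ECG, new stroke) are retained in the fixture but score 0 whenever the underlying flag is not collected, matching a cohort in which these items were not charted.",
  "total_range": [0, 25],
  "components": [
    {
      "name": "age", "unit": "years", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 50, "points": 0},
        {"lo": 50, "hi": 70, "points": 1},
        {"lo": 70, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 40, "points": 2},
        {"lo": 40, "hi": 100, "points": 0},
        {"lo": 100, "hi": 120, "points": 1},
        {"lo": 120, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "systolic_bp", "unit": "mm Hg", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 100, "points": 2},
        {"lo": 100, "hi": 250, "points": 0},
        {"lo": 250, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "respiratory_rate", "unit": "breaths/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 9, "points": 2},
        {"lo": 9, "hi": 20, "points": 0},
        {"lo": 20, "hi": 30, "points": 1},
        {"lo": 30, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "temperature", "unit": "degC", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 35, "points": 2},
        {"lo": 35, "hi": 39, "points": 0},
        {"lo": 39, "hi": "inf", "points": 1}
      ]
    },
    {
      "name": "spo2", "unit": "%", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 90, "points": 2},
        {"lo": 90, "hi": 94, "points": 1},
        {"lo": 94, "hi": "inf", "points": 0}
      ]
    }
  ],
  "special_terms": [
    {"type": "flag", "component": "diabetes", "points": 1},
    {"type": "flag", "component": "breathless", "points": 1},
    {"type": "flag", "component": "abnormal_ecg", "points": 2},
    {"type": "flag", "component": "unable_to_stand", "points": 2},
    {"type": "flag", "component": "nursing_home", "points": 1},
    {"type": "flag", "component": "new_stroke", "points": 2},
    {"type": "hook", "name": "scs_consciousness"}
  ]
}
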