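{
  "name": "ViEWS",
  "version": "1.0",
  "provenance": "VitalPac Early Warning Score. Transcribed from Prytherch et al., Resuscitation 2010;81:932-937. Consciousness item: alert (GCS 15 under the AVPU mapping) scores 0, any depressed level scores 3. Supplemental oxygen scores 3 via flag term.",
  "total_range": [0, 21],
  "components": [
    {
      "name": "heart_rate", "unit": "beats/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 41, "points": 3},
        {"lo": 41, "hi": 51, "points": 1},
        {"lo": 51, "hi": 91, "points": 0},
        {"lo": 91, "hi": 111, "points": 1},
        {"lo": 111, "hi": 131, "points": 2},
        {"lo": 131, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "respiratory_rate", "unit": "breaths/min", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 9, "points": 3},
        {"lo": 9, "hi": 12, "points": 1},
        {"lo": 12, "hi": 21, "points": 0},
        {"lo": 21, "hi": 25, "points": 2},
        {"lo": 25, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "temperature", "unit": "degC", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 35.1, "points": 3},
        {"lo": 35.1, "hi": 36.1, "points": 1},
        {"lo": 36.1, "hi": 38.1, "points": 0},
        {"lo": 38.1, "hi": 39.1, "points": 1},
        {"lo": 39.1, "hi": "inf", "points": 2}
      ]
    },
    {
      "name": "systolic_bp", "unit": "mm Hg", "direction": "both",
      "bands": [
        {"lo": "-inf", "hi": 91, "points": 3},
        {"lo": 91, "hi": 101, "points": 2},
        {"lo": 101, "hi": 111, "points": 1},
        {"lo": 111, "hi": 250, "points": 0},
        {"lo": 250, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "spo2", "unit": "%", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 92, "points": 3},
        {"lo": 92, "hi": 94, "points": 2},
        {"lo": 94, "hi": 96, "points": 1},
        {"lo": 96, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "gcs", "unit": "points", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 15, "points": 3},
        {"lo": 15, "hi": "inf", "points": 0}
      ]
    }
  ],
  "special_terms": [
    {"type": "flag", "component": "supplemental_o2", "points": 3}
  ]
}
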