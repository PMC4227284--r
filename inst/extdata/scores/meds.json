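{
  "name": "MEDS",
  "version": "1.0",
  "provenance": "Mortality in Emergency Department Sepsis score, after Shapiro et al., Crit Care Med 2003;31:670-675. Best-effort transcription (assumed source; original article unavailable for re-verification when this fixture was authored): terminal illness 6, tachypnea or hypoxia 3, septic shock 3, platelets <150 x10^9/L 3, bands >5% 3, age >65 y 3, lower respiratory infection 2, nursing-home residence 2, altered mental status 2.",
  "total_range": [0, 27],
  "components": [
    {
      "name": "age", "unit": "years", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 65, "points": 0},
        {"lo": 65, "hi": "inf", "points": 3}
      ]
    },
    {
      "name": "platelets", "unit": "10^9/L", "direction": "low",
      "bands": [
        {"lo": "-inf", "hi": 150, "points": 3},
        {"lo": 150, "hi": "inf", "points": 0}
      ]
    },
    {
      "name": "band_fraction", "unit": "%", "direction": "high",
      "bands": [
        {"lo": "-inf", "hi": 5, "points": 0},
        {"lo": 5, "hi": "inf", "points": 3}
      ]
    }
  ],
  "special_terms": [
    {"type": "flag", "component": "terminal_illness", "points": 6},
    {"type": "flag", "component": "septic_shock", "points": 3},
    {"type": "flag", "component": "pneumonia", "points": 2},
    {"type": "flag", "component": "nursing_home", "points": 2},
    {"type": "hook", "name": "meds_resp_distress"},
    {"type": "hook", "name": "meds_altered_mental_status"}
  ]
}
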