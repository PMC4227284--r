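{
  "description": "Normal physiologic midpoints shared by the assume-normal imputation rule and the synthetic cohort generator (single source of truth). 'mean' is the normal midpoint (chosen so that, wherever such a value exists, it scores 0 points in all nine systems); 'sd' is the between-observation spread used by the generator; 'derange' is the direction in which acute deterioration moves the value; 'lo'/'hi' are plausibility truncation bounds enforced at generation.",
  "analytes": {
    "heart_rate":      {"unit": "beats/min",   "kind": "vital", "mean": 75,   "sd": 12,   "derange": "high", "lo": 10,   "hi": 300},
    "respiratory_rate":{"unit": "breaths/min", "kind": "vital", "mean": 14,   "sd": 2.5,  "derange": "high", "lo": 4,    "hi": 80},
    "systolic_bp":     {"unit": "mm Hg",       "kind": "vital", "mean": 115,  "sd": 12,   "derange": "low",  "lo": 30,   "hi": 300},
    "diastolic_bp":    {"unit": "mm Hg",       "kind": "vital", "mean": 72,   "sd": 8,    "derange": "low",  "lo": 15,   "hi": 200},
    "temperature":     {"unit": "degC",        "kind": "vital", "mean": 37.0, "sd": 0.4,  "derange": "high", "lo": 30,   "hi": 43},
    "spo2":            {"unit": "%",           "kind": "vital", "mean": 98,   "sd": 1.5,  "derange": "low",  "lo": 50,   "hi": 100},
    "wbc":             {"unit": "10^9/L",      "kind": "lab",   "mean": 8,    "sd": 2.5,  "derange": "high", "lo": 0.1,  "hi": 100},
    "platelets":       {"unit": "10^9/L",      "kind": "lab",   "mean": 250,  "sd": 60,   "derange": "low",  "lo": 1,    "hi": 1500},
    "bilirubin":       {"unit": "mg/dL",       "kind": "lab",   "mean": 0.8,  "sd": 0.25, "derange": "high", "lo": 0.05, "hi": 40},
    "creatinine":      {"unit": "mg/dL",       "kind": "lab",   "mean": 0.9,  "sd": 0.2,  "derange": "high", "lo": 0.1,  "hi": 20},
    "bun":             {"unit": "mg/dL",       "kind": "lab",   "mean": 14,   "sd": 4,    "derange": "high", "lo": 1,    "hi": 200},
    "sodium":          {"unit": "mmol/L",      "kind": "lab",   "mean": 140,  "sd": 3,    "derange": "low",  "lo": 100,  "hi": 190},
    "potassium":       {"unit": "mmol/L",      "kind": "lab",   "mean": 4.2,  "sd": 0.35, "derange": "high", "lo": 1.5,  "hi": 9.5},
    "bicarbonate":     {"unit": "mmol/L",      "kind": "lab",   "mean": 24,   "sd": 2.5,  "derange": "low",  "lo": 4,    "hi": 50},
    "hematocrit":      {"unit": "%",           "kind": "lab",   "mean": 40,   "sd": 4,    "derange": "low",  "lo": 10,   "hi": 70},
    "glucose":         {"unit": "mg/dL",       "kind": "lab",   "mean": 95,   "sd": 15,   "derange": "high", "lo": 20,   "hi": 1000},
    "albumin":         {"unit": "g/dL",        "kind": "lab",   "mean": 4.0,  "sd": 0.35, "derange": "low",  "lo": 0.8,  "hi": 6},
    "lactate":         {"unit": "mmol/L",      "kind": "lab",   "mean": 1.0,  "sd": 0.35, "derange": "high", "lo": 0.1,  "hi": 25},
    "band_fraction":   {"unit": "%",           "kind": "lab",   "mean": 2,    "sd": 1.5,  "derange": "high", "lo": 0,    "hi": 60},
    "pao2":            {"unit": "mm Hg",       "kind": "abg",   "mean": 95,   "sd": 8,    "derange": "low",  "lo": 30,   "hi": 600},
    "paco2":           {"unit": "mm Hg",       "kind": "abg",   "mean": 40,   "sd": 4,    "derange": "low",  "lo": 10,   "hi": 120},
    "ph":              {"unit": "pH units",    "kind": "abg",   "mean": 7.40, "sd": 0.03, "derange": "low",  "lo": 6.8,  "hi": 7.9},
    "urine_output":    {"unit": "L/day",       "kind": "derived", "mean": 1.5, "sd": 0.3, "derange": "low",  "lo": 0,    "hi": 10}
  }
}
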