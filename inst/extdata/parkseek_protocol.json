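{
  "timezone": "America/Toronto",
  "max_radial_m": 30,
  "max_gap_s": 43200,
  "surveys": ["WHO5", "WHO5_PROMIS", "WHO5_VIDEO"],
  "criteria": {
    "min_unique_days": 7,
    "min_momentary_responses": 1,
    "require_exit_survey": true
  },
  "delivery_delay_s": 0,
  "rules": [
    {
      "rule_id": "morning",
      "kind": "TIME_WINDOW",
      "expiry_s": 3600,
      "survey_ref": "WHO5_PROMIS",
      "window_start": "09:00",
      "window_end": "10:00",
      "max_per_day": 1
    },
    {
      "rule_id": "evening",
      "kind": "TIME_WINDOW",
      "expiry_s": 3600,
      "survey_ref": "WHO5",
      "window_start": "19:00",
      "window_end": "20:00",
      "max_per_day": 1
    },
    {
      "rule_id": "engagement",
      "kind": "DWELL",
      "expiry_s": 3600,
      "survey_ref": "WHO5_VIDEO",
      "min_dwell_s": 600,
      "geofence_class": "park"
    },
    {
      "rule_id": "followup",
      "kind": "FOLLOWUP_DWELL",
      "expiry_s": 3600,
      "survey_ref": "WHO5_VIDEO",
      "min_dwell_s": 2700,
      "geofence_class": "park"
    },
    {
      "rule_id": "exit",
      "kind": "EXIT",
      "expiry_s": 3600,
      "survey_ref": "WHO5",
      "geofence_class": "park"
    }
  ]
}
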