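{
  "version": "gusnet-default-1",
  "note": "Synthetic default scoring scheme. The published GUS instrument's item weights are not publicly deposited; this scheme honours the documented structure (five boxes, 0-50 total, nurse-measured attempts and time in boxes 2-4, ten closed questions in box 5) with plausible placeholder weights. It is NOT the validated instrument's weighting.",
  "boxes": [
    {
      "box_id": 1,
      "label": "Preference at glance",
      "max_points": 10,
      "items": [
        {
          "id": "glance_preference",
          "kind": "categorical",
          "options": {
            "first_choice": 6,
            "second_choice": 4,
            "third_choice": 2,
            "not_preferred": 0
          }
        },
        {
          "id": "willingness_to_use",
          "kind": "categorical",
          "options": {
            "definitely": 4,
            "probably": 2,
            "no": 0
          }
        }
      ]
    },
    {
      "box_id": 2,
      "label": "Critical issues during preparation",
      "max_points": 10,
      "items": [
        {
          "id": "critical_issues",
          "kind": "count-threshold",
          "breaks": [0, 1, 2, 3],
          "points": [10, 7, 4, 0]
        }
      ]
    },
    {
      "box_id": 3,
      "label": "Attempts to correct actuation",
      "max_points": 10,
      "items": [
        {
          "id": "actuation_attempts",
          "kind": "count-threshold",
          "breaks": [1, 2, 3, 5],
          "points": [10, 7, 4, 0]
        }
      ]
    },
    {
      "box_id": 4,
      "label": "Time to autonomy",
      "max_points": 10,
      "items": [
        {
          "id": "seconds_to_autonomy",
          "kind": "time-threshold",
          "breaks": [0, 30, 60, 120],
          "points": [10, 7, 4, 0]
        }
      ]
    },
    {
      "box_id": 5,
      "label": "Acceptance and preference (ten closed questions)",
      "max_points": 10,
      "items": [
        {"id": "q01", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q02", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q03", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q04", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q05", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q06", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q07", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q08", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q09", "kind": "categorical", "options": {"yes": 1, "no": 0}},
        {"id": "q10", "kind": "categorical", "options": {"yes": 1, "no": 0}}
      ]
    }
  ]
}
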