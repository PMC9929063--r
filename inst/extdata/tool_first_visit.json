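{
  "format": "screening_tool",
  "version": 1,
  "period": "first_visit",
  "provenance": "transcribed_from_paper",
  "rounding_mode": "times100_one_decimal",
  "scoring": [
    {"item_id": "maternal_feelings",        "sprc": 0.069, "score": 6.9},
    {"item_id": "depression_symptoms",      "sprc": 0.019, "score": 1.9},
    {"item_id": "family_social_support",    "sprc": 0.117, "score": 11.7},
    {"item_id": "economic_status",          "sprc": 0.076, "score": 7.6},
    {"item_id": "partner_status",           "sprc": 0.129, "score": 12.9},
    {"item_id": "maternal_mental_disorder", "sprc": 0.160, "score": 16.0},
    {"item_id": "worries_older_child",      "sprc": 0.028, "score": 2.8},
    {"item_id": "multiple_pregnancy",       "sprc": 0.105, "score": 10.5},
    {"item_id": "children_ge3",             "sprc": 0.141, "score": 14.1},
    {"item_id": "maternal_age_lt25",        "sprc": 0.212, "score": 21.2}
  ],
  "step1_threshold": 22,
  "step2": {"rule": "any_of",
            "items": ["family_social_support", "maternal_mental_disorder",
                      "worries_older_child", "multiple_pregnancy"]},
  "step3": {"min_count": 2,
            "items": ["depression_symptoms", "maternal_mental_disorder",
                      "consultation_request"]},
  "mandatory_referral_items": ["drug_use_mother", "drug_use_partner"],
  "step_semantics": "sequential_narrowing",
  "derivation_metrics": {"auc": 0.96, "sensitivity": 0.92, "specificity": 0.92}
}
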