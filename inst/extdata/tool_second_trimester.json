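{
  "format": "screening_tool",
  "version": 1,
  "period": "second_trimester",
  "provenance": "transcribed_from_paper",
  "rounding_mode": "times100_nearest_integer",
  "scoring": [
    {"item_id": "maternity_life",        "sprc": 0.167, "score": 17},
    {"item_id": "talking_with_partner",  "sprc": 0.108, "score": 11},
    {"item_id": "partner_violence",      "sprc": 0.150, "score": 15},
    {"item_id": "childhood_abuse",       "sprc": 0.135, "score": 14},
    {"item_id": "depression_symptoms",   "sprc": 0.058, "score": 6},
    {"item_id": "family_social_support", "sprc": 0.072, "score": 7},
    {"item_id": "smoking",               "sprc": 0.165, "score": 17},
    {"item_id": "consultation_request",  "sprc": 0.053, "score": 5}
  ],
  "step1_threshold": 14,
  "step2": {"rule": "any_of",
            "items": ["talking_with_partner", "partner_violence", "smoking"]},
  "step3": {"min_count": 1,
            "items": ["talking_with_partner", "partner_violence",
                      "depression_symptoms", "consultation_request"]},
  "mandatory_referral_items": [],
  "step_semantics": "sequential_narrowing",
  "derivation_metrics": {"auc": 0.77, "sensitivity": 0.82, "specificity": 0.62}
}
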