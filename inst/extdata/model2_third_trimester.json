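{
  "format": "model2_coefficients",
  "version": 1,
  "period": "third_trimester",
  "provenance": "transcribed_from_paper",
  "rounding_mode": "times100_nearest_integer",
  "comment": "Third-trimester adjusted standardized coefficients; the derived candidate tool was rejected (AUC below the screening-acceptability bound), so no screening tool ships for this period.",
  "coefficients": [
    {"item_id": "depression_symptoms",     "sprc": 0.2880, "score": 29},
    {"item_id": "worries_older_child",     "sprc": 0.1226, "score": 12},
    {"item_id": "family_social_support",   "sprc": 0.2760, "score": 28},
    {"item_id": "childbirth_preparation",  "sprc": 0.0653, "score": 7},
    {"item_id": "consultation_request",    "sprc": 0.5232, "score": 52},
    {"item_id": "health_checkups",         "sprc": 0.2416, "score": 24},
    {"item_id": "fetal_disease_fgr",       "sprc": 0.4354, "score": 44}
  ],
  "roc": {"cutoff": 7, "auc": 0.46, "sensitivity": 0.43, "specificity": 0.57}
}
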