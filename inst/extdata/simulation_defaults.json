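{
  "format": "simulation_defaults",
  "version": 1,
  "comment": "Default generating parameters for synthetic interview cohorts. Outcome prevalences and item odds ratios follow the published derivation cohorts (crude odds ratios of the need-for-support outcome); baseline item prevalences in the outcome-negative stratum are NOT published anywhere and are approximate, field-plausible values chosen once so that simulated first-stage positive rates land broadly near the published ones. Items whose published crude fit diverged (no exposed outcome-positive cases) carry an approximate small odds ratio instead. EPDS effect odds ratios follow the published adjusted estimates; items excluded there as sparse carry 1.0.",
  "missing_rate": 0.015,
  "epds_prevalence_ge9": 0.067,
  "periods": {
    "first_visit": {
      "outcome_prevalence": 0.025,
      "items": {
        "maternal_feelings":        {"baseline": 0.070, "or": 10.985, "epds_or": 6.51},
        "partner_feelings":         {"baseline": 0.050, "or": 5.566,  "epds_or": 0.35},
        "depression_symptoms":      {"baseline": 0.100, "or": 3.987,  "epds_or": 2.86},
        "family_social_support":    {"baseline": 0.020, "or": 13.489, "epds_or": 1.0},
        "economic_status":          {"baseline": 0.070, "or": 10.235, "epds_or": 1.46},
        "partner_status":           {"baseline": 0.080, "or": 6.433,  "epds_or": 2.44},
        "maternal_mental_disorder": {"baseline": 0.060, "or": 13.593, "epds_or": 4.38},
        "drug_use_mother":          {"baseline": 0.002, "or": 3.0,    "epds_or": 1.0},
        "drug_use_partner":         {"baseline": 0.002, "or": 3.0,    "epds_or": 1.0},
        "worries_older_child":      {"baseline": 0.120, "or": 2.154,  "epds_or": 1.41},
        "consultation_request":     {"baseline": 0.070, "or": 3.689,  "epds_or": 3.22},
        "multiple_pregnancy":       {"baseline": 0.020, "or": 4.96,   "epds_or": 1.97},
        "children_ge3":             {"baseline": 0.050, "or": 7.239,  "epds_or": 0.85},
        "maternal_age_lt25":        {"baseline": 0.080, "or": 15.49,  "epds_or": 0.8}
      }
    },
    "second_trimester": {
      "outcome_prevalence": 0.06,
      "items": {
        "maternity_life":        {"baseline": 0.150, "or": 4.165,  "epds_or": 3.15},
        "talking_with_partner":  {"baseline": 0.030, "or": 6.773,  "epds_or": 1.76},
        "partner_violence":      {"baseline": 0.010, "or": 12.918, "epds_or": 1.12},
        "worries_older_child":   {"baseline": 0.100, "or": 1.342,  "epds_or": 1.14},
        "childhood_abuse":       {"baseline": 0.030, "or": 6.413,  "epds_or": 0.77},
        "depression_symptoms":   {"baseline": 0.120, "or": 2.74,   "epds_or": 2.42},
        "family_social_support": {"baseline": 0.005, "or": 7.691,  "epds_or": 1.0},
        "smoking":               {"baseline": 0.010, "or": 24.113, "epds_or": 5.85},
        "alcohol_use":           {"baseline": 0.004, "or": 2.0,    "epds_or": 1.0},
        "consultation_request":  {"baseline": 0.100, "or": 2.051,  "epds_or": 1.96},
        "health_checkups":       {"baseline": 0.005, "or": 2.0,    "epds_or": 1.0}
      }
    },
    "third_trimester": {
      "outcome_prevalence": 0.06,
      "items": {
        "depression_symptoms":       {"baseline": 0.100, "or": 2.329,  "epds_or": 4.65},
        "worries_older_child":       {"baseline": 0.120, "or": 3.039,  "epds_or": 1.7},
        "pregnancy_course_concerns": {"baseline": 0.120, "or": 2.483,  "epds_or": 2.01},
        "family_social_support":     {"baseline": 0.005, "or": 53.397, "epds_or": 24.14},
        "childbirth_preparation":    {"baseline": 0.050, "or": 3.416,  "epds_or": 0.33},
        "consultation_request":      {"baseline": 0.080, "or": 4.458,  "epds_or": 1.71},
        "health_checkups":           {"baseline": 0.005, "or": 12.182, "epds_or": 1.0},
        "fetal_disease_fgr":         {"baseline": 0.040, "or": 7.0,    "epds_or": 0.56}
      }
    },
    "postpartum": {
      "outcome_prevalence": 0.23,
      "items": {
        "fetal_condition":       {"baseline": 0.050, "or": 2.0, "epds_or": 1.0},
        "childcare_feelings":    {"baseline": 0.080, "or": 3.0, "epds_or": 2.0},
        "partner_support":       {"baseline": 0.060, "or": 3.0, "epds_or": 2.0},
        "family_social_support": {"baseline": 0.010, "or": 5.0, "epds_or": 1.0},
        "childcare_difficulty":  {"baseline": 0.100, "or": 3.0, "epds_or": 2.0},
        "consultation_request":  {"baseline": 0.100, "or": 2.5, "epds_or": 1.5},
        "epds":                  {"baseline": 0.060, "or": 2.5, "epds_or": 1.0}
      }
    }
  }
}
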