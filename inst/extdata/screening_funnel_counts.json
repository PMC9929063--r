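{
  "format": "screening_funnel_counts",
  "version": 1,
  "comment": "Published stage-by-stage screening yields and outcome overlaps for the derivation cohorts, plus postpartum EPDS>=9 counts among completers of each period's sheet. admin = records requiring public-health-center cooperation among that stage's survivors (null where not reported).",
  "first_visit": {
    "n_screened": 558,
    "step1": {"n": 54,  "admin": null},
    "step2": {"n": 20,  "admin": 6},
    "step3": {"n": 14,  "admin": 5}
  },
  "second_trimester": {
    "n_screened": 483,
    "step1": {"n": 110, "admin": 34},
    "step2": {"n": 21,  "admin": 12},
    "step3": {"n": 12,  "admin": 12}
  },
  "epds_ge9": {
    "first_visit":      {"n_assessed": 415, "n_ge9": 28},
    "second_trimester": {"n_assessed": 384, "n_ge9": 24},
    "third_trimester":  {"n_assessed": 232, "n_ge9": 17}
  }
}
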