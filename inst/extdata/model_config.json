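{
  "schema_version": "growthrisk-model-config/1",
  "equations": {
    "eq1": {
      "id": "eq1",
      "variant": "base",
      "window_months": [4.5, 7.5],
      "alpha": -3.718,
      "beta_female": 0.488,
      "beta_bw_z": 0.599,
      "beta_gain_z": 1.501,
      "beta_maternal_bmi": null,
      "thresholds": {
        "t10": 0.2072,
        "t20": 0.1155,
        "t30": 0.0731
      }
    },
    "eq2": {
      "id": "eq2",
      "variant": "base",
      "window_months": [7.5, 10.5],
      "alpha": -3.542,
      "beta_female": 0.288,
      "beta_bw_z": 0.551,
      "beta_gain_z": 1.508,
      "beta_maternal_bmi": null,
      "thresholds": {
        "t10": 0.2082,
        "t20": 0.1104,
        "t30": 0.0662
      }
    },
    "eq3": {
      "id": "eq3",
      "variant": "base",
      "window_months": [10.5, 13.5],
      "alpha": -3.937,
      "beta_female": 0.234,
      "beta_bw_z": 0.824,
      "beta_gain_z": 2.174,
      "beta_maternal_bmi": null,
      "thresholds": {
        "t10": 0.2391,
        "t20": 0.1065,
        "t30": 0.0609
      }
    },
    "eq1_mbmi": {
      "id": "eq1",
      "variant": "with_maternal_bmi",
      "window_months": [4.5, 7.5],
      "alpha": -4.92,
      "beta_female": 0.493,
      "beta_bw_z": 0.577,
      "beta_gain_z": 1.494,
      "beta_maternal_bmi": 0.044,
      "thresholds": {
        "t10": 0.2183,
        "t20": 0.1156,
        "t30": 0.0696
      }
    },
    "eq2_mbmi": {
      "id": "eq2",
      "variant": "with_maternal_bmi",
      "window_months": [7.5, 10.5],
      "alpha": -4.745,
      "beta_female": 0.255,
      "beta_bw_z": 0.505,
      "beta_gain_z": 1.501,
      "beta_maternal_bmi": 0.046,
      "thresholds": {
        "t10": 0.2042,
        "t20": 0.1076,
        "t30": 0.0646
      }
    },
    "eq3_mbmi": {
      "id": "eq3",
      "variant": "with_maternal_bmi",
      "window_months": [10.5, 13.5],
      "alpha": -4.625,
      "beta_female": 0.23,
      "beta_bw_z": 0.798,
      "beta_gain_z": 2.149,
      "beta_maternal_bmi": 0.026,
      "thresholds": {
        "t10": 0.2404,
        "t20": 0.1051,
        "t30": 0.0612
      }
    }
  },
  "conditional_model": {
    "a": 0,
    "b": 0.5,
    "residual_sd": 0.866025403784439,
    "n_fit": null,
    "degenerate": false,
    "baseline_age_days": null,
    "followup_age_days": null
  },
  "outcome_rule": {
    "bmi_centile_cutoff": 91,
    "band_width_sd": 0.67,
    "strict": true
  },
  "reference_path": null
}
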