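{
  "parameters": {
    "ka": 1.78,
    "tlag": 0.389,
    "v_tam_f": 1120,
    "cl20_f": 5.77,
    "cl23_f": 0.493,
    "cl30_f": 5.10,
    "v_endx_f": 400
  },
  "covariate_effects": {
    "age_exponent": -0.886,
    "age_reference": 65,
    "rif_cl20": 6.51,
    "rif_cl23": 1.18,
    "rif_vtam": 0.581,
    "ssri_cl23": -0.654,
    "as_cl23": {
      "0": -0.722,
      "0.5": -0.510,
      "1": -0.323,
      "1.5": -0.211,
      "2": 0,
      "2.5_3": 0.533
    }
  },
  "random_effects": {
    "omega2": {"cl20": 0.148, "cl23": 0.201},
    "pi2": {"cl20": 0.0222, "cl23": 0.0289},
    "phi2": {"cl20": 0.0256, "cl23": 0.0256},
    "sigma2": {"tam": 0.0260, "endx": 0.0267},
    "sigma_cov": 0.0169
  },
  "population": {
    "n": 10000,
    "phenotype_counts": {"gNM": 8650, "gIM": 770, "gPM": 580},
    "as_split_gNM": {"1": 0.30, "1.5": 0.10, "2": 0.55, "2.5_3": 0.05},
    "age_mean": 64,
    "age_sd": 13,
    "age_bounds": [25, 95],
    "p_rif": 0,
    "p_ssri": 0,
    "seed": 1
  },
  "strategies": {
    "standard": {"name": "standard", "standard_dose": 20},
    "cyp2d6_guided": {"name": "cyp2d6_guided",
                      "guided_doses": {"gNM": 20, "gIM": 40, "gPM": 60}},
    "mipd": {"name": "mipd", "runin_weeks": 4, "tdm_days": [14, 21, 28],
             "threshold": 5.97}
  },
  "seed": 1
}
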