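{
  "scenario": {
    "seed": 1,
    "n_reaches": 200,
    "n_stations": 40,
    "samples_per_station": 6,
    "noise_sigma": 0.3,
    "substances": [
      {"name": "popchem", "pattern": "pop", "true_ef": 10,
       "true_dt50": 10, "eqs_aa": 0.2, "eqs_mac": 1.8},
      {"name": "agrichem", "pattern": "agri_km2", "true_ef": 200,
       "true_dt50": 20, "eqs_aa": 0.6, "eqs_mac": 2.0}
    ]
  },
  "calibration": {"n_boot": 200, "include_uniform": false,
                  "normalizer": "mean_load"},
  "indicators": {"threshold": 0.25},
  "verification": {"rate_fractions": [0.1, 0.2, 0.5],
                   "flag_type": "exceed_aa"}
}
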