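{
  "comment": "Published reference results the simulation model is validated against (EUR, years, percent).",
  "cohorts": {
    "g1": {"mean_ltc": 28324.51, "sd_ltc": 6120.84, "median_ltc": 28076.08,
           "cfi": 14857.04, "cri": 1166.05, "cre": 1005.48, "apu": 9399.40, "tsc": 1896.54,
           "noi": 1.15, "nor": 0.45, "nop": 3.64,
           "ep_lts_pct": 0.12, "ep_ttr_pct": 0.43,
           "dr_lts_pct": {"1": 1.12, "10": 5.65, "25": 12.62},
           "dr_ttr_pct": {"1": 3.32, "5": 8.64, "10": 15.57}},
    "g2": {"mean_ltc": 32187.07, "sd_ltc": 6901.79, "median_ltc": 31849.58,
           "cfi": 4203.30, "cfs": 4880.87, "vsb": 12421.78, "cri": 903.21,
           "cre": 774.28, "apu": 7107.08, "tsc": 1896.54,
           "thi_mean": 4.01, "thi_sd": 5.18, "tsb_mean": 22.72, "tsb_sd": 14.60,
           "nhi": 2.46, "noi": 1.13, "nor": 0.38, "nop": 3.06,
           "ep_nhi_pct": 8.30, "ep_lts_pct": 0.10, "ep_ttr_pct": 0.36},
    "g3": {"mean_ltc": 28381.01, "sd_ltc": 10326.73, "median_ltc": 28846.55,
           "cfi": 4203.30, "cfs": 22281.25, "tsc": 1896.54,
           "nhi": 10.30, "nhi_sd": 4.26, "ep_nhi_pct": 25.84,
           "care_gap_mean": 3.32, "care_gap_sd": 7.83}
  },
  "top": {"mean": 26.73, "sd": 13.94},
  "cost_per_successful_year": {"g1": 1059.61, "g2": 1229.14, "g3": 1212.55},
  "strategy": {"mean": 29099.50, "sd": 8384.29, "cost_per_successful_year": 1088.61,
               "shares_pct": {"g3_age_first": 16.46, "g3_age_second": 5.93,
                              "g1_direct": 23.76, "surgery_then_implant": 53.85}},
  "crossings": {"mean_ltc_g1_vs_g3": [16, 17], "per_successful_year_g1_vs_g3": 14},
  "table5": {
    "strata": ["total", "10", "20", "30"],
    "n": [10000, 196, 323, 258],
    "g1": {"mean": [28325, 21123, 27037, 30842], "sd": [6121, 3249, 4258, 4652],
           "homogeneity": [0.82, 0.87, 0.86, 0.87]},
    "g2": {"mean": [32187, 25321, 31096, 34232], "sd": [6902, 4496, 5662, 5975],
           "homogeneity": [0.82, 0.85, 0.85, 0.85]},
    "g3": {"mean": [28381, 18471, 27409, 32552], "sd": [10327, 8018, 9690, 8037],
           "homogeneity": [0.73, 0.70, 0.74, 0.80]}
  },
  "table6": {
    "nhi_levels": [0, 1, 2, 3, 4, 5],
    "mean": [28325, 30606, 32347, 32796, 34067, 35394],
    "sd": [6121, 6499, 6493, 6953, 7567, 7361]
  }
}
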