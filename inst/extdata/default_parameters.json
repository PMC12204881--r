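{
  "LEX":  {"family": "fixed", "value": 81},
  "MIA":  {"family": "fixed", "value": 5},
  "DIR":  {"family": "fixed", "value": 0.05},
  "FOA":  {"family": "fixed", "value": 145},
  "APU":  {"family": "fixed", "value": 5719.9},
  "TTUa": {"family": "fixed", "value": 6},
  "AFI":  {"family": "weibull3", "shape": 244.32323, "scale": 2866.73542, "threshold": -2806.08613},
  "ISB":  {"family": "lognormal", "meanlog": 9.57283, "sdlog": 0.07429},
  "LTS":  {"family": "triangular", "lower": -3, "mode": 0, "upper": 400},
  "TTR":  {"family": "triangular", "lower": -3, "mode": 0, "upper": 140},
  "REV":  {"family": "lognormal", "meanlog": 8.29047, "sdlog": 0.20121},
  "TTUb": {"family": "exponential_shifted", "rate": 1.41988, "shift": 0},
  "THIt": {"family": "lognormal", "meanlog": 0.70939, "sdlog": 1.3453},
  "DSH":  {"family": "weibull3", "shape": 0.68361, "scale": 1.74601, "threshold": 0.28273},
  "HIS":  {"family": "lognormal", "meanlog": 8.2339, "sdlog": 0.25662},
  "caps": {
    "max_reimplantations": 2,
    "max_revisions": 3,
    "max_upgrades": 12,
    "max_nhi_g2": 6,
    "max_nhi_g3": 15,
    "thi_cap": 25
  }
}
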