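[
  {
    "chemical_class": "PHTHALATE",
    "outcome": "Male infertility",
    "base_prf_chemical": "BBP_DBP",
    "prf_override": {"base": 1.0, "low": 0.71, "high": 1.0}
  },
  {"chemical_class": "PBDE", "outcome": "*", "base_prf_chemical": "PBDE47"},
  {"chemical_class": "PHTHALATE", "outcome": "*", "base_prf_chemical": "DEHP"},
  {"chemical_class": "BPA", "outcome": "*", "base_prf_chemical": "BPA"},
  {
    "chemical_class": "PFAS",
    "outcome": "*",
    "base_prf_chemical": "PFOA",
    "envelope_prf_chemicals": ["PFOA", "PFOS"]
  },
  {"chemical_class": "*", "outcome": "*"}
]
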