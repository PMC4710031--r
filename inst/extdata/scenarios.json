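[
  {
    "parameter_id": "prevalence",
    "min_multiplier": 0.75,
    "max_multiplier": 1.25
  },
  {
    "parameter_id": "incidence",
    "min_multiplier": 0.75,
    "max_multiplier": 1.25
  },
  {
    "parameter_id": "unit_costs",
    "bounds": true
  },
  {
    "parameter_id": "resource_use.diagnosis",
    "bounds": true
  },
  {
    "parameter_id": "resource_use.monitoring",
    "bounds": true
  },
  {
    "parameter_id": "exacerbation",
    "min_multiplier": 0.75,
    "max_multiplier": 1.25
  },
  {
    "parameter_id": "end_of_life",
    "min_multiplier": 0.75,
    "max_multiplier": 1.25
  }
]
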