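{
  "schema_version": 1,
  "arms": [
    {
      "name": "control",
      "role": "control",
      "true_param": 0.4,
      "adherence": 1,
      "available_from": 0
    },
    {
      "name": "treat",
      "role": "treatment",
      "true_param": 0.4,
      "adherence": 1,
      "available_from": 0
    }
  ],
  "rules": {
    "outcome": "binary",
    "direction": "lower-better",
    "max_n": 2000,
    "n_looks": 10,
    "superiority_threshold": 0.99,
    "futility_threshold": 0.01,
    "mcid_margin": 0.2,
    "mcid_certainty": 0.95,
    "burn_in": 200,
    "rar_enabled": false,
    "platform_enabled": false,
    "perpetual": false,
    "comparison_mode": "all-arms",
    "cost_per_patient": 500,
    "accrual_rate": 10,
    "decision_draws": 10000,
    "rar_draws": 1000,
    "rar_floor": 0.01,
    "protect_control": false,
    "perpetual_cap": 10000,
    "new_arm_burn_in": 50,
    "prior": {
      "alpha": 1,
      "beta": 1
    },
    "planning_sd": 1
  },
  "simulation": {
    "n_sims": 200,
    "seed": 42
  }
}
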