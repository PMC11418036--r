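{
  "schema_version": 1,
  "comment": "Built-in Q-value specifications. poly_coeffs are (intercept, age, ln(age), age^2, age^3) for ln(Q in umol/L) on ages 2-25. plateau_mg_dl are the adult (>= 25 y) median creatinine values. 'reference' names the population whose age curve anchors the 12->25 gradual-change interpolation.",
  "populations": {
    "europe": {
      "label": "Europe (White, IDMS-traceable creatinine)",
      "poly_coeffs": {
        "male":   [3.200, 0.259, -0.543, -0.00763, 0.0000790],
        "female": [3.080, 0.177, -0.223, -0.00596, 0.0000686]
      },
      "plateau_mg_dl": { "female": 0.70, "male": 0.90 }
    },
    "us": {
      "label": "USA (race-free)",
      "plateau_mg_dl": { "female": 0.73, "male": 0.97 },
      "reference": "europe"
    }
  }
}
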