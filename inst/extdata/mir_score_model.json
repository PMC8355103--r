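{
  "name": "published-7-mirna-serum-panel",
  "description": "Frozen logistic linear predictor (log-odds) of a 7-miRNA serum panel for colorectal cancer risk, transcribed from the published equation. Inputs are normalized expression values (mean normalizer Cq minus target Cq).",
  "intercept": 0.1899,
  "coefficients": {
    "let-7g-5p": 0.2351,
    "miR-19a-3p": -0.2024,
    "miR-23a-3p": 1.6595,
    "miR-92a-3p": 0.4794,
    "miR-144-5p": 0.2002,
    "miR-21-5p": -1.6772,
    "miR-27a-3p": 0.1014
  },
  "normalizers": ["miR-93-5p", "miR-1246", "miR-223-3p"],
  "expression_convention": "expression = mean(Cq of normalizers) - Cq(target); log2 scale, higher = more abundant; 2^expression is the 2^-dCt relative quantity",
  "version": "1.0"
}
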