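factors:
  - {name: X1, label: ZnSO4,           low: 0.4, high: 1,   units: mg/L}
  - {name: X2, label: transferrin,     low: 4,   high: 10,  units: mg/L}
  - {name: X3, label: putrescine,      low: 0.4, high: 1,   units: mg/L}
  - {name: X4, label: BSA,             low: 80,  high: 200, units: mg/L}
  - {name: X5, label: ferric citrate,  low: 0.3, high: 1,   units: mmol/L}
  - {name: X6, label: sodium pyruvate, low: 0.3, high: 1,   units: mmol/L}
  - {name: X7, label: ethanolamine,    low: 2,   high: 6,   units: mg/L}
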