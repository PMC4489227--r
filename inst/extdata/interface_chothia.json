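{
  "heavy": [35, 37, 39, 44, 45, 47, 91, 93, 95, 100, 103],
  "kappa": [34, 36, 38, 43, 44, 46, 87, 89, 91, 96, 98],
  "lambda": [34, 36, 38, 43, 44, 46, 87, 89, 91, 96, 98],
  "alpha": [34, 36, 38, 43, 44, 46, 87, 89, 91, 96, 98],
  "beta": [35, 37, 39, 44, 45, 47, 91, 93, 95, 100, 103]
}
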