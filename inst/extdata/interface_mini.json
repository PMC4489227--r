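{
  "heavy": [18, 20, 22, 24, 34, 36, 38, 40],
  "kappa": [18, 20, 22, 24, 34, 36, 38, 40],
  "lambda": [18, 20, 22, 24, 34, 36, 38, 40],
  "alpha": [18, 20, 22, 24, 34, 36, 38, 40],
  "beta": [18, 20, 22, 24, 34, 36, 38, 40]
}
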