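# convergent defense: strong predator deterrence and mortality whose
# underlying avoidance/vulnerability traits are white noise (labile)
seed: 1
nSpecies: 124
gammaAvoid: 2
gammaPred: 2
traitModels:
  pref: {model: BM, sigma: 1}
  avoid: {model: WN, sigma: 1}
  tol: {model: BM, sigma: 1}
  vuln: {model: WN, sigma: 1}
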