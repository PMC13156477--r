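# conserved habitat filtering: strong, Brownian-conserved size preference
# in colonization and size-dependent survival in extinction
seed: 1
nSpecies: 124
betaSize: 1
gammaSize: 0.5
traitModels:
  pref: {model: BM, sigma: 1}
  avoid: {model: BM, sigma: 1}
  tol: {model: BM, sigma: 1}
  vuln: {model: BM, sigma: 1}
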