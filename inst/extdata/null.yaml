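# null scenario: all effect sizes zero; downstream statistics should be
# at their calibrated null distributions
seed: 1
nSpecies: 124
betaSize: 0
gammaAvoid: 0
gammaSize: 0
gammaPred: 0
alphaSurvival: 0
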