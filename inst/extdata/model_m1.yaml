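# Two-deme isolation-with-migration model with free reciprocal migration
# rates (migrants per generation, backward convention M[i][j] = N_i * m_ij).
demes:
  - id: "1"
    size: 10000
  - id: "2"
    size: 10000
migration:
  - {from: "1", to: "2", rate: M12}
  - {from: "2", to: "1", rate: M21}
mutation_rate: 5.0e-7
priors:
  - {name: M12, scale: log10, lower: -4, upper: 3}
  - {name: M21, scale: log10, lower: -4, upper: 3}
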