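# A minimal circuit config mirroring the builder arguments one-to-one:
# a constitutive transcription unit feeding one mRNA pool whose protein is
# degraded by a ClpXP pool running on fixed ClpP/ClpX supplies.
id: toy_from_config
compartments: [nucleus, cytoplasm]
transcription_units:
  - id: TU_R
    mrna: mRNA_R
    promoter:
      k_max: 0.02
mrna_pools:
  - id: pool_mRNA_R
    mrna: mRNA_R
    protein: R
    k_tl: 0.05
    k_dm: 0.0005
    k_dp: 0.0001
degradation_pools:
  - id: pool_degradation
    target: R
    k_dim_f: 0.001
    k_dim_r: 0.002
    k_bind: 0.002
    k_degr: 0.1
    k_dil: 0
connections:
  - species: mRNA_R
    compartment: cytoplasm
    producer: TU_R
    consumers: [pool_mRNA_R]
  - species: R
    compartment: cytoplasm
    producer: pool_mRNA_R
    consumers: [pool_degradation]
  - species: ClpP
    compartment: cytoplasm
    consumers: [pool_degradation]
    initial_amount: 50
    constant: true
  - species: ClpX
    compartment: cytoplasm
    consumers: [pool_degradation]
    initial_amount: 10
    constant: true
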