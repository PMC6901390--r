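label: sequential
temperature_K: 323
buffer_mM: 50
initial_mM:
  MAN: 20
  NADp: 20
loadings:
  - enzyme: AldT
    units_per_ml: 0.16
  - enzyme: ManD
    units_per_ml: 0.07
    addition_time_h: 1.5
  - enzyme: KDGA
    units_per_ml: 0.51
    addition_time_h: 16.5
  - enzyme: LDH
    units_per_ml: 5.8
    addition_time_h: 17.5
spikes:
  - time_h: 17.5
    species_mM:
      NADH: 10
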