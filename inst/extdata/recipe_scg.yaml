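# Mannose from spent-coffee-ground hydrolysate as cascade substrate.
label: scg
temperature_K: 323
buffer_mM: 100
initial_mM:
  MAN: 14.57
  NADp: 3.75
loadings:
  - enzyme: AldT
    units_per_ml: 0.2
  - enzyme: ManD
    units_per_ml: 0.1
  - enzyme: KDGA
    units_per_ml: 0.4
  - enzyme: LDH
    units_per_ml: 11.6
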