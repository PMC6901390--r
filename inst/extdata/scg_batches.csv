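batch,scg_mass_mg,measured_mg_per_100mg,std_recovery,mannose_mM
scg_dried,300,24,0.8362,14.57
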