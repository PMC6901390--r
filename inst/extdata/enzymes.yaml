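# Measured kinetic constants of the cascade enzymes at 50 C, pH 7.0 in
# sodium phosphate buffer, plus operational thermal half-lives at standard
# loading.  Km in mM, Vmax in U/mg, kcat in 1/s, half_life_h in hours
# (.inf = no measurable deactivation over 20 h).
AldT:
  substrate: mannose
  Km_mM: 9.73
  Vmax_U_per_mg: 5.20
  kcat_per_s: 2.51
  half_life_h: 9.8
ManD:
  substrate: mannonate
  Km_mM: 5.37
  Km_lactone_mM: 4.90
  Vmax_U_per_mg: 2.39
  Vmax_lactone_U_per_mg: 1.90
  kcat_per_s: 1.67
  kcat_lactone_per_s: 1.33
  half_life_h: 1.4
KDGA:
  substrate: pyruvate + glyceraldehyde
  Km_mM: 8.07
  Vmax_U_per_mg: 17.04
  kcat_per_s: 10.51
  half_life_h: .inf
LDH:
  substrate: pyruvate
  Km_mM: 10.95
  Vmax_U_per_mg: 194.3
  kcat_per_s: 116.58
  half_life_h: .inf
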