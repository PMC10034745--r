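parameter,value
log10_ka,1.62
log10_kb,10.18
log10_kw,-1.50
ea_acid_kcal_mol,14
ea_base_kcal_mol,17
ea_water_kcal_mol,19
pkd,15.05
t_ref_k,293.15
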