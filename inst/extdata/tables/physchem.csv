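property,genistein,daidzein,unit
log_pow,3.04,3.3,
boiling_point,555.5,512,degC
melting_point,301.5,323,degC
vapor_pressure,1.33e-9,3.46e-10,mmHg
molecular_weight,270.24,254.23,g/mol
water_solubility,0.12,0.053,mg/mL
pka_1,7.25,7.51,
pka_2,9.47,,
density,1.5,1.4,g/cm3
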