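assay,genistein_pct_inhibition_10uM,genistein_ic50_uM,daidzein_pct_inhibition_10uM,daidzein_ic50_uM
Estrogen ERalpha (h) (agonist RL),101.07,0.14,100.24,0.308
ERbeta Human Estrogen NHR Binding (Agonist),104.33,0.00308,100.00,0.02472
EGFR Human RTK Kinase Enzyme activity,71.05,5.984,17.78,
MAO-A (antagonist RL),85.95,2.12,49.64,9.18
5-HT2A (h) (agonist RL),57.31,7.60,38.85,
5-HT2B (h) (agonist RL),91.89,0.682,44.11,
Adenosine A1 (h) (antagonist RL),53.51,9.12,19.92,
Adenosine A2A (h) (agonist RL),52.21,10.0,20.50,
COX1 (h),70.76,7.69,44.74,
COX2 (h),53.81,13.6,21.63,
PDE4D2 (h) (phosphodiesterase 4D),87.03,0.738,0.04,
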