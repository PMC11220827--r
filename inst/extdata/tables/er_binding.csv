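parameter,receptor,genistein_nM,daidzein_nM,reference_control_nM
IC50,ERalpha,140,308,
IC50,ERbeta,3.1,24.7,1.18
Ki,ERalpha,40,87.9,
Ki,ERbeta,0.64,5.1,0.24
LOEC,ERalpha,44,35.2,
LOEC,ERbeta,0.52,3.2,
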