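assay,genistein_minus_s9_logM,genistein_plus_s9_logM,daidzein_minus_s9_logM,daidzein_plus_s9_logM,reference_logM,reference_name
Cytotoxicity,>-5,>-5,>-5,>-5,-6.6,Tributyltin acetate
ERalpha receptor,-8.2,-8.3,-6.9,-7.0,-12.2,17beta-estradiol
Anti-ERalpha antiestrogen,>-5,>-5,>-5,>-5,-8.3,Tamoxifen
AR androgens,>-5,>-5,>-5,>-5,-10.1,Dihydrotestosterone
Anti-AR anti androgens,>-5,>-5,>-5,>-5,-7.7,Flutamide
TRbeta thyroid,>-5,>-5,>-5,>-5,-9.9,T3 (triiodothyronine)
Anti-TRbeta antithyroid,>-5,>-5,>-5,>-5,-6.9,Deoxynivalenol
hTPO inhibition (thyroid),-4.7,>-4.7,-4.6,>-4.7,-6.3,Methimazole
TTR binding (thyroid),-6.7,-6.7,-6.0,-6.0,-7.9,Tetrabromobisphenol A
Steroidogenesis (ERalpha) 17beta-estradiol,>-6,>-6.7,>-5.5,>-5.7,-6.0,"Forskolin (up), prochloraz (down)"
Steroidogenesis (AR) Testosterone,-5.5,-5.7,-6.0,-5.7,-6.0,"Forskolin (up), prochloraz (down)"
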