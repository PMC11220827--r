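assay,measure,endpoint,daidzein_value,daidzein_unit,genistein_value,genistein_unit
Cell stress,LOEC,decrease in mitochondrial membrane potential,10.8,uM,11.6,uM
CALUX ERalpha,LOEC,Agonist,100,nM,6.5,nM
TPO,LOEC,Inhibition,28,uM,19,uM
TTR,LOEC,Inhibition of binding of T4 to TTR,1,uM,0.21,uM
AR,,Agonist/antagonist,,,,
TRbeta,,Agonist/antagonist,,,,
Estrogen synthesis,,Increase/decrease,,,,
Androgen synthesis,,Increase/decrease,,,,
Pharmacology profiling: ERalpha,LOEC,Binding to receptor,35.2,nM,44.0,nM
Pharmacology profiling: ERbeta,LOEC,Binding to receptor,3.2,nM,0.52,nM
Transcriptomics: MCF-7 cells,BMD_median,Gene pathway deregulation,38,nM,6.5,nM
Transcriptomics: HepG2 cells,BMD_median,Gene pathway deregulation,16.2,uM,15.7,uM
Transcriptomics: HepaRG cells,BMD_median,Gene pathway deregulation,33.1,uM,40.0,nM
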