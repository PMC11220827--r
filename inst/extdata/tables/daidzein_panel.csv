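chemical_id,assay_id,endpoint_class,measure,value_nM,sd_nM,s9,direction
daidzein,cell_stress_mmp,cell_stress,LOEC,10800,,n/a,down
daidzein,calux_eralpha,functional_transactivation,LOEC,100,0,plus,agonist
daidzein,calux_eralpha,functional_transactivation,LOEC,110,18,minus,agonist
daidzein,htpo_inhibition,enzyme_inhibition,LOEC,28000,13000,n/a,inhibition
daidzein,ttr_binding,enzyme_inhibition,LOEC,1000,0,n/a,inhibition
daidzein,steroidogenesis_androgen,steroidogenesis,LOEC,2100,1500,n/a,down
daidzein,pharmacology_eralpha,receptor_binding,LOEC,35.2,,n/a,agonist
daidzein,pharmacology_erbeta,receptor_binding,LOEC,3.2,,n/a,agonist
daidzein,transcriptomics_mcf7,transcriptomic_pathway,BMD_median,38,,n/a,down
daidzein,transcriptomics_hepg2,transcriptomic_pathway,BMD_median,16200,,n/a,up
daidzein,transcriptomics_heparg,transcriptomic_pathway,BMD_median,33100,,n/a,down
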