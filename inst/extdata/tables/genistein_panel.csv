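chemical_id,assay_id,endpoint_class,measure,value_nM,sd_nM,s9,direction
genistein,cell_stress_mmp,cell_stress,LOEC,11600,,n/a,down
genistein,calux_eralpha,functional_transactivation,LOEC,5.2,2.1,plus,agonist
genistein,calux_eralpha,functional_transactivation,LOEC,6.5,2.1,minus,agonist
genistein,htpo_inhibition,enzyme_inhibition,LOEC,19000,8900,n/a,inhibition
genistein,ttr_binding,enzyme_inhibition,LOEC,210,67,n/a,inhibition
genistein,steroidogenesis_androgen,steroidogenesis,LOEC,3200,0,n/a,down
genistein,pharmacology_eralpha,receptor_binding,LOEC,44,,n/a,agonist
genistein,pharmacology_erbeta,receptor_binding,LOEC,0.52,,n/a,agonist
genistein,transcriptomics_mcf7,transcriptomic_pathway,BMD_median,6.5,,n/a,up
genistein,transcriptomics_hepg2,transcriptomic_pathway,BMD_median,15700,,n/a,down
genistein,transcriptomics_heparg,transcriptomic_pathway,BMD_median,40,,n/a,up
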