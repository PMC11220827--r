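file,md5
assay_summary.csv,977cdec6b210dbfd0d4627477dc51838
ber_exposure.csv,7355d5c7db5c618c09f45654d0f8da9e
daidzein_panel.csv,8e5c56617cc6454791ceddf9a1ef851d
eats_loec.csv,bafe765a8fa71413ec61b98e6b7bf9e3
er_binding.csv,f4b8efb1633021e3015fbbd2765582a7
genistein_panel.csv,88dbce2d8ee3b0d176d5e1382e60af60
pathway_bmd.csv,73880b491f5b9e63566a11c9b9245280
pharmacology_screen.csv,67dfdd5b9f8862a0fea4370597bb18af
physchem.csv,c85d7641c9255cec17deca23ea863cc4
profiler_calls.csv,9e0e635d8fcca4a36bed4146510870f7
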