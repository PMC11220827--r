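pod_nM,concentration_pct,exposure_metric,exposure_value_nM
10,0.1,cmax_total_mean,5.95
10,0.1,cmax_total_ci5,3.37
10,0.1,cmax_total_ci95,9.89
10,0.1,cmax_fu_mean,0.3
10,0.1,cmax_fu_ci5,0.18
10,0.1,cmax_fu_ci95,0.50
10,0.02,cmax_total_mean,1.18
10,0.02,cmax_total_ci5,0.68
10,0.02,cmax_total_ci95,1.96
10,0.02,cmax_fu_mean,0.06
10,0.02,cmax_fu_ci5,0.04
10,0.02,cmax_fu_ci95,0.10
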