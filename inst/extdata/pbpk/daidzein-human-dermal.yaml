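parameters:
  chemical_id: daidzein
  species: human
  body_weight: 60.0
  compartments:
  - name: gut
    volume_L_kg: 0.017
    flow_L_h_kg: 0.98
    kp: 1.0
  - name: liver
    volume_L_kg: 0.026
    flow_L_h_kg: 0.28
    kp: 2.0
  - name: kidney
    volume_L_kg: 0.004
    flow_L_h_kg: 1.13
    kp: 1.5
  - name: skin
    volume_L_kg: 0.037
    flow_L_h_kg: 0.32
    kp: 0.8
  - name: rest
    volume_L_kg: 0.6
    flow_L_h_kg: 2.9
    kp: 1.5
  plasma_volume_L_kg: 0.0435
  fu_plasma: 0.0504202
  hepatic_clint_L_h_kg: 16.1573
  ka_oral_per_h: 1.0
  f_abs_dermal: 0.25
  k_perm_skin_per_h: 0.065
  k_met_skin_per_h: 0.529231
  molecular_weight: 254.23
schedule:
  route: dermal
  dose: 0.5
  area_cm2: 15670.0
  interval_h: 24.0
  n_doses: 7.0
variability:
  cv:
    hepatic_clint: 1.6
  n_individuals: 1000.0
  seed: 1.0
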