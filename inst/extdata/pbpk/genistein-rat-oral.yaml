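parameters:
  chemical_id: genistein
  species: rat
  body_weight: 0.25
  compartments:
  - name: gut
    volume_L_kg: 0.027
    flow_L_h_kg: 2.67
    kp: 1.0
  - name: liver
    volume_L_kg: 0.034
    flow_L_h_kg: 0.36
    kp: 2.0
  - name: kidney
    volume_L_kg: 0.007
    flow_L_h_kg: 2.49
    kp: 1.5
  - name: skin
    volume_L_kg: 0.19
    flow_L_h_kg: 1.03
    kp: 0.8
  - name: rest
    volume_L_kg: 0.5
    flow_L_h_kg: 8.9
    kp: 1.5
  plasma_volume_L_kg: 0.0312
  fu_plasma: 0.0199
  hepatic_clint_L_h_kg: 185.562
  ka_oral_per_h: 0.5
  f_abs_oral: 0.25
  molecular_weight: 270.24
schedule:
  route: oral
  dose: 0.3
  interval_h: 24.0
  n_doses: 7.0
variability:
  cv:
    hepatic_clint: 0.6244
  n_individuals: 1000.0
  seed: 1.0
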