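# demo: hydrogen-bond mimic, QCT + DC-SCIVR + signature assignment
surface:
  kind: hbond-mimic
  coupling: 3.0e-7
trajectory:
  dt: 10
  n_steps: 2500
spectrum:
  grid_min: 3000
  grid_max: 3600
  grid_step: 1
subspaces: "1 | 2"
reference:
  parity: -1
assignment: {}
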