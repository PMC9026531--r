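# isotropic vs anisotropic aorta, all three shunt placements
placements: [central, right, left]
aorta:
  isotropic: ogden_aorta
  anisotropic: hgo_aorta
shunt:
  elastic: elastic_graft
solver:
  n_cycles: 8
  dx: 0.005
  tol: 0.001
seed: 1
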