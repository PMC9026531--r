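# central-shunt pulsatile run on the default idealized pediatric network
placement: central
aorta: ogden_aorta
shunt: elastic_graft
waveform:
  period: 0.5
  systole: 0.22
  t_peak: 0.09
  v_peak: 1.4
  v_base: 0.0
solver:
  n_cycles: 8
  dx: 0.005
  cfl: 0.8
  tol: 0.001
seed: 1
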