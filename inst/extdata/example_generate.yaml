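# synthetic Gore-Tex graft tensile test: Yeoh specimen-1 constants
material:
  model: yeoh3
  c10: 0.11
  c20: -4.96e-06
  c30: 1.67e-10
stretch_max: 1.6
n_samples: 100
noise_sd: 0.05
seed: 20220407
diameter_mm: 4.5
thickness_mm: 0.35
length_mm: 20.0
rate_mm_per_min: 30.0
specimen_id: example_graft
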