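# Default in silico experiment campaign: 30 bilateral/CCO stenosis models,
# 78 release experiments, 5,500 emboli per source.
mild: [10, 25, 40]
severe: [50, 70, 85]
cco: true
n_per_source: 5500
base_seed: 1
policy:
  base_cycles: 10
  extension_cycles: 10
  unresolved_threshold: 0.1
  dt: 5.0e-5
waveform:
  period: 0.83
  mean_flow: 79.0
  systole_fraction: 0.36
  diastolic_level: 0.25
fluid:
  viscosity: 4.0   # cP
  density: 1.06    # g/cc
embolus:
  diameter: 500    # um
  density: 1.15    # g/cc
targets:
  desc_fraction: 0.65
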