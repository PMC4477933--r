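seed: 1
out_dir: mvrepair_run
geometry:
  ap_diameter: 43.0
  alpm_diameter: 37.0
  saddle_height: 5.0
chordae:
  n_marginal_anterior: 16.0
  n_marginal_posterior: 16.0
  n_strut: 2.0
prolapse:
  scallop: P2
  fraction: 0.7
surgery:
  chordal_margin: 5.0
  ring_catalog:
  - 24.0
  - 26.0
  - 28.0
  - 30.0
  - 32.0
  - 34.0
  - 36.0
  - 38.0
  - 40.0
  alpm_systole: 35.0
materials_file: ~
pressure_file: ~
solver:
  duration: 250.0
  mass_scaling: 100.0
  damping: 0.25
skip_repair: no
simulate: yes
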