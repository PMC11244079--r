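# Scaled-down configuration for examples and quick end-to-end checks.
# Same structure as default_config.yaml, ~60x smaller.

seed: 7

image:
  size: 192
  length_px: 70

outline:
  n_points: 360
  min_size: 32
  smooth_window: 5

efd:
  n_harmonics: 6
  power_reference_harmonics: 30

generator:
  delta: 3.4
  base_sd: 0.045
  floor_sd: 0.015
  between_cultivar_ratio: 1.0
  between_accession_ratio: 0.5
  wild_length_ratio: 0.85
  templates:
    wild:
      a: [1.0, 0.07, 0.02]
      b: [0.0, 0.0, 0.0]
      c: [0.0, 0.0, 0.0]
      d: [0.72, -0.04, 0.015]
    domestic:
      a: [1.0, 0.10, 0.035]
      b: [0.0, 0.0, 0.0]
      c: [0.0, 0.0, 0.0]
      d: [0.42, -0.06, 0.02]

reference:
  n_cultivars: 12
  pips_per_cultivar: 6
  wild_accessions: 4
  pips_per_accession: 18
  n_per_class: 60
  min_per_cultivar: 3

sites:
  - name: "Site A"
    n_pips: 40
    domestic_fraction: 0.9
  - name: "Site B"
    n_pips: 30
    domestic_fraction: 0.7

lda:
  f_enter: 3.84
  f_remove: 2.71
  tolerance_min: 0.001
  priors: equal

report:
  min_count: 2
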