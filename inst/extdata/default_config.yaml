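# Default pipeline configuration.
#
# The sample sizes mirror the study design the package models: a balanced
# reference of 1319 wild + 1319 domestic pips drawn from 330 cultivars and
# 22 wild accessions, and three unknown assemblages (wells N and KK of
# Sa Osa, and Nora) of 1686, 301 and 241 pips with mostly-domestic
# composition. The generator templates are illustrative morphotype shapes
# (a roundish short-beak "wild" form, an elongated long-beak "domestic"
# form built from harmonics 1-3); the class separation `delta` is the
# Mahalanobis distance between the class means in feature space, set so
# that the reference discrimination matches the mid-90s% accuracy regime
# typical of wild/domestic pip classification.

seed: 101

image:
  size: 512          # canvas, px
  length_px: 142     # seed major axis, px (~6 mm at 600 dpi)

outline:
  n_points: 360
  min_size: 32
  smooth_window: 5

efd:
  n_harmonics: 6
  power_reference_harmonics: 30

generator:
  delta: 3.4               # wild/domestic Mahalanobis separation
  base_sd: 0.045           # per-coefficient sd = max(base_sd / harmonic, floor_sd)
  floor_sd: 0.015
  between_cultivar_ratio: 1.0    # cultivar sub-mean spread, x within-class sd
  between_accession_ratio: 0.5   # wild accession sub-mean spread
  wild_length_ratio: 0.85        # wild seeds are smaller
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
  n_cultivars: 330
  pips_per_cultivar: 4
  wild_accessions: 22
  pips_per_accession: 60
  n_per_class: 1319       # balanced reference size per status class
  min_per_cultivar: 3

sites:
  - name: "Well N"
    n_pips: 1686
    domestic_fraction: 0.92
  - name: "Well KK"
    n_pips: 301
    domestic_fraction: 0.74
  - name: "Nora"
    n_pips: 241
    domestic_fraction: 0.97

lda:
  f_enter: 3.84
  f_remove: 2.71
  tolerance_min: 0.001
  priors: equal

report:
  min_count: 10
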