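# Small synthetic study for quick demonstrations and smoke tests:
# two groups x three fields x 150 cells.
synthetic:
  fields_per_group: 3
  base:
    n_cells: 150
    field_px: [760, 760]
    microns_per_pixel: 0.4
    signal_to_background: 20
    noise_sd: 50
    frac_diffuse_cc3: 0.10
  groups:
    - label: vehicle
      frac_gh2ax: 0.25
      frac_bleb: 0.05
      frac_coloc: 0.02
    - label: treated
      frac_gh2ax: 0.30
      frac_bleb: 0.25
      frac_coloc: 0.20
microns_per_pixel: 0.4
ring_width_um: auto
thresholds:
  cyto_cc3: {method: absolute, value: 5000}
  spot: {method: absolute, value: 20000}
  gh2ax: {method: auto}
comparisons:
  - {group_a: vehicle, group_b: treated, metric: pct_coloc}
seed: 7
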