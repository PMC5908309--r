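# Packaged synthetic study: two treatment groups (vehicle vs treated),
# six fields per group, ~1350 cells per field, mirroring the assay's
# per-specimen analysis scale (>= 6 fields and >= 15,000 cells analysed
# per specimen). The treated group carries a strong apoptotic response
# (20% colocalized cells) against a 1% vehicle baseline.
synthetic:
  fields_per_group: 6
  base:
    n_cells: 1350
    field_px: [2100, 2100]
    microns_per_pixel: 0.4
    nucleus_area_range_um2: [50, 200]
    signal_to_background: 20
    noise_sd: 50
    background_level: 500
    frac_diffuse_cc3: 0.10
  groups:
    - label: vehicle
      frac_gh2ax: 0.25
      frac_bleb: 0.05
      frac_coloc: 0.01
    - label: treated
      frac_gh2ax: 0.30
      frac_bleb: 0.25
      frac_coloc: 0.20
microns_per_pixel: 0.4
ring_width_um: auto
segmentation:
  min_area_um2: 50
  max_area_um2: 200
  smooth_sigma: 1
  watershed_tolerance: 2
spot:
  expected_spot_area_um2: 0.9
  min_spot_area_um2: 0.2
  max_spot_area_um2: 5.0
  min_puncta_per_cell: 2
thresholds:
  # absolute thresholds sit mid-gap between the rendered intensity levels:
  # background 500, diffuse cytoplasmic CC3 ~10,500, puncta ~30,500
  cyto_cc3: {method: absolute, value: 5000}
  spot: {method: absolute, value: 20000}
  gh2ax: {method: auto}
comparisons:
  - {group_a: vehicle, group_b: treated, metric: pct_coloc}
  - {group_a: vehicle, group_b: treated, metric: pct_bleb}
  - {group_a: vehicle, group_b: treated, metric: pct_gh2ax}
seed: 20180330
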