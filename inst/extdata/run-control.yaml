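# Full-pipeline configuration: characterize the standard well and analyse
# a synthetic field mimicking its flow regimes.
well:
  label: control
  well_radius_mm: 11.05
  mean_depth_mm: 2
  orbital_radius_mm: 5
  rpm: 150
field:
  scenario: control_like
  n_radii: 20
  n_azimuths: 8
  n_samples: 180
  period_s: 0.4
  r_max_mm: 10.5
profile:
  n_bins: 20
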