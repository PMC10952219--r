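label: control
well_radius_mm: 11.05
mean_depth_mm: 2
orbital_radius_mm: 5
rpm: 150
gravity_m_s2: 9.81
tilt_angle_deg: 0
fluid:
  density_liquid_kg_m3: 1003
  density_air_kg_m3: 1.1115
  dynamic_viscosity_pa_s: 0.78e-3
  surface_tension_n_m: 0.072
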