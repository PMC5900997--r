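frc_L: 2.64
n_terminals: 500.0
host:
  right_fraction: 0.54
  right_semiaxes_mm:
  - 52.5
  - 65.0
  - 100.0
  left_semiaxes_mm:
  - 47.5
  - 62.0
  - 98.0
  gap_mm: 20.0
tree:
  branching_fraction: 0.4
  angle_cap_deg: 60.0
  min_length_mm: 1.0
  airway_root_diameter_mm: 18.0
  airway_diameter_ratio: 1.3
  artery_root_diameter_mm: 24.0
  artery_diameter_ratio: 1.35
  vein_artery_ratio: 1.2
mechanics:
  v0_gradient_per_cm: 0.06
  pe_ref_cmH2O: 5.0
  pe_gradient_cmH2O_per_cm: 0.25
  compliance_total_mL_per_cmH2O: 100.0
  compliance_cv: 0.05
ventilation:
  tidal_volume_mL: 650.0
  breath_s: 5.0
  ie_ratio: 1.0
  dt_s: 0.01
  mu_air_Pa_s: 1.8e-05
  rho_air_kg_m3: 1.12
  zpe_gamma: 0.327
  warmup_breaths: 3.0
  max_warmup_breaths: 20.0
  drift_tol: 0.005
perfusion:
  mu_blood_Pa_s: 0.00336
  rho_blood_kg_m3: 1060.0
  g_m_s2: 9.81
  inlet_Pa: 2000.0
  outlet_Pa: 666.0
  alpha_per_Pa: 0.000149
  cap_resistance_lung_Pa_s_mm3: 0.026
  cap_volume_total_mL: 100.0
  tol: 1.0e-06
  max_iter: 60.0
gas:
  D_mm2_s: 22.5
  sigma_O2_mmol_L_mmHg: 0.0014
  hb_mmol_L: 2.3
  p50_mmHg: 26.8
  hill_n: 2.7
  T_ta_lung_mmol_mmHg_s: 0.01
  T_b_lung_mmol_mmHg_s: 0.025
  tissue_volume_total_mL: 500.0
  pv_mmHg: 40.0
  dry_pressure_mmHg: 713.0
  gas_mmol_per_mL: 0.0393
transport:
  dt_s: 0.05
  node_spacing_mm: 3.0
  coarsen_by_radius: yes
  cfl: 0.9
  peclet_cutoff: 5.0
  diffusion: yes
  transit_substeps: 8.0
protocol:
  breaths_per_block: 20.0
  n_cycles: 5.0
  extra_o2_breaths: 20.0
  fio2_air: 0.21
  fio2_o2: 1.0
  warmup_breaths: 6.0
  include_arterial: no
imaging:
  voxel_inplane_mm: 1.6
  voxel_slab_mm: 15.0
  fill_threshold: 0.5
  vein_point_volume_mm3: 0.1
  sphere_sample_spacing_mm: 1.6
inference:
  sv_min: 0.01
  sv_increment: 0.15
  sv_n: 50.0
  sv_max: 10.0
  alpha: 0.05
analysis:
  section_mm: 10.0
  slice_mm: 15.0
misalignment:
  eelv_mean: 0.09
  eelv_sd: 0.12
  eelv_max: 0.4
  volume_tol: 0.1
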