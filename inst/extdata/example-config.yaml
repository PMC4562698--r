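world:
  n_tags: 17
  sim_days: 3
  active_windows:
  - - 21600
    - 32400
  - - 61200
    - 72000
  time_step_s: 1
  arena:
  - 60.0
  - 40.0
  n_nests: 9
  nest_spacing_m: 20.0
  n_receivers: 8
  home_radius_m: 7.0
  ou_sd_m: 1.5
  ou_tau_s: 20.0
  visit_rate_per_h: 2.0
  visit_duration_s: 120.0
  flight_rate_per_h: 6.0
  heading_sd_rad: 0.3
  colony_bout_s: 600.0
  away_bout_s: 900.0
  epoch: 2014-08-01 00:00:00
  seed: 1
propagation:
  rssi_at_ref: 6.8798234
  slope_per_log10m: -27.9471992
  orientation_penalty_max: 19.5
  orientation_ramp_m: 0.13
  mount_gain: 5.0
  noise_sd: 2.5
  noise_dist_scale_m: 6.0
  noise_dist_cap_m: 10.0
  shadow_sd: 8.0
  flight_attenuation: 12.0
  shadow_tau_s: 600.0
  rssi_min: -17
  rssi_max: 57
  d_min_clamp: 0.01
  d_sat: 3.5
  max_range_m: 100.0
  tag_range_m: 12.0
tag:
  pulse_interval_s: 20
  detection_threshold_rssi: 0.0
  max_encounter_s: 300
  max_concurrent: 30
  memory_capacity: 300
  clock_saver_period_s: 30.0
  battery_life_s: '.inf'
  clock_drift_s_per_day: 3.0
pipeline:
  merge_gap_s: 20.0
  break_gap_s: 21.0
  stagger_s: 21.0
  network_thresholds:
  - 0.0
  - 40.0
seed: 1
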