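# One modest cohort shared by scheduler/simulator/analytics tests (built
# once when the suite loads; ~1 s). Full-preset runs live in the
# acceptance tests only.
shared_fences <- generate_geofences(n_parks = 5, n_landuse = 36, seed = 7)
shared_cfg <- sim_config(n_participants = 8, study_days = 10, seed = 42)
shared_cohort <- suppressWarnings(
  simulate_cohort(shared_cfg, parkseek_profile(), shared_fences))
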