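schema_version: 1
grid:
  n_rows: 10.0
  n_cols: 10.0
  cell_size: 30.0
steps_per_year: 24
years: 20.0
spinup_years: 10.0
scenario:
  preset: covarying
species:
- name: forage
  vertical: pelagic
  spawn_steps:
  - 5
  - 6
  - 7
  - 8
  ltl_access:
    adult:
      zoo_large: 0.35
      macrozoo: 0.105
  t_min: -1.0
  t_opt: 10.0
  t_max: 19.0
  i_max: 18.0
  beta: 0.75
  eta_early: 1.7
  xi: 0.7
  k_o2: 28.0
  h_o2: 2.0
  e_mob: 0.75
  lambda: 0.18
  beta_m: 0.75
  lw_c: 0.0045
  lw_b: 3.05
  r_min: 20.0
  r_max: 40000.0
  mat_intercept: 12.5
  mat_slope: 0.25
  rel_fec: 1.0
  egg_mass: 0.0012
  egg_survival: 0.25
  egg_capacity: 1.0e+15
  gonad_alloc: 0.35
  p_sat: 5.2
  m_bg: 0.6
  m_early: 1.5
  max_age: 7.0
  w_ref: 30.0
- name: flatfish
  vertical: benthic
  spawn_steps:
  - 3
  - 4
  - 5
  - 6
  habitat:
  - 1
  - 11
  - 21
  - 31
  - 41
  - 51
  - 61
  - 2
  - 12
  - 22
  - 32
  - 42
  - 52
  - 62
  - 3
  - 13
  - 23
  - 33
  - 43
  - 53
  - 63
  - 4
  - 14
  - 24
  - 34
  - 44
  - 54
  - 64
  - 5
  - 15
  - 25
  - 35
  - 45
  - 55
  - 65
  - 6
  - 16
  - 26
  - 36
  - 46
  - 56
  - 66
  - 7
  - 17
  - 27
  - 37
  - 47
  - 57
  - 67
  - 8
  - 18
  - 28
  - 38
  - 48
  - 58
  - 68
  - 9
  - 19
  - 29
  - 39
  - 49
  - 59
  - 69
  - 10
  - 20
  - 30
  - 40
  - 50
  - 60
  - 70
  t_min: 1.0
  t_opt: 12.0
  t_max: 23.0
  i_max: 14.0
  beta: 0.75
  eta_early: 1.5
  xi: 0.7
  k_o2: 28.0
  h_o2: 2.0
  e_mob: 0.75
  lambda: 0.18
  beta_m: 0.75
  lw_c: 0.0105
  lw_b: 3.0
  r_min: 40.0
  r_max: 25000.0
  mat_intercept: 19.0
  mat_slope: 0.4
  rel_fec: 1.0
  egg_mass: 0.0025
  egg_survival: 0.2
  egg_capacity: 1.0e+15
  gonad_alloc: 0.3
  p_sat: 7.2
  m_bg: 0.45
  m_early: 1.2
  max_age: 8.0
  w_ref: 250.0
- name: piscivore
  vertical: demersal
  spawn_steps:
  - 2
  - 3
  - 4
  - 5
  habitat:
  - 1
  - 11
  - 21
  - 31
  - 41
  - 51
  - 61
  - 2
  - 12
  - 22
  - 32
  - 42
  - 52
  - 62
  - 3
  - 13
  - 23
  - 33
  - 43
  - 53
  - 63
  - 4
  - 14
  - 24
  - 34
  - 44
  - 54
  - 64
  - 5
  - 15
  - 25
  - 35
  - 45
  - 55
  - 65
  - 6
  - 16
  - 26
  - 36
  - 46
  - 56
  - 66
  - 7
  - 17
  - 27
  - 37
  - 47
  - 57
  - 67
  - 8
  - 18
  - 28
  - 38
  - 48
  - 58
  - 68
  - 9
  - 19
  - 29
  - 39
  - 49
  - 59
  - 69
  - 10
  - 20
  - 30
  - 40
  - 50
  - 60
  - 70
  ltl_access:
    early:
      zoo_small: 0.17
      zoo_large: 0.17
    juvenile:
      zoo_large: 0.17
      macrozoo: 0.035
    adult:
      macrozoo: 0.026
  t_min: 0.0
  t_opt: 11.0
  t_max: 21.0
  i_max: 11.0
  beta: 0.75
  eta_early: 1.5
  xi: 0.7
  k_o2: 28.0
  h_o2: 2.0
  e_mob: 0.75
  lambda: 0.18
  beta_m: 0.75
  lw_c: 0.0085
  lw_b: 3.0
  r_min: 6.0
  r_max: 16000.0
  mat_intercept: 30.0
  mat_slope: 0.6
  rel_fec: 1.0
  egg_mass: 0.002
  egg_survival: 0.04
  egg_capacity: 1.0e+15
  gonad_alloc: 0.28
  p_sat: 1.0
  m_bg: 0.5
  m_early: 1.5
  max_age: 15.0
  w_ref: 600.0
sim:
  rho_e: 1.0
  m_starv: 6.0
  n_spawn_schools: 24
  min_n: 0.01
  init_n0:
  - 2.0e+07
  - 3.0e+05
  - 3.0e+04
  init_z0: 0.8
  init_max_age: 6.0
analysis:
  eps_frac: 0.01
  bin_width: 0.5
seed: 1
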