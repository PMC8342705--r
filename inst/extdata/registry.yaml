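field:
  frequency_ghz: 6.41
  e0_v_per_m: 4.9
  t_us: 1.0
species:
  insulin:
    charge_q_c: 7.4805e-09
    mass_m_kg: 9.52e-18
    dipole_debye: 369.0
  papain:
    charge_q_c: 4.01e-08
    mass_m_kg: 3.88e-17
    dipole_debye: 150.0
  zno_s:
    charge_q_c: .na.real
    mass_m_kg: .na.real
    inert: yes
  zno_t:
    charge_q_c: .na.real
    mass_m_kg: .na.real
    inert: yes
samples:
  I:
    components:
    - species: insulin
      volume_ul: 250.0
      conc_mg_per_ml: 6.9
    reference: yes
  P1:
    components:
    - species: papain
      volume_ul: 250.0
      conc_mg_per_ml: 10.0
  P2:
    components:
    - species: papain
      volume_ul: 250.0
      conc_mg_per_ml: 5.0
  P3:
    components:
    - species: papain
      volume_ul: 250.0
      conc_mg_per_ml: 2.5
  IZnO_S:
    components:
    - species: insulin
      volume_ul: 166.666666666666657
      conc_mg_per_ml: 6.9
    - species: zno_s
      volume_ul: 83.333333333333329
      conc_mg_per_ml: 3.45
  IZnO_T:
    components:
    - species: insulin
      volume_ul: 166.666666666666657
      conc_mg_per_ml: 6.9
    - species: zno_t
      volume_ul: 83.333333333333329
      conc_mg_per_ml: 3.45
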