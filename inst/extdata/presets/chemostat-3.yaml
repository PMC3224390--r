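# Scenario preset: replicate chemostat cultivation 3 (batch mu_max not determined in print; assumed as run 1).
# Calibration constants are versioned here, not hard-coded: the producer
# kinetics reproduce the printed batch mu_max, a population q_p peak near
# 0.52 mmol/Cmol/h at ~75 h after feed start, a >10-fold q_p decline within
# ~330 h driven by outgrowth of the non-producing variant, and a
# steady-state biomass near 3 g DW/L.
name: chemostat-3
version: 1
description: >
  Ethanol-limited chemostat, D = 0.03 1/h, 0.25 Cmol/L ethanol + 4 mM PAA
  feed, 15% initial non-producing variant.
config:
  D: 0.03
  feed_ethanol: 0.25
  feed_paa: 4.0
  batch_init_ethanol: 0.25
  batch_init_biomass: 0.005
  f0: 0.15
  t_switch: auto
  horizon: 680
  gdw_per_cmol: 24.6
  toc_fraction: 0.02
producer:
  mu_max: 0.088
  Ks: 0.001
  Yxs_max: 0.6
  ms: 0.0115
  qp_cell_max: 0.78
  Yps_burden: 0.0320512821
  k_induction: 0.03
  k_decay: 0.0
  repression_threshold: 0.01
  paa_side_fraction: 0.10
nonproducer:
  mu_max: 0.088
  Ks: 0.001
  Yxs_max: 0.6
  ms: 0.0115
  qp_cell_max: 0.0
  Yps_burden: 0.0320512821
  k_induction: 0.03
  k_decay: 0.0
  repression_threshold: 0.01
  paa_side_fraction: 0.10
noise:
  sampling_interval: 12
  relative_sd:
    biomass: 0.03
    peng: 0.03
    paa: 0.03
    ethanol: 0.03
    ohpaa: 0.03
    toc: 0.03
    o2_uptake: 0.03
    co2_evolution: 0.03
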