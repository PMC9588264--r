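# Institutional OAR constraint set for two-lateral-beam prostate proton
# plans (70 Gy / 28 fractions). metric: V_rel (% of ROI >= dose_gy),
# V_abs (cm3 >= dose_gy), Dmean (Gy), Dcc (min dose over the hottest
# volume_cc, Gy). limit is compared as value < limit.
constraints:
  - {roi: bladder, metric: V_abs, dose_gy: 70, limit: 10, limit_units: cm3}
  - {roi: bladder, metric: V_rel, dose_gy: 65, limit: 15, limit_units: "%"}
  - {roi: bladder, metric: V_rel, dose_gy: 61, limit: 25, limit_units: "%"}
  - {roi: bladder, metric: V_rel, dose_gy: 55, limit: 30, limit_units: "%"}
  - {roi: bladder, metric: V_rel, dose_gy: 44, limit: 50, limit_units: "%"}
  - {roi: bladder, metric: V_rel, dose_gy: 39, limit: 60, limit_units: "%"}
  - {roi: rectum, metric: V_abs, dose_gy: 70, limit: 10, limit_units: cm3}
  - {roi: rectum, metric: V_rel, dose_gy: 65, limit: 10, limit_units: "%"}
  - {roi: rectum, metric: V_rel, dose_gy: 61, limit: 15, limit_units: "%"}
  - {roi: rectum, metric: V_rel, dose_gy: 53, limit: 30, limit_units: "%"}
  - {roi: rectum, metric: V_rel, dose_gy: 35, limit: 50, limit_units: "%"}
  - {roi: femur_right, metric: V_rel, dose_gy: 39, limit: 5, limit_units: "%"}
  - {roi: femur_left, metric: V_rel, dose_gy: 39, limit: 5, limit_units: "%"}
  - {roi: penile_bulb, metric: Dmean, limit: 39, limit_units: Gy}
  - {roi: body, metric: Dcc, volume_cc: 0.03, limit: 74.9, limit_units: Gy}
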