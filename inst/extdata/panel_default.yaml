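# Default synthetic expert panel: 18 experts scoring 12 candidate criteria
# across four dimensions (device features, user needs, environment, policy).
# Nine criteria carry high true importance and three moderate, so a
# threshold-7 Fuzzy Delphi screen typically retains nine conditions.
n_experts: 18
interval_width: 2
score_sd: 1
outlier_rate: 0
criteria:
  - {criterion_id: safety, importance: 8.2}
  - {criterion_id: usefulness, importance: 8.6}
  - {criterion_id: smart_technology, importance: 8.0}
  - {criterion_id: ease_of_use, importance: 6.2}
  - {criterion_id: health_management, importance: 7.9}
  - {criterion_id: economic_affordability, importance: 7.8}
  - {criterion_id: psychological_resilience, importance: 6.4}
  - {criterion_id: digital_inclusion, importance: 7.9}
  - {criterion_id: spatial_adaptability, importance: 6.4}
  - {criterion_id: cultural_adaptability, importance: 7.5}
  - {criterion_id: cost_control, importance: 7.7}
  - {criterion_id: inclusive_policies, importance: 7.9}
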