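# Synthetic 163-respondent satisfaction survey with ten planted
# conjunction rules at designed coverages over the two outer decision
# classes (synthetic stand-in for the study's unavailable raw survey).
conditions:
  - safety
  - usefulness
  - smart_technology
  - health_management
  - economic_affordability
  - digital_inclusion
  - cultural_adaptability
  - cost_control
  - inclusive_policies
class_sizes:
  "1": 14
  "2": 41
  "3": 108
domain: [1, 2, 3, 4, 5]
noise: 0
exclusive: true
blockers: true
planted_rules:
  - conditions: {safety: 2, usefulness: 2}
    decision: 1
    count: 5          # 5/14  = 35.71%
  - conditions: {economic_affordability: 3, cost_control: 2}
    decision: 1
    count: 5          # 5/14  = 35.71%
  - conditions: {smart_technology: 1, economic_affordability: 1}
    decision: 1
    count: 2          # 2/14  = 14.29%
  - conditions: {safety: 1, smart_technology: 1}
    decision: 1
    count: 2          # 2/14  = 14.29%
  - conditions: {usefulness: 1, health_management: 1}
    decision: 1
    count: 2          # 2/14  = 14.29%
  - conditions: {safety: 5, cost_control: 5}
    decision: 3
    count: 49         # 49/108 = 45.37%
  - conditions: {safety: 5, digital_inclusion: 3, inclusive_policies: 5}
    decision: 3
    count: 12         # 12/108 = 11.11%
  - conditions: {usefulness: 4, cultural_adaptability: 5}
    decision: 3
    count: 19         # 19/108 = 17.59%
  - conditions: {usefulness: 4, health_management: 4}
    decision: 3
    count: 22         # 22/108 = 20.37%
  - conditions: {digital_inclusion: 5, inclusive_policies: 3}
    decision: 3
    count: 15         # 15/108 = 13.89%
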