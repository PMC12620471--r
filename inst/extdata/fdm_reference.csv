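criterion_id,C_U,O_L,C_M,O_M
safety,8,6,6.0666,8.4
usefulness,9,7,6.9333,9.1333
smart_technology,8,7,6.7333,8.9333
ease_of_use,7,5,4.4666,7.4667
health_management,8,7,6,8.4
economic_affordability,8,7,5.5333,8.5333
psychological_resilience,7,6,5.6667,8.0667
digital_inclusion,8,7,6,8.3333
spatial_adaptability,7,6,5.7333,8.2
cultural_adaptability,7,7,5.6667,7.9333
cost_control,8,6,5.8667,8.3333
inclusive_policies,8,7,5.9333,8.5333
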