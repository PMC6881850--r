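name: scenario_2
eligible_states:
- C
- D
start_year: 2011.0
target_year: 2020.0
rate_start:
  seasonal:
    children: 0.05
    adolescents: 0.15
    adults: 0.2
  perennial:
    children: 0.05
    adolescents: 0.1
    adults: 0.2
rate_target:
  seasonal:
    children: 0.75
    adolescents: 0.75
    adults: 0.75
  perennial:
    children: 0.75
    adolescents: 0.75
    adults: 0.75
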