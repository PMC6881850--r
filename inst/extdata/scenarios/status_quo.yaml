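name: status_quo
eligible_states:
- C
- D
start_year: 2011.0
target_year: 2030.0
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
    children: 0.1
    adolescents: 0.2
    adults: 0.3
  perennial:
    children: 0.05
    adolescents: 0.15
    adults: 0.3
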