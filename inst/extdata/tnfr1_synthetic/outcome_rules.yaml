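response_outputs:
  t_survival: survival
  t_apoptosis: apoptosis
  t_necroptosis: necroptosis
resolution_rules:
- label: apoptosis
  requires_outputs:
  - apoptosis
  requires_transitions:
  - t_bcl2_bax
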