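model: tnfr1_synthetic
note: Synthetic reconstruction of a TNFR1 signal-transduction Petri net assembled
  from published structural descriptions; not the original supplementary model.
expected_counts:
  places: 118
  transitions: 130
  edges: 299
initial_marking_places:
- IkB_g
- A20_g
- XIAP_g
- cFLIPL_g
- BCL2_g
synthesis_transitions:
- syn_APAF1
- syn_BAX
- syn_BID
- syn_cFLIPS
- syn_cIAP
- syn_CYLD
- syn_CytC
- syn_FADD
- syn_IKK
- syn_LUBAC
- syn_MLKL
- syn_NEMO
- syn_NFkB
- syn_ProCASP3
- syn_ProCASP8
- syn_ProCASP9
- syn_RIP1
- syn_RIP3
- syn_SMAC
- syn_TAB1
- syn_TAK1
- syn_TNF
- syn_TNFR1
- syn_TRADD
- syn_TRAF2
- syn_Ub
- trans_A20
- trans_BCL2
- trans_cFLIPL
- trans_IkB
- trans_XIAP
response_outputs:
  t_survival: survival
  t_apoptosis: apoptosis
  t_necroptosis: necroptosis
expected_pi_supports:
- - IkB_g
  - NFkB.IkB_g
- - A20_g
  - NFkB.A20_g
- - XIAP_g
  - NFkB.XIAP_g
- - cFLIPL_g
  - NFkB.cFLIPL_g
- - BCL2_g
  - NFkB.BCL2_g
fig_column_set:
- CI
- CIIa
- CIIb
- Apoptosome
- RIP1.RIP3
- CASP3
- CASP8
- CASP9
- MLKL_PM
- BCL2.BAX
- XIAP.CASP3
- XIAP.CASP9
- CIIb.cFLIPs
- CI.CYLD
- NFkB_n
- TRADD.RIP1
- CIIb.cFLIPL
- CI.A20
- SMAC.XIAP
- tBID
- MOMP
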