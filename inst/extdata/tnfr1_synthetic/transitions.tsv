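id	name
syn_TNF	Syn_TNF
syn_TNFR1	Syn_TNFR1
syn_TRADD	Syn_TRADD
syn_RIP1	Syn_RIP1
syn_TRAF2	Syn_TRAF2
syn_cIAP	Syn_cIAP1/2
syn_LUBAC	Syn_LUBAC
syn_TAK1	Syn_TAK1
syn_TAB1	Syn_TAB1
syn_IKK	Syn_IKK
syn_NEMO	Syn_NEMO
syn_Ub	Syn_Ub
syn_CYLD	Syn_CYLD
syn_FADD	Syn_FADD
syn_ProCASP8	Syn_Procaspase8
syn_ProCASP3	Syn_Procaspase3
syn_ProCASP9	Syn_Procaspase9
syn_cFLIPS	Syn_cFLIPs
syn_RIP3	Syn_RIP3
syn_MLKL	Syn_MLKL
syn_NFkB	Syn_NF-kB
syn_BID	Syn_BID
syn_BAX	Syn_BAX
syn_APAF1	Syn_APAF1
syn_SMAC	Syn_SMAC
syn_CytC	Syn_CytC
bind_IkB	T26 NF-kB binds IkB gene
rel_IkB	T27 transcribe IkB
spl_IkB	Splice IkB pre-mRNA
exp_IkB	Export IkB mRNA
trans_IkB	Translation IkB
bind_A20	Bind A20 gene
rel_A20	Transcribe A20
spl_A20	Splice A20 pre-mRNA
exp_A20	Export A20 mRNA
trans_A20	Translation A20
bind_XIAP	Bind XIAP gene
rel_XIAP	Transcribe XIAP
spl_XIAP	Splice XIAP pre-mRNA
exp_XIAP	Export XIAP mRNA
trans_XIAP	Translation XIAP
bind_cFLIPL	Bind cFLIPL gene
rel_cFLIPL	Transcribe cFLIPL
spl_cFLIPL	Splice cFLIPL pre-mRNA
exp_cFLIPL	Export cFLIPL mRNA
trans_cFLIPL	Translation cFLIPL
bind_BCL2	Bind BCL-2 gene
rel_BCL2	Transcribe BCL-2
spl_BCL2	Splice BCL-2 pre-mRNA
exp_BCL2	Export BCL-2 mRNA
trans_BCL2	Translation BCL-2
deg_NFkB	Deg_NF-kB
t_transloc	T25 NF-kB translocation
t_ikb_imp	IkB nuclear import
t_export	NF-kB nuclear export by IkB
t_nfkb_cyto	NF-kB:IkB to cytosol
t_ikb_phos	IKK phosphorylates IkB
t_ikb_ub	IkB ubiquitination
t_surv_sig	NF-kB response genes on
t_survival	Survival
deg_prot	Proteasomal degradation
t_tnf_sec	TNF secretion
t_tnfr1_tri	TNFR1 trimerisation
t_ci_core	T1 receptor complex
t_rip1_rec	T2 RIP1 recruitment
t_traf2_ciap	TRAF2:cIAP1/2
t_tc_act	TRAF2:cIAP activation
t_ciap_rec	cIAP recruitment
t_k63	K63 ubiquitination
t_ci_full	M1 chains, kinase recruitment
t_a20_bind	A20 binds complex I
t_a20_edit	A20 ubiquitin editing
t_a20_dissoc	A20 dissociates complex I
t_cyld_bind	CYLD recruitment
t_cyld_deub	CYLD K63 deubiquitination
t_cyld_dissoc	Complex I dissociation
t_ci_dissoc	Complex I destabilisation
t_tradd_dissoc	TRADD dissociation
t_c8_fold	Procaspase-8 maturation
t_fadd_c8	FADD:procaspase-8
t_ciia	CIIa assembly
t_ciib	CIIb assembly
t_ciia_act	CIIa caspase processing
t_casp8_a	CASP8 activation at CIIa
t_ciib_act	CIIb caspase processing
t_casp8_b	CASP8 activation at CIIb
t_flipl_ciia	cFLIPL blocks CIIa
t_p43	p43-FLIP processing
deg_p43	Deg p43-FLIP
t_flipl_ciib	cFLIPL in CIIb
t_rip_cleave	RIP1/RIP3 cleavage
t_rip1cl_ub	Cleaved RIP1 turnover
t_flips_ciib	cFLIPs in CIIb
t_necro_flip	Necrosome via cFLIPs
t_necro_ciib	Necrosome from CIIb
t_necro_tr	Necrosome from TRADD:RIP1
t_casp3_ext	Extrinsic CASP3 activation
deg_CASP8	Deg CASP8
t_dna_frag	CASP3 substrate cleavage
t_apoptosis	Apoptosis
t_xiap_c3	XIAP inhibits CASP3
deg_xiap_c3	Deg XIAP:CASP3
t_cyld_cleave	CASP8 cleaves CYLD
t_bid	BID cleavage
t_tbid_bax	tBID engages BAX
t_bax_act	BAX activation
t_bax_oligo	BAX oligomerisation
t_bcl2_bax	BCL-2 sequesters BAX
deg_bcl2_bax	Deg BCL-2:BAX
t_bcl2_tbid	BCL-2 sequesters tBID
deg_bcl2_tbid	Deg BCL-2:tBID
t_momp	MOMP pore formation
t_release	CytC and SMAC release
t_apaf	CytC:APAF1
t_aposome	Apoptosome assembly
t_casp9	CASP9 activation
t_casp3_int	Intrinsic CASP3 activation
t_xiap_c9	XIAP inhibits CASP9
deg_xiap_c9	Deg XIAP:CASP9
t_smac_dim	SMAC dimerisation
t_smac_xiap	SMAC neutralises XIAP
deg_smac_xiap	Deg SMAC:XIAP
t_a20_rip3	A20 inhibits necrosome
deg_rip3_a20	Deg RIP3:A20
t_rip3_p	RIP3 autophosphorylation
t_mlkl_rec	MLKL recruitment
t_mlkl_oligo	MLKL oligomerisation
t_mlkl_pm	MLKL to plasma membrane
t_pore	Membrane pore formation
t_necroptosis	Necroptosis
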