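source	target	weight	read
syn_TNF	TNF	1	FALSE
syn_TNFR1	TNFR1	1	FALSE
syn_TRADD	TRADD	1	FALSE
syn_RIP1	RIP1	1	FALSE
syn_TRAF2	TRAF2	1	FALSE
syn_cIAP	cIAP	1	FALSE
syn_LUBAC	LUBAC	1	FALSE
syn_TAK1	TAK1	1	FALSE
syn_TAB1	TAB1	1	FALSE
syn_IKK	IKK	1	FALSE
syn_NEMO	NEMO	1	FALSE
syn_Ub	Ub	1	FALSE
syn_CYLD	CYLD	1	FALSE
syn_FADD	FADD	1	FALSE
syn_ProCASP8	ProCASP8	1	FALSE
syn_ProCASP3	ProCASP3	1	FALSE
syn_ProCASP9	ProCASP9	1	FALSE
syn_cFLIPS	cFLIPS	1	FALSE
syn_RIP3	RIP3	1	FALSE
syn_MLKL	MLKL	1	FALSE
syn_NFkB	NFkB	1	FALSE
syn_BID	BID	1	FALSE
syn_BAX	BAX	1	FALSE
syn_APAF1	APAF1	1	FALSE
syn_SMAC	SMAC_m	1	FALSE
syn_CytC	CytC_m	1	FALSE
NFkB_n	bind_IkB	1	FALSE
IkB_g	bind_IkB	1	FALSE
bind_IkB	NFkB.IkB_g	1	FALSE
NFkB.IkB_g	rel_IkB	1	FALSE
rel_IkB	IkB_g	1	FALSE
rel_IkB	NFkB_n	1	FALSE
rel_IkB	IkB_pre	1	FALSE
IkB_pre	spl_IkB	1	FALSE
spl_IkB	IkB_mRNA_n	1	FALSE
IkB_mRNA_n	exp_IkB	1	FALSE
exp_IkB	IkB_mRNA	1	FALSE
IkB_mRNA	trans_IkB	1	FALSE
trans_IkB	IkB	1	FALSE
NFkB_n	bind_A20	1	FALSE
A20_g	bind_A20	1	FALSE
bind_A20	NFkB.A20_g	1	FALSE
NFkB.A20_g	rel_A20	1	FALSE
rel_A20	A20_g	1	FALSE
rel_A20	NFkB_n	1	FALSE
rel_A20	A20_pre	1	FALSE
A20_pre	spl_A20	1	FALSE
spl_A20	A20_mRNA_n	1	FALSE
A20_mRNA_n	exp_A20	1	FALSE
exp_A20	A20_mRNA	1	FALSE
A20_mRNA	trans_A20	1	FALSE
trans_A20	A20	1	FALSE
NFkB_n	bind_XIAP	1	FALSE
XIAP_g	bind_XIAP	1	FALSE
bind_XIAP	NFkB.XIAP_g	1	FALSE
NFkB.XIAP_g	rel_XIAP	1	FALSE
rel_XIAP	XIAP_g	1	FALSE
rel_XIAP	NFkB_n	1	FALSE
rel_XIAP	XIAP_pre	1	FALSE
XIAP_pre	spl_XIAP	1	FALSE
spl_XIAP	XIAP_mRNA_n	1	FALSE
XIAP_mRNA_n	exp_XIAP	1	FALSE
exp_XIAP	XIAP_mRNA	1	FALSE
XIAP_mRNA	trans_XIAP	1	FALSE
trans_XIAP	XIAP	1	FALSE
NFkB_n	bind_cFLIPL	1	FALSE
cFLIPL_g	bind_cFLIPL	1	FALSE
bind_cFLIPL	NFkB.cFLIPL_g	1	FALSE
NFkB.cFLIPL_g	rel_cFLIPL	1	FALSE
rel_cFLIPL	cFLIPL_g	1	FALSE
rel_cFLIPL	NFkB_n	1	FALSE
rel_cFLIPL	cFLIPL_pre	1	FALSE
cFLIPL_pre	spl_cFLIPL	1	FALSE
spl_cFLIPL	cFLIPL_mRNA_n	1	FALSE
cFLIPL_mRNA_n	exp_cFLIPL	1	FALSE
exp_cFLIPL	cFLIPL_mRNA	1	FALSE
cFLIPL_mRNA	trans_cFLIPL	1	FALSE
trans_cFLIPL	cFLIPL	1	FALSE
NFkB_n	bind_BCL2	1	FALSE
BCL2_g	bind_BCL2	1	FALSE
bind_BCL2	NFkB.BCL2_g	1	FALSE
NFkB.BCL2_g	rel_BCL2	1	FALSE
rel_BCL2	BCL2_g	1	FALSE
rel_BCL2	NFkB_n	1	FALSE
rel_BCL2	BCL2_pre	1	FALSE
BCL2_pre	spl_BCL2	1	FALSE
spl_BCL2	BCL2_mRNA_n	1	FALSE
BCL2_mRNA_n	exp_BCL2	1	FALSE
exp_BCL2	BCL2_mRNA	1	FALSE
BCL2_mRNA	trans_BCL2	1	FALSE
trans_BCL2	BCL2	1	FALSE
NFkB	deg_NFkB	1	FALSE
NFkB	t_transloc	1	FALSE
t_transloc	NFkB_n	1	FALSE
IkB	t_ikb_imp	1	FALSE
t_ikb_imp	IkB_n	1	FALSE
NFkB_n	t_export	1	FALSE
IkB_n	t_export	1	FALSE
t_export	NFkB.IkB_n	1	FALSE
NFkB.IkB_n	t_nfkb_cyto	1	FALSE
t_nfkb_cyto	NFkB.IkB	1	FALSE
NFkB.IkB	t_ikb_phos	1	FALSE
CI	t_ikb_phos	1	TRUE
t_ikb_phos	CI	1	TRUE
t_ikb_phos	NFkB	1	FALSE
t_ikb_phos	IkB_p	1	FALSE
IkB_p	t_ikb_ub	1	FALSE
Ub	t_ikb_ub	1	FALSE
t_ikb_ub	Ub_sub	1	FALSE
NFkB_n	t_surv_sig	1	FALSE
t_surv_sig	SurvivalSignal	1	FALSE
SurvivalSignal	t_survival	1	FALSE
Ub_sub	deg_prot	1	FALSE
TNF	t_tnf_sec	1	FALSE
t_tnf_sec	TNF_e	1	FALSE
TNFR1	t_tnfr1_tri	1	FALSE
t_tnfr1_tri	TNFR1_tri	1	FALSE
TNF_e	t_ci_core	1	FALSE
TNFR1_tri	t_ci_core	1	FALSE
TRADD	t_ci_core	1	FALSE
t_ci_core	TNF.TNFR1.TRADD	1	FALSE
TNF.TNFR1.TRADD	t_rip1_rec	1	FALSE
RIP1	t_rip1_rec	1	FALSE
t_rip1_rec	CIpre	1	FALSE
TRAF2	t_traf2_ciap	1	FALSE
cIAP	t_traf2_ciap	1	FALSE
t_traf2_ciap	TRAF2.cIAP	1	FALSE
TRAF2.cIAP	t_tc_act	1	FALSE
t_tc_act	TRAF2.cIAP_a	1	FALSE
CIpre	t_ciap_rec	1	FALSE
TRAF2.cIAP_a	t_ciap_rec	1	FALSE
t_ciap_rec	CIpre2	1	FALSE
CIpre2	t_k63	1	FALSE
Ub	t_k63	2	FALSE
t_k63	CI_K63	1	FALSE
CI_K63	t_ci_full	1	FALSE
LUBAC	t_ci_full	1	FALSE
Ub	t_ci_full	1	FALSE
TAK1	t_ci_full	1	FALSE
TAB1	t_ci_full	1	FALSE
IKK	t_ci_full	1	FALSE
NEMO	t_ci_full	1	FALSE
t_ci_full	CI	1	FALSE
CI	t_a20_bind	1	FALSE
A20	t_a20_bind	1	FALSE
t_a20_bind	CI.A20	1	FALSE
CI.A20	t_a20_edit	1	FALSE
t_a20_edit	CI.A20_ed	1	FALSE
CI.A20_ed	t_a20_dissoc	1	FALSE
t_a20_dissoc	Ub_sub	1	FALSE
CI_K63	t_cyld_bind	1	FALSE
CYLD	t_cyld_bind	1	FALSE
t_cyld_bind	CI.CYLD	1	FALSE
CI.CYLD	t_cyld_deub	1	FALSE
t_cyld_deub	CI_deub	1	FALSE
CI_deub	t_cyld_dissoc	1	FALSE
t_cyld_dissoc	TRADD.RIP1	1	FALSE
t_cyld_dissoc	Ub_sub	1	FALSE
CI_K63	t_ci_dissoc	1	FALSE
t_ci_dissoc	TRADD.RIP1	1	FALSE
t_ci_dissoc	Ub_sub	1	FALSE
TNF.TNFR1.TRADD	t_tradd_dissoc	1	FALSE
t_tradd_dissoc	TRADD_c	1	FALSE
ProCASP8	t_c8_fold	1	FALSE
t_c8_fold	ProCASP8_m	1	FALSE
FADD	t_fadd_c8	1	FALSE
ProCASP8_m	t_fadd_c8	1	FALSE
t_fadd_c8	FADD.ProC8	1	FALSE
TRADD_c	t_ciia	1	FALSE
FADD.ProC8	t_ciia	1	FALSE
t_ciia	CIIa	1	FALSE
TRADD.RIP1	t_ciib	1	FALSE
FADD.ProC8	t_ciib	1	FALSE
t_ciib	CIIb	1	FALSE
CIIa	t_ciia_act	1	FALSE
t_ciia_act	CIIa_act	1	FALSE
t_ciia_act	CASP8_p10a	1	FALSE
CIIa_act	t_casp8_a	1	FALSE
CASP8_p10a	t_casp8_a	1	FALSE
t_casp8_a	CASP8	1	FALSE
t_casp8_a	Ub_sub	1	FALSE
CIIb	t_ciib_act	1	FALSE
t_ciib_act	CIIb_act	1	FALSE
t_ciib_act	CASP8_p10b	1	FALSE
CIIb_act	t_casp8_b	1	FALSE
CASP8_p10b	t_casp8_b	1	FALSE
t_casp8_b	CASP8	1	FALSE
t_casp8_b	Ub_sub	1	FALSE
CIIa	t_flipl_ciia	1	FALSE
cFLIPL	t_flipl_ciia	1	FALSE
t_flipl_ciia	CIIa.cFLIPL	1	FALSE
CIIa.cFLIPL	t_p43	1	FALSE
t_p43	p43_FLIP	1	FALSE
p43_FLIP	deg_p43	1	FALSE
CIIb	t_flipl_ciib	1	FALSE
cFLIPL	t_flipl_ciib	1	FALSE
t_flipl_ciib	CIIb.cFLIPL	1	FALSE
CIIb.cFLIPL	t_rip_cleave	1	FALSE
t_rip_cleave	RIP1_cl	1	FALSE
RIP1_cl	t_rip1cl_ub	1	FALSE
t_rip1cl_ub	Ub_sub	1	FALSE
CIIb	t_flips_ciib	1	FALSE
cFLIPS	t_flips_ciib	1	FALSE
t_flips_ciib	CIIb.cFLIPs	1	FALSE
CIIb.cFLIPs	t_necro_flip	1	FALSE
RIP3	t_necro_flip	1	FALSE
t_necro_flip	RIP1.RIP3	1	FALSE
t_necro_flip	Ub_sub	1	FALSE
CIIb	t_necro_ciib	1	FALSE
RIP3	t_necro_ciib	1	FALSE
t_necro_ciib	RIP1.RIP3	1	FALSE
t_necro_ciib	Ub_sub	1	FALSE
TRADD.RIP1	t_necro_tr	1	FALSE
RIP3	t_necro_tr	1	FALSE
t_necro_tr	RIP1.RIP3	1	FALSE
ProCASP3	t_casp3_ext	1	FALSE
CASP8	t_casp3_ext	1	TRUE
t_casp3_ext	CASP8	1	TRUE
t_casp3_ext	CASP3	1	FALSE
CASP8	deg_CASP8	1	FALSE
CASP3	t_dna_frag	1	FALSE
t_dna_frag	DNA_frag	1	FALSE
DNA_frag	t_apoptosis	1	FALSE
XIAP	t_xiap_c3	1	FALSE
CASP3	t_xiap_c3	1	FALSE
t_xiap_c3	XIAP.CASP3	1	FALSE
XIAP.CASP3	deg_xiap_c3	1	FALSE
CYLD	t_cyld_cleave	1	FALSE
CASP8	t_cyld_cleave	1	TRUE
t_cyld_cleave	CASP8	1	TRUE
t_cyld_cleave	Ub_sub	1	FALSE
BID	t_bid	1	FALSE
CASP8	t_bid	1	TRUE
t_bid	CASP8	1	TRUE
t_bid	tBID	1	FALSE
tBID	t_tbid_bax	1	FALSE
BAX	t_tbid_bax	1	FALSE
t_tbid_bax	tBID.BAX	1	FALSE
tBID.BAX	t_bax_act	1	FALSE
t_bax_act	BAX_a	1	FALSE
t_bax_act	Ub_sub	1	FALSE
BAX_a	t_bax_oligo	1	FALSE
t_bax_oligo	BAX_oligo	1	FALSE
BCL2	t_bcl2_bax	1	FALSE
BAX_a	t_bcl2_bax	1	FALSE
t_bcl2_bax	BCL2.BAX	1	FALSE
BCL2.BAX	deg_bcl2_bax	1	FALSE
BCL2	t_bcl2_tbid	1	FALSE
tBID	t_bcl2_tbid	1	FALSE
t_bcl2_tbid	BCL2.tBID	1	FALSE
BCL2.tBID	deg_bcl2_tbid	1	FALSE
BAX_oligo	t_momp	1	FALSE
t_momp	MOMP	1	FALSE
MOMP	t_release	1	FALSE
CytC_m	t_release	1	FALSE
SMAC_m	t_release	1	FALSE
t_release	CytC_c	1	FALSE
t_release	SMAC_c	1	FALSE
CytC_c	t_apaf	1	FALSE
APAF1	t_apaf	1	FALSE
t_apaf	CytC.APAF1	1	FALSE
CytC.APAF1	t_aposome	1	FALSE
ProCASP9	t_aposome	1	FALSE
t_aposome	Apoptosome	1	FALSE
t_aposome	CASP9_p12	1	FALSE
Apoptosome	t_casp9	1	FALSE
CASP9_p12	t_casp9	1	FALSE
t_casp9	CASP9	1	FALSE
ProCASP3	t_casp3_int	1	FALSE
CASP9	t_casp3_int	1	TRUE
t_casp3_int	CASP9	1	TRUE
t_casp3_int	CASP3	1	FALSE
XIAP	t_xiap_c9	1	FALSE
CASP9	t_xiap_c9	1	FALSE
t_xiap_c9	XIAP.CASP9	1	FALSE
XIAP.CASP9	deg_xiap_c9	1	FALSE
SMAC_c	t_smac_dim	1	FALSE
t_smac_dim	SMAC_dim	1	FALSE
SMAC_dim	t_smac_xiap	1	FALSE
XIAP	t_smac_xiap	1	FALSE
t_smac_xiap	SMAC.XIAP	1	FALSE
SMAC.XIAP	deg_smac_xiap	1	FALSE
RIP1.RIP3	t_a20_rip3	1	FALSE
A20	t_a20_rip3	1	FALSE
t_a20_rip3	RIP3.A20	1	FALSE
RIP3.A20	deg_rip3_a20	1	FALSE
RIP1.RIP3	t_rip3_p	1	FALSE
t_rip3_p	RIP1.RIP3_p	1	FALSE
RIP1.RIP3_p	t_mlkl_rec	1	FALSE
MLKL	t_mlkl_rec	1	FALSE
t_mlkl_rec	MLKL_p	1	FALSE
t_mlkl_rec	Ub_sub	1	FALSE
MLKL_p	t_mlkl_oligo	1	FALSE
t_mlkl_oligo	MLKL_oligo	1	FALSE
MLKL_oligo	t_mlkl_pm	1	FALSE
t_mlkl_pm	MLKL_PM	1	FALSE
MLKL_PM	t_pore	1	FALSE
t_pore	Membrane_pore	1	FALSE
Membrane_pore	t_necroptosis	1	FALSE
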