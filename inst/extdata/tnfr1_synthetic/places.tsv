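id	name	annotation	marking
A20	A20	protein	0
A20_g	A20_g	gene	1
A20_mRNA	A20_mRNA	transcript	0
A20_mRNA_n	A20_mRNA_n	transcript	0
A20_pre	A20_pre	transcript	0
APAF1	APAF1	protein	0
Apoptosome	Apoptosome	protein	0
BAX	BAX	protein	0
BAX_a	BAX_a	protein	0
BAX_oligo	BAX_oligo	protein	0
BCL2	BCL-2	protein	0
BCL2_g	BCL-2_g	gene	1
BCL2_mRNA	BCL-2_mRNA	transcript	0
BCL2_mRNA_n	BCL-2_mRNA_n	transcript	0
BCL2_pre	BCL-2_pre	transcript	0
BCL2.BAX	BCL-2:BAX	complex	0
BCL2.tBID	BCL-2:tBID	complex	0
BID	BID	protein	0
CASP3	CASP3	protein	0
CASP8	CASP8	protein	0
CASP8_p10a	CASP8_p10a	protein	0
CASP8_p10b	CASP8_p10b	protein	0
CASP9	CASP9	protein	0
CASP9_p12	CASP9_p12	protein	0
cFLIPL	cFLIPL	protein	0
cFLIPL_g	cFLIPL_g	gene	1
cFLIPL_mRNA	cFLIPL_mRNA	transcript	0
cFLIPL_mRNA_n	cFLIPL_mRNA_n	transcript	0
cFLIPL_pre	cFLIPL_pre	transcript	0
cFLIPS	cFLIPS	protein	0
CI	CI	protein	0
CI_deub	CI_deub	protein	0
CI_K63	CI_K63	protein	0
CI.A20	CI:A20	complex	0
CI.A20_ed	CI:A20_ed	complex	0
CI.CYLD	CI:CYLD	complex	0
cIAP	cIAP1/2	protein	0
CIIa	CIIa	protein	0
CIIa_act	CIIa_act	protein	0
CIIa.cFLIPL	CIIa:cFLIPL	complex	0
CIIb	CIIb	protein	0
CIIb_act	CIIb_act	protein	0
CIIb.cFLIPL	CIIb:cFLIPL	complex	0
CIIb.cFLIPs	CIIb:cFLIPs	complex	0
CIpre	CIpre	protein	0
CIpre2	CIpre2	protein	0
CYLD	CYLD	protein	0
CytC_c	CytC_c	protein	0
CytC_m	CytC_m	protein	0
CytC.APAF1	CytC:APAF1	complex	0
DNA_frag	DNA_frag	response	0
FADD	FADD	protein	0
FADD.ProC8	FADD:ProC8	complex	0
IkB	IkB	protein	0
IkB_g	IkB_g	gene	1
IkB_mRNA	IkB_mRNA	transcript	0
IkB_mRNA_n	IkB_mRNA_n	transcript	0
IkB_n	IkB_n	protein	0
IkB_p	IkB_p	protein	0
IkB_pre	IkB_pre	transcript	0
IKK	IKK	protein	0
LUBAC	LUBAC	protein	0
Membrane_pore	Membrane_pore	response	0
MLKL	MLKL	protein	0
MLKL_oligo	MLKL_oligo	protein	0
MLKL_p	MLKL_p	protein	0
MLKL_PM	MLKL_PM	protein	0
MOMP	MOMP	response	0
NEMO	NEMO	protein	0
NFkB	NF-kB	protein	0
NFkB_n	NF-kB_n	protein	0
NFkB.A20_g	NF-kB:A20_g	gene	0
NFkB.BCL2_g	NF-kB:BCL-2_g	gene	0
NFkB.cFLIPL_g	NF-kB:cFLIPL_g	gene	0
NFkB.IkB	NF-kB:IkB	complex	0
NFkB.IkB_g	NF-kB:IkB_g	gene	0
NFkB.IkB_n	NF-kB:IkB_n	complex	0
NFkB.XIAP_g	NF-kB:XIAP_g	gene	0
p43_FLIP	p43_FLIP	protein	0
ProCASP3	ProCASP3	protein	0
ProCASP8	ProCASP8	protein	0
ProCASP8_m	ProCASP8_m	protein	0
ProCASP9	ProCASP9	protein	0
RIP1	RIP1	protein	0
RIP1_cl	RIP1_cl	protein	0
RIP1.RIP3	RIP1:RIP3	complex	0
RIP1.RIP3_p	RIP1:RIP3_p	complex	0
RIP3	RIP3	protein	0
RIP3.A20	RIP3:A20	complex	0
SMAC_c	SMAC_c	protein	0
SMAC_dim	SMAC_dim	protein	0
SMAC_m	SMAC_m	protein	0
SMAC.XIAP	SMAC:XIAP	complex	0
SurvivalSignal	SurvivalSignal	response	0
TAB1	TAB1	protein	0
TAK1	TAK1	protein	0
tBID	tBID	protein	0
tBID.BAX	tBID:BAX	complex	0
TNF	TNF	protein	0
TNF_e	TNF_e	protein	0
TNF.TNFR1.TRADD	TNF:TNFR1:TRADD	complex	0
TNFR1	TNFR1	protein	0
TNFR1_tri	TNFR1_tri	protein	0
TRADD	TRADD	protein	0
TRADD_c	TRADD_c	protein	0
TRADD.RIP1	TRADD:RIP1	complex	0
TRAF2	TRAF2	protein	0
TRAF2.cIAP	TRAF2:cIAP	complex	0
TRAF2.cIAP_a	TRAF2:cIAP_a	complex	0
Ub	Ub	protein	0
Ub_sub	Ub_sub	response	0
XIAP	XIAP	protein	0
XIAP_g	XIAP_g	gene	1
XIAP_mRNA	XIAP_mRNA	transcript	0
XIAP_mRNA_n	XIAP_mRNA_n	transcript	0
XIAP_pre	XIAP_pre	transcript	0
XIAP.CASP3	XIAP:CASP3	complex	0
XIAP.CASP9	XIAP:CASP9	complex	0
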