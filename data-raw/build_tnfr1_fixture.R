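# Builds the synthetic TNFR1-architecture fixture (TSV files under
# inst/extdata/tnfr1_synthetic/). Reaction syntax:
#   "id | name | in1 + 2*in2 + ~readplace -> out1 + out2"
# "~p" marks a read arc (tested, not consumed). Empty left side = synthesis
# input; empty right side = output (degradation / dissociation / response).

rx <- c(
  ## ---- housekeeping protein syntheses (26 input transitions) ----
  "syn_TNF | Syn_TNF | -> TNF",
  "syn_TNFR1 | Syn_TNFR1 | -> TNFR1",
  "syn_TRADD | Syn_TRADD | -> TRADD",
  "syn_RIP1 | Syn_RIP1 | -> RIP1",
  "syn_TRAF2 | Syn_TRAF2 | -> TRAF2",
  "syn_cIAP | Syn_cIAP1/2 | -> cIAP",
  "syn_LUBAC | Syn_LUBAC | -> LUBAC",
  "syn_TAK1 | Syn_TAK1 | -> TAK1",
  "syn_TAB1 | Syn_TAB1 | -> TAB1",
  "syn_IKK | Syn_IKK | -> IKK",
  "syn_NEMO | Syn_NEMO | -> NEMO",
  "syn_Ub | Syn_Ub | -> Ub",
  "syn_CYLD | Syn_CYLD | -> CYLD",
  "syn_FADD | Syn_FADD | -> FADD",
  "syn_ProCASP8 | Syn_Procaspase8 | -> ProCASP8",
  "syn_ProCASP3 | Syn_Procaspase3 | -> ProCASP3",
  "syn_ProCASP9 | Syn_Procaspase9 | -> ProCASP9",
  "syn_cFLIPS | Syn_cFLIPs | -> cFLIPS",
  "syn_RIP3 | Syn_RIP3 | -> RIP3",
  "syn_MLKL | Syn_MLKL | -> MLKL",
  "syn_NFkB | Syn_NF-kB | -> NFkB",
  "syn_BID | Syn_BID | -> BID",
  "syn_BAX | Syn_BAX | -> BAX",
  "syn_APAF1 | Syn_APAF1 | -> APAF1",
  "syn_SMAC | Syn_SMAC | -> SMAC_m",
  "syn_CytC | Syn_CytC | -> CytC_m",

  ## ---- NF-kB-dependent gene expression (five conserved gene motifs) ----
  ## transcription -> splicing -> nuclear export -> translation
  "bind_IkB | T26 NF-kB binds IkB gene | NFkB_n + IkB_g -> NFkB.IkB_g",
  "rel_IkB | T27 transcribe IkB | NFkB.IkB_g -> IkB_g + NFkB_n + IkB_pre",
  "spl_IkB | Splice IkB pre-mRNA | IkB_pre -> IkB_mRNA_n",
  "exp_IkB | Export IkB mRNA | IkB_mRNA_n -> IkB_mRNA",
  "trans_IkB | Translation IkB | IkB_mRNA -> IkB",
  "bind_A20 | Bind A20 gene | NFkB_n + A20_g -> NFkB.A20_g",
  "rel_A20 | Transcribe A20 | NFkB.A20_g -> A20_g + NFkB_n + A20_pre",
  "spl_A20 | Splice A20 pre-mRNA | A20_pre -> A20_mRNA_n",
  "exp_A20 | Export A20 mRNA | A20_mRNA_n -> A20_mRNA",
  "trans_A20 | Translation A20 | A20_mRNA -> A20",
  "bind_XIAP | Bind XIAP gene | NFkB_n + XIAP_g -> NFkB.XIAP_g",
  "rel_XIAP | Transcribe XIAP | NFkB.XIAP_g -> XIAP_g + NFkB_n + XIAP_pre",
  "spl_XIAP | Splice XIAP pre-mRNA | XIAP_pre -> XIAP_mRNA_n",
  "exp_XIAP | Export XIAP mRNA | XIAP_mRNA_n -> XIAP_mRNA",
  "trans_XIAP | Translation XIAP | XIAP_mRNA -> XIAP",
  "bind_cFLIPL | Bind cFLIPL gene | NFkB_n + cFLIPL_g -> NFkB.cFLIPL_g",
  "rel_cFLIPL | Transcribe cFLIPL | NFkB.cFLIPL_g -> cFLIPL_g + NFkB_n + cFLIPL_pre",
  "spl_cFLIPL | Splice cFLIPL pre-mRNA | cFLIPL_pre -> cFLIPL_mRNA_n",
  "exp_cFLIPL | Export cFLIPL mRNA | cFLIPL_mRNA_n -> cFLIPL_mRNA",
  "trans_cFLIPL | Translation cFLIPL | cFLIPL_mRNA -> cFLIPL",
  "bind_BCL2 | Bind BCL-2 gene | NFkB_n + BCL2_g -> NFkB.BCL2_g",
  "rel_BCL2 | Transcribe BCL-2 | NFkB.BCL2_g -> BCL2_g + NFkB_n + BCL2_pre",
  "spl_BCL2 | Splice BCL-2 pre-mRNA | BCL2_pre -> BCL2_mRNA_n",
  "exp_BCL2 | Export BCL-2 mRNA | BCL2_mRNA_n -> BCL2_mRNA",
  "trans_BCL2 | Translation BCL-2 | BCL2_mRNA -> BCL2",

  ## ---- NF-kB core ----
  "deg_NFkB | Deg_NF-kB | NFkB ->",
  "t_transloc | T25 NF-kB translocation | NFkB -> NFkB_n",
  "t_ikb_imp | IkB nuclear import | IkB -> IkB_n",
  "t_export | NF-kB nuclear export by IkB | NFkB_n + IkB_n -> NFkB.IkB_n",
  "t_nfkb_cyto | NF-kB:IkB to cytosol | NFkB.IkB_n -> NFkB.IkB",
  "t_ikb_phos | IKK phosphorylates IkB | NFkB.IkB + ~CI -> NFkB + IkB_p",
  "t_ikb_ub | IkB ubiquitination | IkB_p + Ub -> Ub_sub",
  "t_surv_sig | NF-kB response genes on | NFkB_n -> SurvivalSignal",
  "t_survival | Survival | SurvivalSignal ->",

  ## ---- shared proteasomal degradation hub ----
  "deg_prot | Proteasomal degradation | Ub_sub ->",

  ## ---- complex I assembly ----
  "t_tnf_sec | TNF secretion | TNF -> TNF_e",
  "t_tnfr1_tri | TNFR1 trimerisation | TNFR1 -> TNFR1_tri",
  "t_ci_core | T1 receptor complex | TNF_e + TNFR1_tri + TRADD -> TNF.TNFR1.TRADD",
  "t_rip1_rec | T2 RIP1 recruitment | TNF.TNFR1.TRADD + RIP1 -> CIpre",
  "t_traf2_ciap | TRAF2:cIAP1/2 | TRAF2 + cIAP -> TRAF2.cIAP",
  "t_tc_act | TRAF2:cIAP activation | TRAF2.cIAP -> TRAF2.cIAP_a",
  "t_ciap_rec | cIAP recruitment | CIpre + TRAF2.cIAP_a -> CIpre2",
  "t_k63 | K63 ubiquitination | CIpre2 + 2*Ub -> CI_K63",
  "t_ci_full | M1 chains, kinase recruitment | CI_K63 + LUBAC + Ub + TAK1 + TAB1 + IKK + NEMO -> CI",
  "t_a20_bind | A20 binds complex I | CI + A20 -> CI.A20",
  "t_a20_edit | A20 ubiquitin editing | CI.A20 -> CI.A20_ed",
  "t_a20_dissoc | A20 dissociates complex I | CI.A20_ed -> Ub_sub",
  "t_cyld_bind | CYLD recruitment | CI_K63 + CYLD -> CI.CYLD",
  "t_cyld_deub | CYLD K63 deubiquitination | CI.CYLD -> CI_deub",
  "t_cyld_dissoc | Complex I dissociation | CI_deub -> TRADD.RIP1 + Ub_sub",
  "t_ci_dissoc | Complex I destabilisation | CI_K63 -> TRADD.RIP1 + Ub_sub",
  "t_tradd_dissoc | TRADD dissociation | TNF.TNFR1.TRADD -> TRADD_c",

  ## ---- complex IIa / IIb and caspase 8 ----
  "t_c8_fold | Procaspase-8 maturation | ProCASP8 -> ProCASP8_m",
  "t_fadd_c8 | FADD:procaspase-8 | FADD + ProCASP8_m -> FADD.ProC8",
  "t_ciia | CIIa assembly | TRADD_c + FADD.ProC8 -> CIIa",
  "t_ciib | CIIb assembly | TRADD.RIP1 + FADD.ProC8 -> CIIb",
  "t_ciia_act | CIIa caspase processing | CIIa -> CIIa_act + CASP8_p10a",
  "t_casp8_a | CASP8 activation at CIIa | CIIa_act + CASP8_p10a -> CASP8 + Ub_sub",
  "t_ciib_act | CIIb caspase processing | CIIb -> CIIb_act + CASP8_p10b",
  "t_casp8_b | CASP8 activation at CIIb | CIIb_act + CASP8_p10b -> CASP8 + Ub_sub",
  "t_flipl_ciia | cFLIPL blocks CIIa | CIIa + cFLIPL -> CIIa.cFLIPL",
  "t_p43 | p43-FLIP processing | CIIa.cFLIPL -> p43_FLIP",
  "deg_p43 | Deg p43-FLIP | p43_FLIP ->",
  "t_flipl_ciib | cFLIPL in CIIb | CIIb + cFLIPL -> CIIb.cFLIPL",
  "t_rip_cleave | RIP1/RIP3 cleavage | CIIb.cFLIPL -> RIP1_cl",
  "t_rip1cl_ub | Cleaved RIP1 turnover | RIP1_cl -> Ub_sub",
  "t_flips_ciib | cFLIPs in CIIb | CIIb + cFLIPS -> CIIb.cFLIPs",
  "t_necro_flip | Necrosome via cFLIPs | CIIb.cFLIPs + RIP3 -> RIP1.RIP3 + Ub_sub",
  "t_necro_ciib | Necrosome from CIIb | CIIb + RIP3 -> RIP1.RIP3 + Ub_sub",
  "t_necro_tr | Necrosome from TRADD:RIP1 | TRADD.RIP1 + RIP3 -> RIP1.RIP3",
  "t_casp3_ext | Extrinsic CASP3 activation | ProCASP3 + ~CASP8 -> CASP3",
  "deg_CASP8 | Deg CASP8 | CASP8 ->",
  "t_dna_frag | CASP3 substrate cleavage | CASP3 -> DNA_frag",
  "t_apoptosis | Apoptosis | DNA_frag ->",
  "t_xiap_c3 | XIAP inhibits CASP3 | XIAP + CASP3 -> XIAP.CASP3",
  "deg_xiap_c3 | Deg XIAP:CASP3 | XIAP.CASP3 ->",
  "t_cyld_cleave | CASP8 cleaves CYLD | CYLD + ~CASP8 -> Ub_sub",

  ## ---- intrinsic (mitochondrial) apoptosis ----
  "t_bid | BID cleavage | BID + ~CASP8 -> tBID",
  "t_tbid_bax | tBID engages BAX | tBID + BAX -> tBID.BAX",
  "t_bax_act | BAX activation | tBID.BAX -> BAX_a + Ub_sub",
  "t_bax_oligo | BAX oligomerisation | BAX_a -> BAX_oligo",
  "t_bcl2_bax | BCL-2 sequesters BAX | BCL2 + BAX_a -> BCL2.BAX",
  "deg_bcl2_bax | Deg BCL-2:BAX | BCL2.BAX ->",
  "t_bcl2_tbid | BCL-2 sequesters tBID | BCL2 + tBID -> BCL2.tBID",
  "deg_bcl2_tbid | Deg BCL-2:tBID | BCL2.tBID ->",
  "t_momp | MOMP pore formation | BAX_oligo -> MOMP",
  "t_release | CytC and SMAC release | MOMP + CytC_m + SMAC_m -> CytC_c + SMAC_c",
  "t_apaf | CytC:APAF1 | CytC_c + APAF1 -> CytC.APAF1",
  "t_aposome | Apoptosome assembly | CytC.APAF1 + ProCASP9 -> Apoptosome + CASP9_p12",
  "t_casp9 | CASP9 activation | Apoptosome + CASP9_p12 -> CASP9",
  "t_casp3_int | Intrinsic CASP3 activation | ProCASP3 + ~CASP9 -> CASP3",
  "t_xiap_c9 | XIAP inhibits CASP9 | XIAP + CASP9 -> XIAP.CASP9",
  "deg_xiap_c9 | Deg XIAP:CASP9 | XIAP.CASP9 ->",
  "t_smac_dim | SMAC dimerisation | SMAC_c -> SMAC_dim",
  "t_smac_xiap | SMAC neutralises XIAP | SMAC_dim + XIAP -> SMAC.XIAP",
  "deg_smac_xiap | Deg SMAC:XIAP | SMAC.XIAP ->",

  ## ---- necroptosis ----
  "t_a20_rip3 | A20 inhibits necrosome | RIP1.RIP3 + A20 -> RIP3.A20",
  "deg_rip3_a20 | Deg RIP3:A20 | RIP3.A20 ->",
  "t_rip3_p | RIP3 autophosphorylation | RIP1.RIP3 -> RIP1.RIP3_p",
  "t_mlkl_rec | MLKL recruitment | RIP1.RIP3_p + MLKL -> MLKL_p + Ub_sub",
  "t_mlkl_oligo | MLKL oligomerisation | MLKL_p -> MLKL_oligo",
  "t_mlkl_pm | MLKL to plasma membrane | MLKL_oligo -> MLKL_PM",
  "t_pore | Membrane pore formation | MLKL_PM -> Membrane_pore",
  "t_necroptosis | Necroptosis | Membrane_pore ->"
)

marking <- c(IkB_g = 1, A20_g = 1, XIAP_g = 1, cFLIPL_g = 1, BCL2_g = 1)

parse_side <- function(s) {
  s <- trimws(s)
  if (s == "") return(data.frame(place = character(), weight = numeric(),
                                 read = logical()))
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  do.call(rbind, lapply(terms, function(tm) {
    read <- startsWith(tm, "~")
    tm <- sub("^~", "", tm)
    w <- 1
    if (grepl("*", tm, fixed = TRUE)) {
      parts <- strsplit(tm, "*", fixed = TRUE)[[1]]
      w <- as.numeric(parts[1]); tm <- trimws(parts[2])
    }
    data.frame(place = tm, weight = w, read = read)
  }))
}

build <- function() {
  trans <- list(); arcs <- list()
  for (line in rx) {
    f <- trimws(strsplit(line, "|", fixed = TRUE)[[1]])
    id <- f[1]; name <- f[2]
    sides <- strsplit(f[3], "->", fixed = TRUE)[[1]]
    lhs <- parse_side(sides[1])
    rhs <- parse_side(if (length(sides) > 1) sides[2] else "")
    stopifnot(!any(rhs$read))
    if (id %in% names(trans)) stop("duplicate transition id: ", id)
    trans[[id]] <- name
    if (nrow(lhs)) {
      arcs[[length(arcs) + 1L]] <- data.frame(source = lhs$place, target = id,
                                              weight = lhs$weight, read = lhs$read)
      rd <- lhs[lhs$read, , drop = FALSE]
      if (nrow(rd)) {
        arcs[[length(arcs) + 1L]] <- data.frame(source = id, target = rd$place,
                                                weight = rd$weight, read = TRUE)
      }
    }
    if (nrow(rhs)) {
      arcs[[length(arcs) + 1L]] <- data.frame(source = id, target = rhs$place,
                                              weight = rhs$weight, read = FALSE)
    }
  }
  arcs <- do.call(rbind, arcs)
  pl <- sort(setdiff(unique(c(arcs$source, arcs$target)), names(trans)))
  list(places = pl, transitions = trans, arcs = arcs)
}

m <- build()
cat(sprintf("places=%d transitions=%d edges=%d\n",
            length(m$places), length(m$transitions), nrow(m$arcs)))
syn <- grep("^syn_", names(m$transitions), value = TRUE)
cat(sprintf("syntheses=%d translations=%d\n", length(syn),
            length(grep("^trans_", names(m$transitions)))))

## ---- emit fixture ----
out <- "inst/extdata/tnfr1_synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

place_name <- function(id) {
  nm <- gsub(".", ":", id, fixed = TRUE)
  nm <- sub("^NFkB", "NF-kB", nm)
  nm <- sub(":NFkB", ":NF-kB", nm)
  nm <- gsub("IkB", "IkB", nm)
  nm <- sub("^BCL2", "BCL-2", nm)
  nm <- sub(":BCL2", ":BCL-2", nm)
  nm <- sub("^cIAP$", "cIAP1/2", nm)
  nm
}

annot <- function(id) {
  if (grepl("_g$", id)) "gene"
  else if (grepl("(_pre|_mRNA)", id)) "transcript"
  else if (grepl("[.]", id)) "complex"
  else if (id %in% c("SurvivalSignal", "DNA_frag", "Membrane_pore", "MOMP",
                     "Ub_sub")) "response"
  else "protein"
}

places <- data.frame(
  id = m$places,
  name = vapply(m$places, place_name, character(1)),
  annotation = vapply(m$places, annot, character(1)),
  marking = ifelse(m$places %in% names(marking), 1L, 0L)
)
write.table(places, file.path(out, "places.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

transitions <- data.frame(id = names(m$transitions),
                          name = unlist(m$transitions))
write.table(transitions, file.path(out, "transitions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

arcs <- m$arcs
write.table(arcs, file.path(out, "arcs.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

manifest <- list(
  model = "tnfr1_synthetic",
  note = paste("Synthetic reconstruction of a TNFR1 signal-transduction",
               "Petri net assembled from published structural descriptions;",
               "not the original supplementary model."),
  expected_counts = list(places = 118L, transitions = 130L, edges = 299L),
  initial_marking_places = names(marking),
  synthesis_transitions = sort(c(syn, grep("^trans_", names(m$transitions),
                                           value = TRUE))),
  response_outputs = list(t_survival = "survival",
                          t_apoptosis = "apoptosis",
                          t_necroptosis = "necroptosis"),
  expected_pi_supports = list(
    c("IkB_g", "NFkB.IkB_g"), c("A20_g", "NFkB.A20_g"),
    c("XIAP_g", "NFkB.XIAP_g"), c("cFLIPL_g", "NFkB.cFLIPL_g"),
    c("BCL2_g", "NFkB.BCL2_g")),
  fig_column_set = c("CI", "CIIa", "CIIb", "Apoptosome", "RIP1.RIP3",
                     "CASP3", "CASP8", "CASP9", "MLKL_PM", "BCL2.BAX",
                     "XIAP.CASP3", "XIAP.CASP9", "CIIb.cFLIPs", "CI.CYLD",
                     "NFkB_n", "TRADD.RIP1", "CIIb.cFLIPL", "CI.A20",
                     "SMAC.XIAP", "tBID", "MOMP")
)
yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

rules <- list(
  response_outputs = list(t_survival = "survival",
                          t_apoptosis = "apoptosis",
                          t_necroptosis = "necroptosis"),
  resolution_rules = list(
    list(label = "apoptosis",
         requires_outputs = list("apoptosis"),
         requires_transitions = list("t_bcl2_bax"))
  )
)
yaml::write_yaml(rules, file.path(out, "outcome_rules.yaml"))
cat("fixture written to", out, "\n")
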