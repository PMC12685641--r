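# Curated kinetic model of cGAS-STING / IL-6 / FOXO-driven autophagy in
# NSCLC: 6 compartments, 72 dynamic signaling species (plus 17 constant
# boundary templates: gene loci and external pools), 83 irreversible
# reactions. Topology transcribed from the pathway narrative; rate
# constants are a documented default parameterization, calibrated once so
# that trajectories are bounded on [0, 100] s and the expected late-time
# accumulators (autophagosome, nuclear FOXO1/FOXO3a, ER-membrane
# cGAMP-STING, ATG12/5) dominate. Every parameter is "calibrated, not
# printed": the source narrative does not publish rate constants.

# en dash used in the printed reaction name "LC3-2 gene"
.EN <- "–"

.nsclc_species <- function() {
  # id, name, compartment, initial amount (molecules), boundary
  s <- function(id, name, comp, x0, b = FALSE) {
    species_state(id, name, comp, x0, boundary = b)
  }
  list(
    # -- boundary: external ligand / metabolite pools --------------------
    s("dsdna_pm",  "dsDNA",        "pm",  2e5, TRUE),
    s("egf_pm",    "EGF",          "pm",  1e5, TRUE),
    s("lps_pm",    "LPS",          "pm",  1e5, TRUE),
    s("il10_pm",   "IL10",         "pm",  1e5, TRUE),
    s("adp_pm",    "ADP",          "pm",  1e6, TRUE),
    s("atp_cyt",   "ATP",          "cyt", 1e6, TRUE),
    s("gtp_cyt",   "GTP",          "cyt", 1e6, TRUE),
    s("ampgamma",  "AMP gamma",    "cyt", 8e5, TRUE),
    s("atg10",     "ATG10",        "cyt", 1e4, TRUE),
    # -- boundary: gene loci (constant transcription templates) ----------
    s("atg5_gene",   "ATG5 gene",   "nuc", 1e3, TRUE),
    s("atg7_gene",   "ATG7 gene",   "nuc", 1e3, TRUE),
    s("atg12_gene",  "ATG12 gene",  "nuc", 1e3, TRUE),
    s("lc32_gene",   paste0("LC3", .EN, "2 gene"), "nuc", 1e3, TRUE),
    s("atg16l_gene", "ATG16L gene", "nuc", 1e3, TRUE),
    s("sting_gene",  "Sting gene",  "nuc", 1e3, TRUE),
    s("ifn1_gene",   "IFN1 gene",   "nuc", 1e3, TRUE),
    s("il6_gene",    "IL6 gene",    "nuc", 1e3, TRUE),
    # -- cGAS sensing and cGAMP-STING axis -------------------------------
    s("dsdna_cyt",        "dsDNA",            "cyt", 1e3),
    s("cgas_cyt",         "cGAS",             "cyt", 1.2e5),
    s("rec_cgas",         "recruited cGAS",   "cyt", 1e3),
    s("dsdna_cgas",       "dsDNAcGAScomplex", "cyt", 1e3),
    s("cgamp_cyt",        "cGAMP",            "cyt", 1e3),
    s("cgamp_er",         "cGAMP",            "er",  1e3),
    s("sting_er",         "STING",            "er",  7e5),
    s("cgampsting_er",    "cGAMP STING",      "er",  1e3),
    s("cgampsting_ergic", "cGAMP STING",      "ergic", 1e3),
    s("cgampsting_golgi", "cGAMP STING",      "golgi", 1e3),
    # -- ERGIC isolation membrane / phagophore branch --------------------
    s("sec12_tmed9", "SEC12/TMED9",             "ergic", 1.5e5),
    s("ergic_mem",   "ERGIC",                   "ergic", 8e5),
    s("ergic_iso",   "ERGIC isolation membrane","ergic", 1e3),
    s("ergic_cyt",   "ERGIC",                   "cyt",   1e3),
    s("ewc",         "ERGIC/WIPI2/COP2",        "cyt",   1e3),
    s("phagophore",  "Phagophore",              "cyt",   1e3),
    # -- Golgi TBK1/IKK activation ---------------------------------------
    s("tbk_golgi", "TBK",           "golgi", 2e4),
    s("ikk_golgi", "IKK",           "golgi", 2e4),
    s("act_tbk",   "activated TBK", "golgi", 1e3),
    s("act_ikk",   "activated IKK", "golgi", 1e3),
    # -- IRF3 / NF-kB ----------------------------------------------------
    s("pirf3_cyt", "Phos IRF3",           "cyt", 1e3),
    s("pirf3_nuc", "Phos IRF3",           "nuc", 1e3),
    s("ikk_nfkb",  "IKK/NFKB complex",    "cyt", 1e3),
    s("nfkb_nuc",  "NFKBp65p50 complex",  "nuc", 1e3),
    # -- IFN1 and IL6 expression and export ------------------------------
    s("ifn1_nuc", "IFN1", "nuc", 1e3),
    s("ifn1_cyt", "IFN1", "cyt", 1e3),
    s("ifn1_pm",  "IFN1", "pm",  1e3),
    s("il6_nuc",  "IL6",  "nuc", 1e3),
    s("il6_cyt",  "IL6",  "cyt", 1e3),
    s("il6_pm",   "IL6",  "pm",  1e3),
    # -- receptors and JAK/STAT ------------------------------------------
    s("ifnar",          "IFNAR1/2",              "pm",  1.5e5),
    s("ifn_act",        "IFN activated",         "pm",  1e3),
    s("jak1tyk2",       "JAK1/TYK2",             "cyt", 1e3),
    s("il6r",           "IL6R/gp130",            "pm",  1.5e5),
    s("il6_il6r",       "IL6/IL6R/gp130",        "pm",  1e3),
    s("il10r",          "IL10R1/R2",             "pm",  1.5e5),
    s("il10_rc",        "IL10 receptor complex", "pm",  1e3),
    s("stat3_dimer",    "STAT3 dimer",           "cyt", 1e3),
    s("stat12irf9_cyt", "STAT1/2/IRF9",          "cyt", 1e3),
    s("stat12irf9_nuc", "STAT1/2/IRF9",          "nuc", 1e3),
    s("sting_nuc",      "STING",                 "nuc", 1e3),
    # -- FOXO shuttling ---------------------------------------------------
    s("foxo1_cyt", "FoxO1", "cyt", 6.5e5),
    s("foxo3_cyt", "FoxO3", "cyt", 6e5),
    s("foxo1_nuc", "FoxO1", "nuc", 1e3),
    s("foxo3_nuc", "FoxO3", "nuc", 1e3),
    # -- ATG machinery ----------------------------------------------------
    s("atg5",          "ATG5",           "cyt", 1e3),
    s("atg7",          "ATG7",           "cyt", 1e3),
    s("atg12",         "ATG12",          "cyt", 1e3),
    s("atg127",        "ATG12/7",        "cyt", 1e3),
    s("atg1210",       "ATG12/10",       "cyt", 1e3),
    s("atg125",        "ATG12/5",        "cyt", 1e3),
    s("atg16l",        "ATG16L",         "cyt", 1e3),
    s("atg12516",      "ATG12/5/16L",    "cyt", 1e3),
    s("lc32",          "LC3-2",          "cyt", 1e3),
    s("lc3_atg",       "LC3/ATG12/5/16L","cyt", 1e3),
    s("autophagosome", "Autophagosome",  "cyt", 1e3),
    # -- ADP / AMP / ULK1 energy sensing ---------------------------------
    s("adp_cyt", "ADP",          "cyt", 1e3),
    s("adpamp",  "ADPAMP gamma", "cyt", 1e3),
    s("ulk1c",   "ULK1 complex", "cyt", 1e3),
    # -- EGF / PI3K / AKT / mTORC1 / HIF-1a ------------------------------
    s("egfr",     "EGFR",       "pm",  2e5),
    s("egf_egfr", "EGF/EGFR",   "pm",  1e3),
    s("pi3k",     "PI3K",       "cyt", 1e3),
    s("akt",      "AKT",        "cyt", 1.2e5),
    s("mtorc1",   "mTORC1",     "cyt", 1e3),
    s("hif1a_i",  "HIF1alpha",  "cyt", 1.8e5),
    s("hif1a",    "HIF1 alpha", "cyt", 1e3),
    # -- LPS / TLR4 / MYD88 ----------------------------------------------
    s("tlr4",     "TLR4",     "pm",  1.8e5),
    s("lps_tlr4", "LPS/TLR4", "pm",  1e3),
    s("myd88",    "MYD88",    "cyt", 1.2e4),
    s("irak4",    "IRAK4",    "cyt", 1.2e4),
    s("traf3",    "TRAF3",    "cyt", 1.5e4),
    s("traf6",    "TRAF6",    "cyt", 1.5e4)
  )
}

.nsclc_reactions <- function() {
  ma <- function(id, name, re, pr, k, mo = character()) {
    reaction(id, name, reactants = re, products = pr, modifiers = mo,
             rate = rate_law("mass_action", k = k))
  }
  mm <- function(id, name, re, pr, Vmax, Km, mo = character()) {
    reaction(id, name, reactants = re, products = pr, modifiers = mo,
             rate = rate_law("michaelis_menten", Vmax = Vmax, Km = Km))
  }
  # gene-expression step: constant gene template, transcription factor as
  # the Hill driver (modifier)
  hill <- function(id, name, gene, tf, prod, Vmax, K, n = 2) {
    reaction(id, name,
             reactants = stats::setNames(1L, gene),
             products = stats::setNames(c(1L, 1L), c(gene, prod)),
             modifiers = tf,
             rate = rate_law("hill", Vmax = Vmax, K = K, n = n))
  }
  c1 <- function(x) stats::setNames(1L, x)
  c2 <- function(x, y) stats::setNames(c(1L, 1L), c(x, y))

  list(
    # -- cGAS sensing ----------------------------------------------------
    ma("r01", "dsDNA{Plasma membrane} -> dsDNA{Cytoplasm}",
       c1("dsdna_pm"), c1("dsdna_cyt"), 2e-3),
    ma("r02", "dsDNA{Cytoplasm} -> recruited cGAS",
       c1("dsdna_cyt"), c1("rec_cgas"), 0.05),
    ma("r03", "cGAS -> recruited cGAS",
       c1("cgas_cyt"), c1("rec_cgas"), 0.03),
    ma("r04", "recruited cGAS -> dsDNAcGAScomplex",
       c1("rec_cgas"), c1("dsdna_cgas"), 0.08),
    ma("r05", "dsDNAcGAScomplex + ATP -> dsDNAcGAScomplex + cGAMP{Cytoplasm}",
       c2("dsdna_cgas", "atp_cyt"), c2("dsdna_cgas", "cgamp_cyt"), 2e-8),
    ma("r06", "dsDNAcGAScomplex + GTP -> dsDNAcGAScomplex + cGAMP{Cytoplasm}",
       c2("dsdna_cgas", "gtp_cyt"), c2("dsdna_cgas", "cgamp_cyt"), 1e-8),
    ma("r07", "cGAMP{Cytoplasm} -> cGAMP{\"ER membrane\"}",
       c1("cgamp_cyt"), c1("cgamp_er"), 0.5),
    ma("r08", "STING{\"ER membrane\"} -> \"cGAMP STING\"{\"ER membrane\"}",
       c1("sting_er"), c1("cgampsting_er"), 0.03),
    ma("r09", "cGAMP{ER membrane} -> cGAMP STING{ER membrane}",
       c1("cgamp_er"), c1("cgampsting_er"), 0.3),
    ma("r10", "cGAMP STING{ER membrane} -> cGAMP STING{ERGIC}",
       c1("cgampsting_er"), c1("cgampsting_ergic"), 5e-4),
    # -- ERGIC / phagophore ----------------------------------------------
    ma("r11", "cGAMP STING{ERGIC} -> cGAMP STING{Golgi}",
       c1("cgampsting_ergic"), c1("cgampsting_golgi"), 0.01),
    ma("r12", "cGAMP STING{ERGIC} + SEC12/TMED9 -> cGAMP STING{ERGIC} + ERGIC isolation membrane",
       c2("cgampsting_ergic", "sec12_tmed9"),
       c2("cgampsting_ergic", "ergic_iso"), 5e-7),
    ma("r13", "ERGIC -> ERGIC isolation membrane",
       c1("ergic_mem"), c1("ergic_iso"), 8e-3),
    ma("r14", "ERGIC{\"ERGIC Isolation membrane\"} -> ERGIC{Cytoplasm}",
       c1("ergic_iso"), c1("ergic_cyt"), 0.1),
    ma("r15", "ERGIC{Cytoplasm} -> ERGIC/WIPI2/COP2",
       c1("ergic_cyt"), c1("ewc"), 0.1),
    ma("r16", "ERGIC/WIPI2/COP2 -> Phagophore",
       c2("pi3k", "ewc"), c2("pi3k", "phagophore"), 5e-6),
    ma("r17", "Phagophore -> Autophagosome",
       c1("phagophore"), c1("autophagosome"), 0.05),
    ma("r18", "ULK1 complex -> Phagophore",
       c1("ulk1c"), c1("phagophore"), 0.02),
    ma("r19", "LC3/ATG12/5/16L -> Autophagosome",
       c1("lc3_atg"), c1("autophagosome"), 1),
    # -- Golgi TBK1/IKK ---------------------------------------------------
    ma("r20", "TRAF3 -> TBK{Golgi}",
       c1("traf3"), c1("tbk_golgi"), 0.01),
    ma("r21", "TRAF6 -> IKK{Golgi}",
       c1("traf6"), c1("ikk_golgi"), 0.01),
    ma("r22", "cGAMP STING{Golgi} + TBK{Golgi} -> cGAMP STING{Golgi} + activated TBK",
       c2("cgampsting_golgi", "tbk_golgi"),
       c2("cgampsting_golgi", "act_tbk"), 2e-6),
    ma("r23", "cGAMP STING{Golgi} + IKK{Golgi} -> cGAMP STING{Golgi} + activated IKK",
       c2("cgampsting_golgi", "ikk_golgi"),
       c2("cgampsting_golgi", "act_ikk"), 2e-6),
    ma("r24", "activated TBK -> Phos IRF3{Cytoplasm}",
       c1("act_tbk"), c1("pirf3_cyt"), 0.05),
    ma("r25", "Phos IRF3{Cytoplasm} -> \"Phos IRF3\"{Nucleus}",
       c1("pirf3_cyt"), c1("pirf3_nuc"), 0.05),
    ma("r26", "activated IKK -> IKK/NFKB complex",
       c1("act_ikk"), c1("ikk_nfkb"), 0.05),
    ma("r27", "IKK/NFKB complex -> NFKBp65p50 complex{Nucleus}",
       c1("ikk_nfkb"), c1("nfkb_nuc"), 0.05),
    # -- IFN1 / IL6 transcription and export ------------------------------
    hill("r28", "Phos IRF3{Nucleus} + IFN1 gene -> IFN1 gene + IFN1{Nucleus}",
         "ifn1_gene", "pirf3_nuc", "ifn1_nuc", 2200, 2e4),
    hill("r29", "NFKBp65p50 complex + IL6 gene -> IL6 gene + IL6{Nucleus}",
         "il6_gene", "nfkb_nuc", "il6_nuc", 2000, 2e4),
    hill("r30", "NFKBp65p50 complex + IFN1 gene -> IFN1 gene + IFN1{Nucleus}",
         "ifn1_gene", "nfkb_nuc", "ifn1_nuc", 800, 2e4),
    ma("r31", "IFN1{Nucleus} -> IFN1{Cytoplasm}",
       c1("ifn1_nuc"), c1("ifn1_cyt"), 0.05),
    ma("r32", "IFN1{Cytoplasm} -> IFN1{\"Plasma membrane\"}",
       c1("ifn1_cyt"), c1("ifn1_pm"), 0.05),
    ma("r33", "IL6{Nucleus} -> IL6{Cytoplasm}",
       c1("il6_nuc"), c1("il6_cyt"), 0.05),
    ma("r34", "IL6{Cytoplasm} -> IL6{\"Plasma membrane\"}",
       c1("il6_cyt"), c1("il6_pm"), 0.05),
    ma("r35", "ATP -> ADP{Cytoplasm}",
       c1("atp_cyt"), c1("adp_cyt"), 1e-3),
    # -- receptor layer and JAK/STAT --------------------------------------
    ma("r36", "IFN1{Plasma membrane} -> IFN activated",
       c1("ifn1_pm"), c1("ifn_act"), 0.04),
    ma("r37", "IFNAR1/2 -> IFN activated",
       c1("ifnar"), c1("ifn_act"), 2e-4),
    ma("r38", "IFN activated -> JAK1/TYK2",
       c1("ifn_act"), c1("jak1tyk2"), 0.05),
    ma("r39", "IL10 -> IL10 receptor complex",
       c1("il10_pm"), c1("il10_rc"), 3e-3),
    ma("r40", "IL10R1/R2 -> IL10 receptor complex",
       c1("il10r"), c1("il10_rc"), 2e-4),
    ma("r41", "IL6{\"Plasma membrane\"} + IL6R/gp130 -> IL6/IL6R/gp130",
       c2("il6_pm", "il6r"), c1("il6_il6r"), 5e-8),
    ma("r42", "IL6/IL6R/gp130 -> STAT3 dimer",
       c1("il6_il6r"), c1("stat3_dimer"), 0.05),
    ma("r43", "IL10 receptor complex -> STAT3 dimer",
       c1("il10_rc"), c1("stat3_dimer"), 0.05),
    ma("r44", "JAK1/TYK2 -> STAT3 dimer",
       c1("jak1tyk2"), c1("stat3_dimer"), 0.05),
    ma("r45", "JAK1/TYK2 -> STAT1/2/IRF9{Cytoplasm}",
       c1("jak1tyk2"), c1("stat12irf9_cyt"), 0.05),
    ma("r46", "STAT1/2/IRF9{Cytoplasm} -> STAT1/2/IRF9{Nucleus}",
       c1("stat12irf9_cyt"), c1("stat12irf9_nuc"), 0.05),
    hill("r47", "STAT1/2/IRF9{Nucleus} + \"Sting gene\" -> STING{Nucleus} + \"Sting gene\"",
         "sting_gene", "stat12irf9_nuc", "sting_nuc", 600, 2e4),
    hill("r48", "HIF1 alpha + \"Sting gene\" -> STING{Nucleus} + \"Sting gene\"",
         "sting_gene", "hif1a", "sting_nuc", 560, 5e4),
    ma("r49", "STING{Nucleus} -> STING{\"ER membrane\"}",
       c1("sting_nuc"), c1("sting_er"), 0.05),
    # -- STAT3 / FOXO shuttling -------------------------------------------
    ma("r50", "STAT3 dimer -> FoxO1{Cytoplasm} + FoxO3{Cytoplasm}",
       c1("stat3_dimer"),
       stats::setNames(c(1L, 1L), c("foxo1_cyt", "foxo3_cyt")), 0.1),
    ma("r51", "FoxO1{Cytoplasm} -> FoxO1{Nucleus}",
       c2("stat3_dimer", "foxo1_cyt"), c2("stat3_dimer", "foxo1_nuc"), 8e-6),
    ma("r52", "FoxO3{Cytoplasm} -> FoxO3{Nucleus}",
       c2("stat3_dimer", "foxo3_cyt"), c2("stat3_dimer", "foxo3_nuc"), 8e-6),
    # -- FOXO-driven ATG transcription ------------------------------------
    hill("r53", "FoxO1{Nucleus} + \"ATG5 gene\" -> \"ATG5 gene\" + ATG5",
         "atg5_gene", "foxo1_nuc", "atg5", 1114, 1e5),
    hill("r54", "FoxO1{Nucleus} + ATG7 gene -> ATG7 gene + ATG7",
         "atg7_gene", "foxo1_nuc", "atg7", 900, 1e5),
    hill("r55", paste0("ATG12 gene + FoxO3{Nucleus} -> ATG12 + \"ATG12 gene\""),
         "atg12_gene", "foxo3_nuc", "atg12", 996, 1e5),
    hill("r56", paste0("FoxO3{Nucleus} + \"LC3", .EN, "2 gene\" -> LC3-2 + \"LC3", .EN, "2 gene\""),
         "lc32_gene", "foxo3_nuc", "lc32", 996, 1e5),
    hill("r57", "FoxO3{Nucleus} + ATG16L gene -> ATG16L gene + ATG16L",
         "atg16l_gene", "foxo3_nuc", "atg16l", 700, 1e5),
    # -- ATG conjugation cascade ------------------------------------------
    ma("r58", "ATG7 -> ATG12/7", c1("atg7"), c1("atg127"), 0.05),
    ma("r59", "ATG12 -> ATG12/7", c1("atg12"), c1("atg127"), 0.05),
    mm("r60", "ATG12/7 -> ATG12/10",
       c1("atg127"), c1("atg1210"), 3200, 1e4, mo = "atg10"),
    ma("r61", "ATG12/10 -> ATG12/5", c1("atg1210"), c1("atg125"), 0.05),
    ma("r62", "ATG5 -> ATG12/5", c1("atg5"), c1("atg125"), 0.05),
    ma("r63", "ATG12/5 -> ATG12/5/16L", c1("atg125"), c1("atg12516"), 0.05),
    ma("r64", "ATG16L -> ATG12/5/16L", c1("atg16l"), c1("atg12516"), 0.05),
    ma("r65", "LC3-2 -> LC3/ATG12/5/16L", c1("lc32"), c1("lc3_atg"), 0.05),
    ma("r66", "ATG12/5/16L -> LC3/ATG12/5/16L",
       c1("atg12516"), c1("lc3_atg"), 0.05),
    # -- ADP / AMP / ULK1 --------------------------------------------------
    ma("r67", "ADP{Plasma membrane} -> ADP{Cytoplasm}",
       c1("adp_pm"), c1("adp_cyt"), 1.5e-3),
    ma("r68", "ADP{Cytoplasm} -> ADPAMP gamma",
       c1("adp_cyt"), c1("adpamp"), 0.1),
    ma("r69", "AMP gamma -> ADPAMP gamma",
       c1("ampgamma"), c1("adpamp"), 1e-4),
    ma("r70", "ADPAMP gamma -> ULK1 complex",
       c1("adpamp"), c1("ulk1c"), 0.08),
    ma("r71", "ULK1 complex -> PI3K", c1("ulk1c"), c1("pi3k"), 0.04),
    # -- EGF / PI3K / AKT / mTORC1 / HIF-1a -------------------------------
    ma("r72", "EGF -> EGF/EGFR", c1("egf_pm"), c1("egf_egfr"), 2e-3),
    ma("r73", "EGFR -> EGF/EGFR", c1("egfr"), c1("egf_egfr"), 1e-4),
    ma("r74", "EGF/EGFR -> PI3K", c1("egf_egfr"), c1("pi3k"), 0.05),
    ma("r75", "PI3K -> AKT", c1("pi3k"), c1("akt"), 0.03),
    ma("r76", "AKT -> mTORC1", c1("akt"), c1("mtorc1"), 0.01),
    mm("r77", "HIF1alpha -> \"HIF1 alpha\"",
       c1("hif1a_i"), c1("hif1a"), 949, 1e5, mo = "mtorc1"),
    # -- LPS / TLR4 / MYD88 ------------------------------------------------
    ma("r78", "LPS -> TLR4", c1("lps_pm"), c1("tlr4"), 2e-3),
    ma("r79", "TLR4 -> LPS/TLR4", c1("tlr4"), c1("lps_tlr4"), 1e-4),
    ma("r80", "LPS/TLR4 -> MYD88", c1("lps_tlr4"), c1("myd88"), 0.05),
    ma("r81", "MYD88 -> IRAK4", c1("myd88"), c1("irak4"), 0.05),
    ma("r82", "IRAK4 -> TRAF3", c1("irak4"), c1("traf3"), 0.03),
    ma("r83", "IRAK4 -> TRAF6", c1("irak4"), c1("traf6"), 0.03)
  )
}

# Pathway membership used by crosstalk scoring. Hand-assigned from the
# pathway narrative; multi-membership encodes bridging complexes. This is
# an interpretive, editable annotation, not a database import.
.nsclc_pathways <- function() {
  P <- list()
  tag <- function(ids, ...) {
    for (i in ids) P[[i]] <<- union(P[[i]], c(...))
  }
  tag(c("dsdna_pm", "dsdna_cyt", "cgas_cyt", "rec_cgas", "dsdna_cgas",
        "cgamp_cyt", "cgamp_er", "sting_er", "cgampsting_er",
        "cgampsting_ergic", "cgampsting_golgi", "atp_cyt", "gtp_cyt",
        "sting_nuc", "sting_gene", "act_tbk", "act_ikk"), "cGAS-STING")
  tag("atp_cyt", "ADP/AMP")  # ATP hydrolysis feeds the cytosolic ADP pool
  tag(c("sec12_tmed9", "ergic_mem", "ergic_iso", "ergic_cyt", "ewc",
        "phagophore"), "cGAS-STING", "autophagy")
  tag(c("tbk_golgi", "ikk_golgi"), "cGAS-STING", "LPS/TLR4")
  tag(c("pirf3_cyt", "pirf3_nuc"), "cGAS-STING", "IFN1")
  tag(c("ikk_nfkb"), "cGAS-STING", "IL-6")
  tag(c("nfkb_nuc"), "cGAS-STING", "IL-6", "IFN1")
  tag(c("ifn1_gene", "ifn1_nuc", "ifn1_cyt", "ifn1_pm", "ifnar",
        "ifn_act"), "IFN1")
  tag(c("jak1tyk2"), "IFN1", "JAK/STAT")
  tag(c("stat12irf9_cyt"), "JAK/STAT", "IFN1")
  tag(c("stat12irf9_nuc"), "JAK/STAT", "IFN1", "cGAS-STING")
  tag(c("il6_gene", "il6_nuc", "il6_cyt", "il6_pm", "il6r", "il6_il6r"),
      "IL-6")
  tag(c("il10_pm", "il10r", "il10_rc"), "IL-10")
  tag(c("stat3_dimer"), "IL-6", "IL-10")
  tag(c("foxo1_cyt", "foxo3_cyt"), "autophagy", "IL-6")
  tag(c("foxo1_nuc", "foxo3_nuc"), "autophagy")
  tag(c("atg5", "atg7", "atg12", "atg10", "atg127", "atg1210", "atg125",
        "atg16l", "atg12516", "lc32", "lc3_atg", "autophagosome",
        "atg5_gene", "atg7_gene", "atg12_gene", "lc32_gene",
        "atg16l_gene"), "autophagy")
  tag(c("adp_pm", "adp_cyt", "ampgamma", "adpamp"), "ADP/AMP")
  tag(c("ulk1c"), "ADP/AMP", "autophagy")
  tag(c("pi3k"), "EGF/EGFR", "ADP/AMP")
  tag(c("egf_pm", "egfr", "egf_egfr", "akt", "mtorc1", "hif1a_i"),
      "EGF/EGFR")
  tag(c("hif1a"), "EGF/EGFR", "cGAS-STING")
  tag(c("lps_pm", "tlr4", "lps_tlr4", "myd88", "irak4", "traf3", "traf6"),
      "LPS/TLR4")
  P
}

#' Build the curated NSCLC autophagy model
#'
#' Deterministically constructs the compartmental kinetic model of
#' cGAS-STING/IL-6/FOXO-driven autophagy in non-small cell lung cancer:
#' six compartments (cytoplasm, plasma membrane, nucleus, ER, Golgi,
#' ERGIC), 72 dynamic signaling species plus 17 constant boundary templates
#' (gene loci and external pools), and 83 irreversible reactions assembled
#' from mass-action (association/translocation), Michaelis-Menten
#' (enzymatic) and Hill (gene expression) rate laws.
#'
#' Rate constants are a calibrated default parameterization (the source
#' narrative prints none); they are chosen once so that trajectories are
#' bounded on the 100 s horizon and autophagosome, nuclear FOXO1/FOXO3a and
#' ER-membrane cGAMP-STING are among the dominant late accumulators.
#'
#' @return A validated `reaction_model`.
#' @examples
#' m <- build_nsclc_model()
#' n_species(m)           # 72 dynamic signaling species
#' length(m$reactions)    # 83
#' @export
build_nsclc_model <- function() {
  comps <- list(
    compartment("cyt",   "Cytoplasm",       "cytoplasm"),
    compartment("pm",    "Plasma membrane", "plasma_membrane"),
    compartment("nuc",   "Nucleus",         "nucleus"),
    compartment("er",    "ER membrane",     "endoplasmic_reticulum"),
    compartment("golgi", "Golgi apparatus", "golgi"),
    compartment("ergic", "ERGIC",           "ergic"))
  m <- reaction_model(
    compartments = comps,
    species = .nsclc_species(),
    reactions = .nsclc_reactions(),
    pathway_tags = .nsclc_pathways(),
    name = "NSCLC cGAS-STING/IL-6/FOXO autophagy model",
    t_end = 100,
    notes = paste("Curated from the pathway narrative; rate constants",
                  "calibrated, not printed."))
  assert_valid(m)
  m
}
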