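## Reduced core model of the pVHL interaction network.
##
## The encoding follows the pathway narrative of the VHL disease literature:
## HIF-1alpha and pVHL are produced constitutively from a joint input; under
## normoxia HIF-1alpha is hydroxylated in an oxygen-dependent step and
## degraded through the VCB (pVHL-Elongin B/C) ubiquitin ligase with Cul2;
## two alternative degradation routes run through p53/Mdm2 and through
## GSK3beta phosphorylation. Non-degraded HIF-1alpha enters the nucleus,
## dimerises with ARNT and drives HRE transcription of VEGF, EPO, endothelin,
## GLUT1, LDH-A, PDK1, MMPs and Nur77 with the p300/Creb/c-jun cofactors.
## VEGF (stabilised by HuR) and EPO signal through three, respectively two,
## branches that improve oxygenation; Sp1 sustains HIF-independent VEGF
## transcription. Glucose uptake (GLUT1/2/4), glycolysis, the pyruvate fates
## (PyrDH/acetyl-CoA, carboxylation to oxalacetate, LDH/lactate), the Krebs
## cycle and the respiratory-chain ATPase close the energy loop that couples
## the signalling half of the model to the metabolic half through the shared
## ATP/ADP, NAD/NADH and oxygen pools. pVHL additionally stabilises the
## extracellular matrix (fibronectin vs MMPs), sequesters HuR and Sp1,
## supports Jade1-dependent beta-catenin degradation against Wnt
## proliferation signalling, and aPKC-zeta-II regulates tight junctions and
## Par6.

## one reaction = one transition plus its arcs; read = side conditions
rx <- function(id, name, from = character(), to = character(),
               read = character(), kind = "internal") {
  list(id = id, name = name, from = from, to = to, read = read, kind = kind)
}

core_reactions <- function() {
  list(
    ## --- HIF-1alpha / pVHL turnover -----------------------------------
    rx("t_98", "input transition for Hif and VHL",
       to = c("hif1a_cyt", "pvhl"), kind = "input"),
    rx("t_hif_out", "constitutive HIF-1a consumption", from = "hif1a_cyt",
       kind = "output"),
    rx("t_pvhl_out", "constitutive pVHL consumption", from = "pvhl",
       kind = "output"),
    rx("t_0", "Hif transport into nucleus", from = "hif1a_cyt",
       to = "hif1a_nuc"),
    rx("t_2", "Hif transport out of nucleus", from = "hif1a_nuc",
       to = "hif1a_cyt"),
    ## pVHL-dependent, oxygen-dependent degradation (VCB/Cul2 route)
    rx("t_113", "activation by oxygen of ARD", from = "hif1a_cyt",
       to = "hif_ard", read = "oxygen"),
    rx("t_115", "acetylation and hydroxylation of Hif", from = "hif_ard",
       to = "hif_oh", read = "phd2"),
    rx("t_116", "interaction of VHL with Elongin B and C", from = "pvhl",
       to = "vcb", read = c("elob", "eloc")),
    rx("t_cul2_in", "Cul2 synthesis", to = "cul2", kind = "input"),
    rx("t_117", "interaction of complex Vcb with Cul2",
       from = c("vcb", "cul2"), to = "vcb_cul2"),
    rx("t_118", "interaction of complex Vcb with modified Hif",
       from = c("vcb_cul2", "hif_oh"), to = "hif_ub"),
    rx("t_119", "degradation VHL dependent of Hif", from = "hif_ub",
       kind = "output"),
    ## p53/Mdm2 route
    rx("t_192", "p53 synthesis", to = "p53", kind = "input"),
    rx("t_190", "Mdm2-dependent Hif-p53 association",
       from = c("hif1a_cyt", "p53"), to = "hif_p53", read = "mdm2"),
    rx("t_191", "degradation p53 dependent of Hif", from = "hif_p53",
       kind = "output"),
    ## GSK3beta route
    rx("t_193", "phosphorylation of Hif by GSK3b",
       from = c("hif1a_cyt", "atp"), to = c("hif_p", "adp"),
       read = "gsk3b"),
    rx("t_194", "degradation of phosphorylated Hif", from = "hif_p",
       kind = "output"),
    ## --- nuclear transcription at the HRE -----------------------------
    rx("t_hre", "HIF-ARNT heterodimer binds the HRE",
       from = c("hif1a_nuc", "arnt"), to = "hif_arnt"),
    rx("t_tx_vegf", "HRE transcription of VEGF", from = "hif_arnt",
       to = c("vegf", "arnt"), read = c("p300", "hre")),
    rx("t_tx_epo", "HRE transcription of EPO", from = "hif_arnt",
       to = c("epo", "arnt"), read = c("creb", "hre")),
    rx("t_tx_et", "HRE transcription of endothelin", from = "hif_arnt",
       to = c("et", "arnt"), read = c("cjun", "hre")),
    rx("t_tx_glut", "HRE transcription of GLUT1", from = "hif_arnt",
       to = c("glut1", "arnt"), read = "hre"),
    rx("t_tx_ldh", "HRE transcription of LDH-A", from = "hif_arnt",
       to = c("ldh", "arnt"), read = "hre"),
    rx("t_tx_pdk", "HRE transcription of PDK1", from = "hif_arnt",
       to = c("pdk", "arnt"), read = "hre"),
    rx("t_tx_mmp", "HRE transcription of MMPs", from = "hif_arnt",
       to = c("mmp", "arnt"), read = "hre"),
    rx("t_tx_nur", "HRE transcription of Nur77", from = "hif_arnt",
       to = c("nur77", "arnt"), read = "hre"),
    ## --- Sp1 ------------------------------------------------------------
    rx("t_167", "Sp1 phosphorylation", from = "sp1", to = "sp1_p"),
    rx("t_199", "Sp1 dephosphorylation", from = "sp1_p", to = "sp1"),
    rx("t_177", "VHL binding to Sp1", from = c("sp1", "pvhl"),
       to = "sp1_vhl"),
    rx("t_208", "Sp1-VHL complex dissociation", from = "sp1_vhl",
       to = c("sp1", "pvhl")),
    rx("t_sp1_tx", "Sp1-dependent VEGF transcription", to = "vegf",
       read = c("sp1", "hre")),
    ## --- HuR stabilisation of VEGF -------------------------------------
    rx("t_hur_bind", "Hur binds VEGF mRNA", from = c("vegf", "hur"),
       to = "vegf_hur"),
    rx("t_178", "Hur releases stabilized VEGF", from = "vegf_hur",
       to = c("vegf_stab", "hur")),
    rx("t_181", "Hur inhibition via VHL", from = "hur", to = "hur_seq",
       read = "pvhl"),
    rx("t_207", "Hur release", from = "hur_seq", to = "hur"),
    ## --- three VEGF signalling branches (each an alternative angiogenic
    ## cascade ending in improved oxygen supply) ---------------------------
    rx("t_13", "VEGF signal cascade, branch 3", from = "vegf_stab",
       to = "oxygen"),
    rx("t_14", "VEGF signal cascade, branch 2", from = "vegf_stab",
       to = "oxygen"),
    rx("t_15", "VEGF signal cascade, branch 1", from = "vegf_stab",
       to = "oxygen"),
    ## --- two EPO branches ------------------------------------------------
    rx("t_35", "EPO receptor activates Jak", from = "epo", to = "jak"),
    rx("t_36", "Jak/Stat5 erythropoietic oxygen supply", from = "jak",
       to = "oxygen"),
    rx("t_38", "EPO receptor recruits Shc-Grb-Sos", from = "epo",
       to = "shc"),
    rx("t_39", "Shc-Grb-Sos activates the MAPK cascade", from = "shc",
       to = "mapk"),
    rx("t_127", "EPO effects on oxygen production", from = "mapk",
       to = "oxygen"),
    ## --- endothelin ------------------------------------------------------
    rx("t_et", "endothelin secretion and vasomotor effects", from = "et",
       kind = "output"),
    ## --- Nur77 / POMC ----------------------------------------------------
    rx("t_nur_pomc", "Nur77 stimulates POMC transcription", from = "nur77",
       to = "pomc"),
    rx("t_pomc_out", "POMC-derived ACTH secretion", from = "pomc",
       kind = "output"),
    ## --- glucose uptake and glycolysis ----------------------------------
    rx("t_69", "glucose intake (eating)", to = "glucose", kind = "input"),
    rx("t_glut1", "GLUT1 glucose uptake", from = "glucose",
       to = "glucose_in", read = "glut1"),
    rx("t_glut1_out", "GLUT1 transporter turnover", from = "glut1",
       kind = "output"),
    rx("t_glut2", "GLUT2 glucose uptake", from = "glucose",
       to = "glucose_in", read = "glut2"),
    rx("t_glut4", "GLUT4 glucose uptake", from = "glucose",
       to = "glucose_in", read = "glut4"),
    rx("t_hex", "hexokinase phosphorylates glucose",
       from = c("glucose_in", "atp"), to = c("g6p", "adp")),
    rx("t_pfk", "phosphofructokinase commits G6P",
       from = c("g6p", "atp"), to = c("fbp", "adp")),
    rx("t_gap", "payoff-phase oxidation", from = c("fbp", "nad"),
       to = c("bpg", "nadh")),
    rx("t_pk", "pyruvate kinase", from = c("bpg", "adp"),
       to = c("pyruvate", "atp")),
    rx("t_216", "other pyruvate generating pathways", to = "pyruvate",
       kind = "input"),
    ## --- pyruvate fates ---------------------------------------------------
    rx("t_ldh", "lactate dehydrogenase", from = c("pyruvate", "nadh"),
       to = c("lactate", "nad"), read = "ldh"),
    rx("t_ldh_out", "LDH enzyme turnover", from = "ldh", kind = "output"),
    rx("t_lac_out", "lactic acid export", from = "lactate", kind = "output"),
    rx("t_pdh", "pyruvate dehydrogenase forms acetyl-CoA",
       from = c("pyruvate", "nad"), to = c("acoa", "nadh"),
       read = "pyrdh"),
    rx("t_82", "pyruvate dehydrogenase inactivation by PDK",
       from = c("pyrdh", "pdk"), to = "pyrdh_i"),
    rx("t_pdh_react", "pyruvate dehydrogenase reactivation",
       from = "pyrdh_i", to = "pyrdh"),
    rx("t_pc", "pyruvate carboxylase forms oxalacetate",
       from = c("pyruvate", "atp"), to = c("oaa", "adp")),
    rx("t_80", "oxalacetate drain to biosynthesis and PHD2 regulation",
       from = "oaa", kind = "output"),
    ## --- Krebs cycle ------------------------------------------------------
    rx("t_cs", "citrate synthase", from = c("acoa", "oaa"), to = "citrate"),
    rx("t_91", "citrate oxidation to succinate", from = c("citrate", "nad"),
       to = c("succinate", "nadh")),
    rx("t_92", "succinate dehydrogenase", from = c("succinate", "fad"),
       to = c("malate", "fadh2")),
    rx("t_93", "malate dehydrogenase regenerates oxalacetate",
       from = c("malate", "nad"), to = c("oaa", "nadh")),
    rx("t_q", "electron transfer from FADH2 to the quinone pool",
       from = c("fadh2", "nad"), to = c("fad", "nadh")),
    ## --- respiratory chain ------------------------------------------------
    rx("t_97", "ATP formation (respiratory-chain ATPase)",
       from = c("nadh", "oxygen", "adp"), to = c("nad", "atp", "h2o")),
    rx("t_224", "water output transition", from = "h2o", kind = "output"),
    ## --- glycogen ---------------------------------------------------------
    rx("t_glyc", "glycogen synthase stores G6P", from = "g6p",
       to = "glycogen", read = "gs_act"),
    rx("t_glyc_out", "glycogenolysis in the mobilization state",
       from = "glycogen", to = "glucose", read = "gs_i"),
    rx("t_99", "glycogen synthase inactivation by GSK3b", from = "gs_act",
       to = "gs_i", read = "gsk3b"),
    rx("t_100", "glycogen synthase reactivation", from = "gs_i",
       to = "gs_act"),
    ## --- GSK3beta and Pkb state cycles -----------------------------------
    rx("t_101", "Pkb activation", from = "pkb", to = "pkb_a"),
    rx("t_102", "Pkb deactivation", from = "pkb_a", to = "pkb"),
    rx("t_103", "GSK3b inactivating phosphorylation by Pkb",
       from = "gsk3b", to = "gsk3b_i", read = "pkb_a"),
    rx("t_132", "GSK3b reactivation", from = "gsk3b_i", to = "gsk3b"),
    ## --- Jade1 / beta-catenin / Wnt --------------------------------------
    rx("t_jade_in", "Jade1 synthesis", to = "jade1", kind = "input"),
    rx("t_jade_out", "Jade1 decay (short-lived)", from = "jade1",
       kind = "output"),
    rx("t_bcat_in", "beta-catenin synthesis", to = "bcat", kind = "input"),
    rx("t_prime", "GSK3b-APC-Axin priming phosphorylation", from = "bcat",
       to = "bcat_p", read = c("gsk3b", "apc_axin")),
    rx("t_jade_deg", "Jade1-dependent beta-catenin degradation",
       from = c("bcat_p", "jade1"), kind = "output"),
    rx("t_wnt", "Wnt proliferative signalling via beta-catenin",
       from = "bcat", to = "prolif", read = "wnt"),
    rx("t_prolif_out", "proliferative transcription programme",
       from = "prolif", kind = "output"),
    ## --- matrix: fibronectin vs MMPs -------------------------------------
    rx("t_fn_in", "fibronectin synthesis", to = "fibronectin",
       kind = "input"),
    rx("t_fn", "pVHL-dependent fibronectin matrix deposition",
       from = "fibronectin", to = "matrix", read = "pvhl"),
    rx("t_mmp_deg", "MMP matrix disaggregation", from = c("matrix", "mmp"),
       to = "mfrag"),
    rx("t_mfrag_out", "matrix fragment clearance", from = "mfrag",
       kind = "output"),
    ## --- aPKC-zeta-II tight junctions ------------------------------------
    rx("t_pkcz_in", "aPKCz2 synthesis", to = "pkcz2", kind = "input"),
    rx("t_pkcz_out", "aPKCz2 consumption", from = "pkcz2", kind = "output"),
    rx("t_tj", "ATP-dependent tight junction assembly via aPKCz2",
       from = c("pkcz2", "atp"), to = c("tj", "adp")),
    rx("t_tj_out", "tight junction turnover", from = "tj", kind = "output"),
    rx("t_174", "Par6 inactivation via aPKCz2", from = "par6",
       to = "par6_i", read = "pkcz2"),
    rx("t_222", "Par6 reactivation", from = "par6_i", to = "par6")
  )
}

## marking convention: 1 token on enzymes and side-condition places, 3 on the
## ATP and NAD pools, 2 on oxygen, 0 elsewhere
core_marking <- function() {
  c(atp = 3L, nad = 3L, oxygen = 2L,
    phd2 = 1L, elob = 1L, eloc = 1L, mdm2 = 1L, gsk3b = 1L, arnt = 1L,
    hre = 1L, p300 = 1L, creb = 1L, cjun = 1L, sp1 = 1L, hur = 1L,
    glut2 = 1L, glut4 = 1L, pyrdh = 1L, fad = 1L, gs_act = 1L, pkb = 1L,
    wnt = 1L, apc_axin = 1L, par6 = 1L)
}

core_pathway_tags <- function() {
  list(
    hif_degradation_pvhl = c("t_113", "t_115", "t_116", "t_117", "t_118",
                             "t_119"),
    hif_degradation_p53 = c("t_190", "t_191", "t_192"),
    hif_degradation_gsk3b = c("t_193", "t_194"),
    glycolysis = c("t_glut1", "t_glut2", "t_glut4", "t_hex", "t_pfk",
                   "t_gap", "t_pk"),
    krebs = c("t_pdh", "t_pc", "t_cs", "t_91", "t_92", "t_93"),
    respiratory_chain = c("t_97", "t_224", "t_q"),
    vegf_1 = "t_15",
    vegf_2 = "t_14",
    vegf_3 = "t_13",
    epo_jak = c("t_35", "t_36"),
    epo_shc = c("t_38", "t_39", "t_127"),
    endothelin = "t_et",
    sp1 = c("t_167", "t_199", "t_177", "t_208", "t_sp1_tx"),
    nur77 = c("t_tx_nur", "t_nur_pomc", "t_pomc_out"),
    jade1_wnt = c("t_jade_in", "t_jade_out", "t_bcat_in", "t_prime",
                  "t_jade_deg", "t_wnt", "t_prolif_out"),
    hur = c("t_hur_bind", "t_178", "t_181", "t_207"),
    mmp_matrix = c("t_tx_mmp", "t_fn_in", "t_fn", "t_mmp_deg",
                   "t_mfrag_out"),
    tight_junction = c("t_pkcz_in", "t_pkcz_out", "t_tj", "t_tj_out",
                       "t_174", "t_222")
  )
}

#' Build the reduced VHL core model
#'
#' Hand-encoded place/transition net of the main pVHL functional pathways
#' (see the package vignette for the full biological account): constitutive
#' HIF-1alpha/pVHL turnover; the oxygen/PHD2/VCB ubiquitination route and the
#' alternative p53- and GSK3beta-dependent HIF-1alpha degradation routes;
#' HRE transcription with its effector programmes; three VEGF and two EPO
#' signalling branches feeding back on oxygenation; Sp1 and HuR control of
#' VEGF; glucose uptake, glycolysis, pyruvate fates, Krebs cycle and
#' respiratory-chain ATP synthesis over shared ATP/ADP, NAD/NADH, FAD/FADH2
#' and oxygen pools; glycogen metabolism under GSK3beta control;
#' Jade1/beta-catenin/Wnt; matrix and tight-junction regulation. All arcs
#' have weight 1; enzymes and cofactors are attached by read (double) arcs.
#'
#' @return a list of class `vhl_core_model`: `net` (a flat [petri_net()]),
#'   `annotations` (id -> biological role), `pathway_tags` (pathway ->
#'   transition ids).
#' @export
build_core_model <- function() {
  rxs <- core_reactions()
  t_df <- data.frame(id = vapply(rxs, `[[`, "", "id"),
                     name = vapply(rxs, `[[`, "", "name"),
                     kind = vapply(rxs, `[[`, "", "kind"))
  arcs <- do.call(rbind, lapply(rxs, function(r) {
    rbind(
      if (length(r$from) > 0)
        data.frame(source = r$from, target = r$id, weight = 1L, read = FALSE),
      if (length(r$to) > 0)
        data.frame(source = r$id, target = r$to, weight = 1L, read = FALSE),
      if (length(r$read) > 0)
        rbind(data.frame(source = r$read, target = r$id, weight = 1L,
                         read = TRUE),
              data.frame(source = r$id, target = r$read, weight = 1L,
                         read = TRUE))
    )
  }))
  p_ids <- setdiff(unique(c(arcs$source, arcs$target)), t_df$id)
  m0 <- core_marking()
  p_df <- data.frame(id = p_ids, tokens = ifelse(p_ids %in% names(m0),
                                                 m0[p_ids], 0L))
  net <- petri_net(p_df, t_df, arcs, name = "vhl_core")
  ann <- stats::setNames(t_df$name, t_df$id)
  structure(list(net = net, annotations = ann,
                 pathway_tags = core_pathway_tags()),
            class = "vhl_core_model")
}

#' @export
print.vhl_core_model <- function(x, ...) {
  cat("<vhl_core_model>\n")
  print(x$net)
  cat("  pathway tags: ", length(x$pathway_tags), "\n", sep = "")
  invisible(x)
}

#' Load the full published network model from a file
#'
#' Reads a full-scale model file (Snoopy .spped dialect, PNML or tabular),
#' reports the raw structural counts of the stored net (including any macro
#' containers and logical copies, i.e. the designed model as drawn), flattens
#' it for analysis, and wraps it as a core-model object without annotations.
#'
#' @param path path to the model file.
#' @param format format tag passed to [read_net()].
#' @return a list of class `vhl_core_model` with an extra `raw_counts`
#'   element: places/transitions/arcs of the net as stored, plus
#'   `firable_transitions` (macro containers excluded).
#' @export
load_full_model <- function(path, format = "auto") {
  doc <- read_net(path, format = format)
  raw <- c(places = nrow(doc$net$places),
           transitions = nrow(doc$net$transitions),
           arcs = nrow(doc$net$arcs),
           firable_transitions = sum(doc$net$transitions$kind != "macro"))
  flat <- flatten(doc$net)
  structure(list(net = flat, annotations = stats::setNames(
    doc$net$transitions$name, doc$net$transitions$id),
    pathway_tags = list(), raw_counts = raw, metadata = doc$metadata),
    class = "vhl_core_model")
}

#' The named in-silico knockout experiments
#'
#' Eight loss-of-function scenarios on the core model, each with the
#' qualitative outcome expected from the biology: (i) pVHL loss leaves the
#' alternative HIF-1alpha degradation routes active; (ii) HIF-1alpha loss
#' alone keeps Sp1-driven VEGF (and thus oxygen supply) running, (iii) and
#' combined with Sp1 loss oxygen is consumed to exhaustion; (iv) HIF-1alpha +
#' pVHL double loss keeps metabolism running on Sp1-only transcription;
#' (v) PHD2 loss blocks hydroxylation while alternative degradation
#' continues; (vi) erasing the Mdm2 token silences the p53 degradation
#' route; (vii) loss of the respiratory ATPase makes oxygen accumulate and
#' ATP run out; (viii) GSK3beta loss locks glycogen synthase active so
#' glycogen piles up.
#'
#' @return a named list of experiments; each has `name`, `spec`
#'   (a [knockout_spec()]) and `expected`, a list with any of
#'   `dead`, `alive` (transition ids), `accumulating`, `depleted` (place
#'   ids).
#' @export
named_experiments <- function() {
  e <- list(
    pvhl = list(
      spec = knockout_spec(clamped_places = c(pvhl = 0L)),
      expected = list(
        dead = c("t_116", "t_117", "t_118", "t_119", "t_177", "t_208",
                 "t_181", "t_fn"),
        alive = c("t_190", "t_191", "t_193", "t_194", "t_sp1_tx", "t_wnt"))),
    hif1a = list(
      spec = knockout_spec(clamped_places = c(hif1a_cyt = 0L,
                                              hif1a_nuc = 0L)),
      expected = list(
        dead = c("t_0", "t_2", "t_113", "t_115", "t_118", "t_119",
                 "t_190", "t_193", "t_hre", "t_tx_vegf", "t_tx_ldh"),
        alive = c("t_sp1_tx", "t_13", "t_14", "t_15", "t_116", "t_97",
                  "t_glyc", "t_hex"))),
    hif1a_sp1 = list(
      spec = knockout_spec(clamped_places = c(hif1a_cyt = 0L,
                                              hif1a_nuc = 0L, sp1 = 0L)),
      expected = list(
        dead = c("t_sp1_tx", "t_167", "t_tx_vegf", "t_hur_bind",
                 "t_13", "t_14", "t_15", "t_35", "t_127"),
        alive = c("t_97", "t_hex"),
        depleted = "oxygen")),
    hif1a_pvhl = list(
      spec = knockout_spec(clamped_places = c(hif1a_cyt = 0L,
                                              hif1a_nuc = 0L, pvhl = 0L)),
      expected = list(
        dead = c("t_0", "t_116", "t_117", "t_118", "t_119", "t_190",
                 "t_193", "t_fn", "t_181", "t_hre"),
        alive = c("t_sp1_tx", "t_hex", "t_97", "t_13"))),
    phd2 = list(
      spec = knockout_spec(clamped_places = c(phd2 = 0L)),
      expected = list(
        dead = c("t_115", "t_118", "t_119"),
        alive = c("t_113", "t_190", "t_191", "t_193", "t_194"),
        accumulating = "hif_ard")),
    mcts1 = list(
      spec = knockout_spec(clamped_places = c(mdm2 = 0L)),
      expected = list(
        dead = c("t_190", "t_191"),
        alive = c("t_113", "t_115", "t_118", "t_119", "t_193"),
        accumulating = "p53")),
    t97 = list(
      spec = knockout_spec(removed_transitions = "t_97"),
      expected = list(
        dead = "t_224",
        alive = c("t_13", "t_113"),
        accumulating = "oxygen",
        depleted = "atp")),
    gsk3b = list(
      spec = knockout_spec(clamped_places = c(gsk3b = 0L)),
      expected = list(
        dead = c("t_99", "t_100", "t_103", "t_132", "t_193", "t_194",
                 "t_prime", "t_glyc_out"),
        alive = c("t_glyc", "t_wnt"),
        accumulating = "glycogen"))
  )
  for (nm in names(e)) e[[nm]]$name <- nm
  e
}

#' Check a knockout report against expected qualitative assertions
#'
#' @param report a [run_experiment()] report.
#' @param expected an `expected` element from [named_experiments()].
#' @return a data frame with one row per assertion (`type`, `id`, `ok`).
#' @export
check_experiment <- function(report, expected) {
  rows <- list()
  add <- function(type, ids, ok_fun) {
    for (id in ids) {
      rows[[length(rows) + 1]] <<- data.frame(type = type, id = id,
                                              ok = ok_fun(id))
    }
  }
  add("dead", expected$dead, function(id)
    id %in% report$dead_transitions ||
      id %in% report$spec$removed_transitions)
  add("alive", expected$alive, function(id)
    !(id %in% report$dead_transitions) && report$fired_counts[id] > 0)
  add("accumulating", expected$accumulating, function(id)
    id %in% report$accumulating_places)
  add("depleted", expected$depleted, function(id)
    id %in% report$depleted_places)
  do.call(rbind, rows)
}
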