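# Packaged reduced model of Arabidopsis thaliana central carbon and energy
# metabolism: source mesophyll (cytoplasm + plastid + mitochondrion),
# transport phloem, sink root (cytoplasm + mitochondrion), shared apoplast,
# environment, and a virtual vacuole receiving biomass deposits.
#
# Compartment suffixes: env apo phl mc mp mm rc rm vac.
# Every non-exchange transformer is elementally and charge balanced in exact
# rational arithmetic; construction fails otherwise.

# metabolite catalogue: formula string (Hill), charge
.MET <- list(
  h2o = c("H2O", "0"),     h = c("H", "1"),        o2 = c("O2", "0"),
  co2 = c("CO2", "0"),     hv = c("", "0"),        nh4 = c("H4N", "1"),
  no3 = c("NO3", "-1"),    no2 = c("NO2", "-1"),   so4 = c("O4S", "-2"),
  h2s = c("H2S", "0"),     pi = c("HO4P", "-2"),   ppi = c("HO7P2", "-3"),
  h2o2 = c("H2O2", "0"),
  glc = c("C6H12O6", "0"), fru = c("C6H12O6", "0"),
  sucr = c("C12H22O11", "0"), sucr2 = c("C12H22O11", "0"),
  malt = c("C12H22O11", "0"),
  suc6p = c("C12H21O14P", "-2"),
  g6p = c("C6H11O9P", "-2"), f6p = c("C6H11O9P", "-2"),
  g1p = c("C6H11O9P", "-2"), fbp = c("C6H10O12P2", "-4"),
  dhap = c("C3H5O6P", "-2"), gap = c("C3H5O6P", "-2"),
  bpg13 = c("C3H4O10P2", "-4"), pg3 = c("C3H4O7P", "-3"),
  pg2 = c("C3H4O7P", "-3"), pep = c("C3H2O6P", "-3"),
  pyr = c("C3H3O3", "-1"),
  ru5p = c("C5H9O8P", "-2"), xu5p = c("C5H9O8P", "-2"),
  r5p = c("C5H9O8P", "-2"), s7p = c("C7H13O10P", "-2"),
  sbp = c("C7H12O13P2", "-4"), e4p = c("C4H7O7P", "-2"),
  rubp = c("C5H8O11P2", "-4"), pgl6 = c("C6H9O9P", "-2"),
  pgc6 = c("C6H10O10P", "-3"),
  atp = c("C10H12N5O13P3", "-4"), adp = c("C10H12N5O10P2", "-3"),
  utp = c("C9H11N2O15P3", "-4"), udp = c("C9H11N2O12P2", "-3"),
  udpg = c("C15H22N2O17P2", "-2"), udpglcur = c("C15H19N2O18P2", "-3"),
  adpglc = c("C16H23N5O15P2", "-2"),
  nad = c("C21H26N7O14P2", "-1"), nadh = c("C21H27N7O14P2", "-2"),
  nadp = c("C21H25N7O17P3", "-3"), nadph = c("C21H26N7O17P3", "-4"),
  cit = c("C6H5O7", "-3"), icit = c("C6H5O7", "-3"),
  akg = c("C5H4O5", "-2"), succ = c("C4H4O4", "-2"),
  fum = c("C4H2O4", "-2"), mal = c("C4H4O5", "-2"),
  oaa = c("C4H2O5", "-2"),
  coa = c("C21H32N7O16P3S", "-4"), accoa = c("C23H34N7O17P3S", "-4"),
  succoa = c("C25H35N7O19P3S", "-5"),
  glu = c("C5H8NO4", "-1"), gln = c("C5H10N2O3", "0"),
  asp = c("C4H6NO4", "-1"), ala = c("C3H7NO2", "0"),
  gly = c("C2H5NO2", "0"), ser = c("C3H7NO3", "0"),
  cys = c("C3H7NO2S", "0"), val = c("C5H11NO2", "0"),
  glyclt = c("C2H3O3", "-1"), glx = c("C2HO3", "-1"),
  pglyc2 = c("C2H2O6P", "-3"), hpyr = c("C3H3O4", "-1"),
  glyc = c("C3H5O4", "-1"), glyc3p = c("C3H7O6P", "-2"),
  thf = c("C19H21N7O6", "-2"), mlthf = c("C20H21N7O6", "-2"),
  fdx_ox = c("", "0"), fdx_red = c("", "-1"),
  pq = c("C53H80O2", "0"), pqh2 = c("C53H82O2", "0"),
  pc_ox = c("", "1"), pc_red = c("", "0"),
  cytc_ox = c("", "1"), cytc_red = c("", "0"),
  q = c("C49H74O4", "0"), qh2 = c("C49H76O4", "0"),
  hdca = c("C16H31O2", "-1"), ocdca = c("C18H35O2", "-1"),
  hdcea = c("C16H29O2", "-1"), ocdcea = c("C18H33O2", "-1"),
  lnlc = c("C18H31O2", "-1"),
  starch = c("C6H10O5", "0"), cell_res = c("C6H10O5", "0"),
  pect_res = c("C6H8O6", "0"), h_lum = c("H", "1")
)

.pf_model_cache <- new.env(parent = emptyenv())

# solve exact coefficients for adjustment species so that a reaction
# balances; adjust ids are plain species ids (placed on either side).
.adjust_stoich <- function(id, stoich, adjust, formula_of) {
  coefs <- lapply(stoich, rq_parse)
  fl <- lapply(names(stoich), formula_of)
  s <- formula_weighted_sum(list(n = vapply(coefs, `[[`, 0, "n"),
                                 d = vapply(coefs, `[[`, 0, "d")), fl)
  if (!length(s$elements$n) && rq_is_zero(s$charge)) return(stoich)
  # delta formula per adjustment: plain species, or "a~b" coupled pair
  deltas <- lapply(adjust, function(a) {
    if (grepl("~", a, fixed = TRUE)) {
      pr <- strsplit(a, "~", fixed = TRUE)[[1]]
      d <- formula_weighted_sum(rq(c(1, -1)),
                                list(formula_of(pr[1]), formula_of(pr[2])))
      list(n = d$elements$n, d = d$elements$d, charge = d$charge)
    } else {
      f <- formula_of(a)
      list(n = f$n, d = f$d, charge = f$charge)
    }
  })
  rows <- unique(c(names(s$elements$n),
                   unlist(lapply(deltas, function(d) names(d$n)))))
  rows <- c(rows, "CHG")
  nc <- length(adjust)
  A_n <- matrix(0, length(rows), nc)
  A_d <- matrix(1, length(rows), nc)
  for (j in seq_len(nc)) {
    f <- deltas[[j]]
    for (k in seq_along(f$n)) {
      i <- match(names(f$n)[k], rows)
      A_n[i, j] <- f$n[k]; A_d[i, j] <- f$d[k]
    }
    A_n[length(rows), j] <- f$charge$n; A_d[length(rows), j] <- f$charge$d
  }
  b_n <- numeric(length(rows)); b_d <- rep(1, length(rows))
  for (k in seq_along(s$elements$n)) {
    i <- match(names(s$elements$n)[k], rows)
    b_n[i] <- -s$elements$n[k]; b_d[i] <- s$elements$d[k]
  }
  b_n[length(rows)] <- -s$charge$n; b_d[length(rows)] <- s$charge$d
  aug <- rq_rref(list(n = cbind(A_n, b_n), d = cbind(A_d, b_d)))
  if ((nc + 1L) %in% aug$pivots)
    stop(sprintf("transformer '%s': residual {%s charge=%s} not balanceable by {%s}",
                 id,
                 paste(sprintf("%s=%s", names(s$elements$n),
                               rq_format(s$elements)), collapse = ","),
                 rq_format(s$charge),
                 paste(adjust, collapse = ",")), call. = FALSE)
  x_n <- numeric(nc); x_d <- rep(1, nc)
  for (r in seq_along(aug$pivots)) {
    p <- aug$pivots[r]
    x_n[p] <- aug$mat$n[r, nc + 1L]
    x_d[p] <- aug$mat$d[r, nc + 1L]
  }
  apply_term <- function(stoich, id2, v) {
    cur <- if (id2 %in% names(stoich))
      rq_add(rq_parse(stoich[[id2]]), v) else v
    stoich[id2] <- rq_format(cur)
    if (cur$n == 0) stoich <- stoich[names(stoich) != id2]
    stoich
  }
  for (j in seq_len(nc)) {
    if (x_n[j] == 0) next
    v <- rq_scalar(x_n[j], x_d[j])
    if (grepl("~", adjust[j], fixed = TRUE)) {
      pr <- strsplit(adjust[j], "~", fixed = TRUE)[[1]]
      stoich <- apply_term(stoich, pr[1], v)
      stoich <- apply_term(stoich, pr[2], rq_neg(v))
    } else {
      stoich <- apply_term(stoich, adjust[j], v)
    }
  }
  stoich
}

#' Build the packaged reduced plant model
#'
#' Deterministically constructs the multi-compartment stoichiometric network
#' (photosynthetic light reactions with linear and NDH-type cyclic electron
#' flow, Calvin-Benson cycle, photorespiration, starch and sucrose
#' metabolism, glycolysis, pentose-phosphate pathways, TCA cycle and
#' oxidative phosphorylation in both mitochondria, nitrate/sulphate
#' assimilation, lumped biosynthesis of biomass monomers, metabolite
#' shuttles and translocators, proton-coupled sucrose translocation, and
#' per-tissue growth reactions).  All named fluxes used by the scenario
#' presets (`RPC_plastide`, `FQR`, `FNR`, `T.ATP.plastid`, ...) exist
#' verbatim.  Construction asserts elemental/charge balance of every
#' non-exchange transformer.
#'
#' @param biomass optional `biomass_spec` (default [compose_biomass()]).
#' @return a `pf_network`.
#' @export
build_model <- function(biomass = NULL) {
  cache_key <- if (is.null(biomass)) "default" else NULL
  if (!is.null(cache_key) && !is.null(.pf_model_cache[[cache_key]]))
    return(.pf_model_cache[[cache_key]])
  bs <- if (is.null(biomass)) compose_biomass() else biomass

  comps <- list(
    compartment("env", "environment", "environment", ph_rank = 1L),
    compartment("apo", "apoplast", "apoplast", ph_rank = 1L),
    compartment("phl", "phloem", "phloem", parent = "apo", ph_rank = 3L),
    compartment("mc", "mesophyll cytoplasm", "cytoplasm", parent = "apo",
                ph_rank = 3L),
    compartment("mp", "mesophyll plastid", "plastid", parent = "mc",
                ph_rank = 4L),
    compartment("mm", "mesophyll mitochondrion", "mitochondrion",
                parent = "mc", ph_rank = 4L),
    compartment("rc", "root cytoplasm", "cytoplasm", parent = "apo",
                ph_rank = 3L),
    compartment("rm", "root mitochondrion", "mitochondrion", parent = "rc",
                ph_rank = 4L),
    compartment("vac", "virtual vacuole", "vacuole_virtual", ph_rank = 2L))

  rxn <- list()
  add <- function(id, eq, kind = "reaction", ec = NA, genes = character(0),
                  path = NA, adjust = NULL) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, eq = eq, kind = kind, ec = ec,
                                     genes = genes, path = path,
                                     adjust = adjust)
  }

  # ---- mesophyll plastid: light reactions --------------------------------
  add("PSII", "2 h2o_mp + 2 pq_mp + 4 hv_mp + 4 h_mp -> o2_mp + 2 pqh2_mp + 4 h_lum_mp",
      ec = "1.10.3.9", genes = c("AT1G67740", "AT3G50820"),
      path = "photosynthesis light reactions")
  add("B6F", "pqh2_mp + 2 pc_ox_mp -> pq_mp + 2 pc_red_mp + 2 h_lum_mp",
      ec = "7.1.1.6", path = "photosynthesis light reactions")
  add("PSI", "2 pc_red_mp + 2 fdx_ox_mp + 2 hv_mp -> 2 pc_ox_mp + 2 fdx_red_mp",
      path = "photosynthesis light reactions")
  add("FNR", "2 fdx_red_mp + nadp_mp + h_mp <-> 2 fdx_ox_mp + nadph_mp",
      ec = "1.18.1.2", genes = "AT5G66190",
      path = "photosynthesis light reactions")
  # NDH-type cyclic flow: pumps 2 H+ per electron at the complex; together
  # with cytochrome b6f this yields 4 lumenal H+ per electron pair.
  add("FQR", "2 fdx_red_mp + pq_mp + 6 h_mp -> 2 fdx_ox_mp + pqh2_mp + 4 h_lum_mp",
      genes = "AT4G37925", path = "photosynthesis light reactions")
  add("ATPS_mp", "adp_mp + pi_mp + 4 h_lum_mp -> atp_mp + h2o_mp + 3 h_mp",
      ec = "7.1.2.2", path = "photosynthesis light reactions")
  # ---- Calvin-Benson cycle ----------------------------------------------
  add("RPC_plastide", "rubp_mp + co2_mp + h2o_mp -> 2 pg3_mp + 2 h_mp",
      ec = "4.1.1.39", genes = c("ATCG00490", "AT1G67090"),
      path = "Calvin-Benson cycle")
  add("RPC2_plastide", "rubp_mp + o2_mp -> pg3_mp + pglyc2_mp + 2 h_mp",
      ec = "4.1.1.39", path = "photorespiration")
  add("PGK_mp", "pg3_mp + atp_mp <-> bpg13_mp + adp_mp", ec = "2.7.2.3",
      path = "Calvin-Benson cycle")
  add("GAPDH_mp", "bpg13_mp + nadph_mp + h_mp <-> gap_mp + nadp_mp + pi_mp",
      ec = "1.2.1.13", path = "Calvin-Benson cycle")
  add("TPI_mp", "gap_mp <-> dhap_mp", ec = "5.3.1.1",
      path = "Calvin-Benson cycle")
  add("FBA_mp", "dhap_mp + gap_mp <-> fbp_mp", ec = "4.1.2.13",
      path = "Calvin-Benson cycle")
  add("FBP_mp", "fbp_mp + h2o_mp -> f6p_mp + pi_mp", ec = "3.1.3.11",
      path = "Calvin-Benson cycle")
  add("TKT1_mp", "f6p_mp + gap_mp <-> xu5p_mp + e4p_mp", ec = "2.2.1.1",
      path = "Calvin-Benson cycle")
  add("FBA2_mp", "e4p_mp + dhap_mp <-> sbp_mp", ec = "4.1.2.13",
      path = "Calvin-Benson cycle")
  add("SBP_mp", "sbp_mp + h2o_mp -> s7p_mp + pi_mp", ec = "3.1.3.37",
      path = "Calvin-Benson cycle")
  add("TKT2_mp", "s7p_mp + gap_mp <-> xu5p_mp + r5p_mp", ec = "2.2.1.1",
      path = "Calvin-Benson cycle")
  add("TALA_mp", "s7p_mp + gap_mp <-> e4p_mp + f6p_mp", ec = "2.2.1.2",
      path = "pentose-phosphate pathway")
  add("RPI_mp", "r5p_mp <-> ru5p_mp", ec = "5.3.1.6",
      path = "pentose-phosphate pathway")
  add("RPE_mp", "xu5p_mp <-> ru5p_mp", ec = "5.1.3.1",
      path = "pentose-phosphate pathway")
  add("PRK", "ru5p_mp + atp_mp -> rubp_mp + adp_mp + h_mp", ec = "2.7.1.19",
      path = "Calvin-Benson cycle")
  add("PGI_mp", "g6p_mp <-> f6p_mp", ec = "5.3.1.9",
      path = "Calvin-Benson cycle")
  # oxidative PPP (dark NADPH source in the plastid)
  add("G6PDH_mp", "g6p_mp + nadp_mp -> pgl6_mp + nadph_mp + h_mp",
      ec = "1.1.1.49", path = "pentose-phosphate pathway")
  add("PGL_mp", "pgl6_mp + h2o_mp -> pgc6_mp + h_mp", ec = "3.1.1.31",
      path = "pentose-phosphate pathway")
  add("GND_mp", "pgc6_mp + nadp_mp -> ru5p_mp + co2_mp + nadph_mp",
      ec = "1.1.1.44", path = "pentose-phosphate pathway")
  # starch
  add("PGM3_plastid", "g6p_mp <-> g1p_mp", ec = "5.4.2.2",
      genes = "AT5G51820", path = "starch biosynthesis")
  add("AGP_mp", "g1p_mp + atp_mp + h_mp -> adpglc_mp + ppi_mp",
      ec = "2.7.7.27", genes = "AT5G48300", path = "starch biosynthesis")
  add("PPA_mp", "ppi_mp + h2o_mp -> 2 pi_mp + h_mp", ec = "3.6.1.1",
      path = "phosphorus metabolism")
  add("SS_mp", "adpglc_mp -> starch_mp + adp_mp + h_mp",
      kind = "polymerization", ec = "2.4.1.21", path = "starch biosynthesis")
  add("SK", "2 starch_mp + h2o_mp -> malt_mp", ec = "2.4.1.1",
      genes = "AT1G10760", path = "starch degradation")
  # photorespiration (plastid part)
  add("PGP_mp", "pglyc2_mp + h2o_mp -> glyclt_mp + pi_mp", ec = "3.1.3.18",
      path = "photorespiration")
  add("GLYK", "glyc_mp + atp_mp -> pg3_mp + adp_mp + h_mp", ec = "2.7.1.31",
      genes = "AT1G80380", path = "photorespiration")
  # nitrogen / sulphur assimilation (plastid)
  add("NIR_mp", "no2_mp + 6 fdx_red_mp + 8 h_mp -> nh4_mp + 2 h2o_mp + 6 fdx_ox_mp",
      ec = "1.7.7.1", genes = "AT2G15620", path = "nitrate reduction")
  add("GS_mp", "glu_mp + nh4_mp + atp_mp -> gln_mp + adp_mp + pi_mp + h_mp",
      ec = "6.3.1.2", path = "glutamine biosynthesis")
  add("GOGAT_mp", "gln_mp + akg_mp + 2 fdx_red_mp + 2 h_mp -> 2 glu_mp + 2 fdx_ox_mp",
      ec = "1.4.7.1", path = "glutamine biosynthesis")
  add("SIR_mp", "so4_mp + atp_mp + 8 fdx_red_mp -> h2s_mp + adp_mp + pi_mp + 8 fdx_ox_mp",
      ec = "1.8.7.1", path = "sulphate reduction",
      adjust = c("h2o_mp", "h_mp"))
  # malate/oxaloacetate shuttle (plastid side; light-activated, export only)
  add("MDHN_mp", "oaa_mp + nadph_mp + h_mp -> mal_mp + nadp_mp",
      ec = "1.1.1.82", path = "malate/oxaloacetate shuttle")
  # plastid transports
  add("TPT", "gap_mp + pi_mc <-> gap_mc + pi_mp", kind = "transport",
      genes = "AT5G46110", path = "translocators")
  # nucleotide translocator with Pi counter-transport (net phosphate neutral)
  add("T.ATP.plastid", "atp_mc + adp_mp + pi_mp -> atp_mp + adp_mc + pi_mc",
      kind = "transport", path = "translocators")
  add("T.ADP.plastid", "atp_mp + adp_mc + pi_mc -> atp_mc + adp_mp + pi_mp",
      kind = "transport", path = "translocators")
  add("T.DIC.mp", "mal_mp + oaa_mc -> mal_mc + oaa_mp", kind = "transport",
      path = "malate/oxaloacetate shuttle")
  add("T.co2.mp", "co2_mc <-> co2_mp", kind = "transport", path = "gas")
  add("T.o2.mp", "o2_mc <-> o2_mp", kind = "transport", path = "gas")
  add("T.h2o.mp", "h2o_mc <-> h2o_mp", kind = "transport", path = "water")
  add("T.h.mp", "h_mc <-> h_mp", kind = "transport", path = "proton")
  add("T.no2.mp", "no2_mc -> no2_mp", kind = "transport",
      path = "nitrate reduction")
  add("T.nh4.mp", "nh4_mc -> nh4_mp", kind = "transport",
      path = "photorespiration")
  add("T.so4.mp", "so4_mc -> so4_mp", kind = "transport",
      path = "sulphate reduction")
  add("T.h2s.mp", "h2s_mp -> h2s_mc", kind = "transport",
      path = "sulphate reduction")
  add("T.glu.mp", "glu_mp -> glu_mc", kind = "transport",
      path = "translocators")
  add("T.gln.mp", "gln_mp -> gln_mc", kind = "transport",
      path = "translocators")
  add("T.akg.mp", "akg_mc -> akg_mp", kind = "transport",
      path = "translocators")
  add("T.glyclt.mp", "glyclt_mp -> glyclt_mc", kind = "transport",
      path = "photorespiration")
  add("T.glyc.mp", "glyc_mc -> glyc_mp", kind = "transport",
      path = "photorespiration")
  add("T.malt.mp", "malt_mp -> malt_mc", kind = "transport",
      path = "starch degradation")

  # ---- mesophyll-only cytosol: photorespiration + nitrate reduction ------
  add("GOX_mc", "glyclt_mc + o2_mc -> glx_mc + h2o2_mc", ec = "1.1.3.15",
      path = "photorespiration")
  add("CAT_mc", "2 h2o2_mc -> 2 h2o_mc + o2_mc", ec = "1.11.1.6",
      path = "photorespiration")
  add("GGT_mc", "glx_mc + glu_mc -> gly_mc + akg_mc", ec = "2.6.1.4",
      path = "photorespiration")
  add("GDC", "gly_mc + thf_mc + nad_mc -> mlthf_mc + co2_mc + nh4_mc + nadh_mc",
      ec = "1.4.4.2", genes = c("AT4G33010", "AT2G26080"),
      path = "photorespiration")
  add("SGAT_mc", "ser_mc + glx_mc -> hpyr_mc + gly_mc", ec = "2.6.1.45",
      path = "photorespiration")
  add("HPR_mc", "hpyr_mc + nadh_mc + h_mc -> glyc_mc + nad_mc",
      ec = "1.1.1.29", path = "photorespiration")
  add("NR_mc", "no3_mc + nadh_mc + h_mc -> no2_mc + nad_mc + h2o_mc",
      ec = "1.7.1.1", genes = "AT1G77760", path = "nitrate reduction")
  # sucrose biosynthesis (source tissue)
  add("SPS_mc", "udpg_mc + f6p_mc -> suc6p_mc + udp_mc + h_mc",
      ec = "2.4.1.14", genes = "AT5G20280", path = "sucrose biosynthesis")
  add("SPP_mc", "suc6p_mc + h2o_mc -> sucr_mc + pi_mc", ec = "3.1.3.24",
      path = "sucrose biosynthesis")
  add("FBPase_mc", "fbp_mc + h2o_mc -> f6p_mc + pi_mc", ec = "3.1.3.11",
      path = "sucrose biosynthesis")
  add("MALT_mc", "malt_mc + h2o_mc -> 2 glc_mc", ec = "3.2.1.20",
      path = "starch degradation")
  add("ME_mc", "mal_mc + nadp_mc -> pyr_mc + co2_mc + nadph_mc",
      ec = "1.1.1.40", path = "malate/oxaloacetate shuttle")

  # root-only cytosol: oxidative PPP, N/S assimilation, sucrose use --------
  add("G6PDH_rc", "g6p_rc + nadp_rc -> pgl6_rc + nadph_rc + h_rc",
      ec = "1.1.1.49", path = "pentose-phosphate pathway")
  add("PGL_rc", "pgl6_rc + h2o_rc -> pgc6_rc + h_rc", ec = "3.1.1.31",
      path = "pentose-phosphate pathway")
  add("GND_rc", "pgc6_rc + nadp_rc -> ru5p_rc + co2_rc + nadph_rc",
      ec = "1.1.1.44", path = "pentose-phosphate pathway")
  add("NR_rc", "no3_rc + nadh_rc + h_rc -> no2_rc + nad_rc + h2o_rc",
      ec = "1.7.1.1", path = "nitrate reduction")
  add("NIR_rc", "no2_rc + 3 nadph_rc + 5 h_rc -> nh4_rc + 3 nadp_rc + 2 h2o_rc",
      ec = "1.7.1.4", path = "nitrate reduction")
  add("SIR_rc", "so4_rc + atp_rc + 4 nadph_rc -> h2s_rc + adp_rc + pi_rc + 4 nadp_rc",
      ec = "1.8.1.2", path = "sulphate reduction",
      adjust = c("h2o_rc", "h_rc"))
  add("GDH_rc", "akg_rc + nh4_rc + nadh_rc + h_rc -> glu_rc + h2o_rc + nad_rc",
      ec = "1.4.1.2", path = "glutamine biosynthesis")
  add("GS_rc", "glu_rc + nh4_rc + atp_rc -> gln_rc + adp_rc + pi_rc + h_rc",
      ec = "6.3.1.2", path = "glutamine biosynthesis")
  add("SUSY_rc", "sucr_rc + udp_rc + h_rc -> udpg_rc + fru_rc",
      ec = "2.4.1.13", genes = "AT5G20830", path = "sucrose degradation")

  # ---- per-tissue cytosol template ---------------------------------------
  for (tis in c("m", "r")) {
    c_ <- paste0(tis, "c")   # cytosol suffix
    S <- function(x) gsub("\\{c\\}", c_, x)
    A <- function(id, eq, ...) add(paste0(id, "_", c_), S(eq), ...)
    A("GLK", "glc_{c} + atp_{c} -> g6p_{c} + adp_{c} + h_{c}",
      ec = "2.7.1.2", path = "glycolysis")
    A("FRK", "fru_{c} + atp_{c} -> f6p_{c} + adp_{c} + h_{c}",
      ec = "2.7.1.4", path = "glycolysis")
    A("PGI", "g6p_{c} <-> f6p_{c}", ec = "5.3.1.9", path = "glycolysis")
    A("PGM1", "g6p_{c} <-> g1p_{c}", ec = "5.4.2.2",
      path = "UDP-glucose biosynthesis")
    A("PFK", "f6p_{c} + atp_{c} -> fbp_{c} + adp_{c} + h_{c}",
      ec = "2.7.1.11", path = "glycolysis")
    A("FBA", "fbp_{c} <-> dhap_{c} + gap_{c}", ec = "4.1.2.13",
      path = "glycolysis")
    A("TPI", "dhap_{c} <-> gap_{c}", ec = "5.3.1.1", path = "glycolysis")
    A("GAPDH", "gap_{c} + nad_{c} + pi_{c} <-> bpg13_{c} + nadh_{c} + h_{c}",
      ec = "1.2.1.12", path = "glycolysis")
    A("PGK", "bpg13_{c} + adp_{c} <-> pg3_{c} + atp_{c}", ec = "2.7.2.3",
      path = "glycolysis")
    A("GPM", "pg3_{c} <-> pg2_{c}", ec = "5.4.2.11", path = "glycolysis")
    A("ENO", "pg2_{c} <-> pep_{c} + h2o_{c}", ec = "4.2.1.11",
      path = "glycolysis")
    A("PYK", "pep_{c} + adp_{c} + h_{c} -> pyr_{c} + atp_{c}",
      ec = "2.7.1.40", path = "glycolysis")
    A("PEPC", "pep_{c} + co2_{c} + h2o_{c} -> oaa_{c} + pi_{c} + h_{c}",
      ec = "4.1.1.31", path = "anaplerosis")
    A("MDH", "mal_{c} + nad_{c} <-> oaa_{c} + nadh_{c} + h_{c}",
      ec = "1.1.1.37", path = "malate/oxaloacetate shuttle")
    A("FUM2", "fum_{c} + h2o_{c} <-> mal_{c}", ec = "4.2.1.2",
      path = "anaplerosis")
    # anaplerotic 2-oxoglutarate to succinate conversion (GABA-shunt lump)
    A("AKGSS", "akg_{c} + nad_{c} + h2o_{c} -> succ_{c} + co2_{c} + nadh_{c} + h_{c}",
      ec = "1.2.1.24", path = "anaplerosis")
    A("NDPK", "atp_{c} + udp_{c} <-> adp_{c} + utp_{c}", ec = "2.7.4.6",
      path = "phosphorus metabolism")
    A("PPA", "ppi_{c} + h2o_{c} -> 2 pi_{c} + h_{c}", ec = "3.6.1.1",
      path = "phosphorus metabolism")
    A("INV", "sucr_{c} + h2o_{c} -> glc_{c} + fru_{c}", ec = "3.2.1.26",
      path = "sucrose degradation")
    A("ACL", "cit_{c} + atp_{c} + coa_{c} -> accoa_{c} + oaa_{c} + adp_{c} + pi_{c}",
      ec = "2.3.3.8", path = "fatty acids biosynthesis")
    A("ALT", "pyr_{c} + glu_{c} <-> ala_{c} + akg_{c}", ec = "2.6.1.2",
      path = "amino acids biosynthesis")
    A("AST", "oaa_{c} + glu_{c} <-> asp_{c} + akg_{c}", ec = "2.6.1.1",
      path = "amino acids biosynthesis")
    A("SERS", "pg3_{c} + glu_{c} + h2o_{c} + nad_{c} -> ser_{c} + akg_{c} + pi_{c} + nadh_{c} + h_{c}",
      ec = "1.1.1.95", path = "amino acids biosynthesis")
    A("SHMT", "ser_{c} + thf_{c} <-> gly_{c} + mlthf_{c} + h2o_{c}",
      ec = "2.1.2.1", path = "folate metabolism")
    A("C1OX", "mlthf_{c} + 2 h2o_{c} + nad_{c} + nadp_{c} -> thf_{c} + co2_{c} + nadh_{c} + nadph_{c} + 2 h_{c}",
      ec = "1.5.1.15", path = "folate metabolism")
    A("CYSS", "ser_{c} + h2s_{c} -> cys_{c} + h2o_{c}", ec = "2.5.1.47",
      path = "amino acids biosynthesis")
    A("VALS", "2 pyr_{c} + 2 h_{c} + nadph_{c} + glu_{c} -> val_{c} + akg_{c} + co2_{c} + h2o_{c} + nadp_{c}",
      ec = "2.6.1.42", path = "amino acids biosynthesis")
    A("G3PD", "dhap_{c} + nadh_{c} + h_{c} -> glyc3p_{c} + nad_{c}",
      ec = "1.1.1.8", path = "fatty acids biosynthesis")
    A("UGP", "g1p_{c} + utp_{c} + h_{c} -> udpg_{c} + ppi_{c}",
      ec = "2.7.7.9", path = "UDP-glucose biosynthesis")
    A("UDPGD", "udpg_{c} + 2 nad_{c} + h2o_{c} -> udpglcur_{c} + 2 nadh_{c} + 3 h_{c}",
      ec = "1.1.1.22", path = "UDP-glucoronate biosynthesis")
    A("CESA", "udpg_{c} -> cell_res_{c} + udp_{c} + h_{c}",
      kind = "polymerization", ec = "2.4.1.12",
      path = "cell wall biosynthesis")
    A("GAUT", "udpglcur_{c} -> pect_res_{c} + udp_{c}",
      kind = "polymerization", ec = "2.4.1.43",
      path = "cell wall biosynthesis")
    A("ATPM", "atp_{c} + h2o_{c} -> adp_{c} + pi_{c} + h_{c}",
      path = "maintenance")
    # non-oxidative PPP
    A("RPI", "r5p_{c} <-> ru5p_{c}", ec = "5.3.1.6",
      path = "pentose-phosphate pathway")
    A("RPE", "xu5p_{c} <-> ru5p_{c}", ec = "5.1.3.1",
      path = "pentose-phosphate pathway")
    A("TKT1", "xu5p_{c} + r5p_{c} <-> s7p_{c} + gap_{c}", ec = "2.2.1.1",
      path = "pentose-phosphate pathway")
    A("TALA", "s7p_{c} + gap_{c} <-> e4p_{c} + f6p_{c}", ec = "2.2.1.2",
      path = "pentose-phosphate pathway")
    A("TKT2", "xu5p_{c} + e4p_{c} <-> f6p_{c} + gap_{c}", ec = "2.2.1.1",
      path = "pentose-phosphate pathway")
    # fatty acid synthesis (lumped, cytosolic by model assumption)
    A("FAS160", "8 accoa_{c} + 7 atp_{c} + 14 nadph_{c} -> hdca_{c} + 8 coa_{c} + 7 adp_{c} + 7 pi_{c} + 14 nadp_{c}",
      ec = "2.3.1.85", path = "fatty acids biosynthesis",
      adjust = S(c("h2o_{c}", "h_{c}")))
    A("FAS180", "9 accoa_{c} + 8 atp_{c} + 16 nadph_{c} -> ocdca_{c} + 9 coa_{c} + 8 adp_{c} + 8 pi_{c} + 16 nadp_{c}",
      ec = "2.3.1.86", path = "fatty acids biosynthesis",
      adjust = S(c("h2o_{c}", "h_{c}")))
    A("FAS161", "8 accoa_{c} + 7 atp_{c} + 13 nadph_{c} -> hdcea_{c} + 8 coa_{c} + 7 adp_{c} + 7 pi_{c} + 13 nadp_{c}",
      path = "fatty acids biosynthesis", adjust = S(c("h2o_{c}", "h_{c}")))
    A("FAS181", "9 accoa_{c} + 8 atp_{c} + 15 nadph_{c} -> ocdcea_{c} + 9 coa_{c} + 8 adp_{c} + 8 pi_{c} + 15 nadp_{c}",
      path = "fatty acids biosynthesis", adjust = S(c("h2o_{c}", "h_{c}")))
    A("FAS182", "9 accoa_{c} + 8 atp_{c} + 14 nadph_{c} -> lnlc_{c} + 9 coa_{c} + 8 adp_{c} + 8 pi_{c} + 14 nadp_{c}",
      path = "fatty acids biosynthesis", adjust = S(c("h2o_{c}", "h_{c}")))
  }

  # ---- mitochondrion template --------------------------------------------
  for (tis in c("m", "r")) {
    m_ <- paste0(tis, "m"); c_ <- paste0(tis, "c")
    S <- function(x) gsub("\\{m\\}", m_, gsub("\\{c\\}", c_, x))
    A <- function(id, eq, ...) add(paste0(id, "_", m_), S(eq), ...)
    A("PDH", "pyr_{m} + coa_{m} + nad_{m} -> accoa_{m} + co2_{m} + nadh_{m}",
      ec = "1.2.4.1", path = "pyruvate decarboxylation to acetyl-CoA")
    A("CS", "accoa_{m} + oaa_{m} + h2o_{m} -> cit_{m} + coa_{m} + h_{m}",
      ec = "2.3.3.1", path = "TCA cycle")
    A("ACO", "cit_{m} <-> icit_{m}", ec = "4.2.1.3", path = "TCA cycle")
    A("ICDH", "icit_{m} + nad_{m} -> akg_{m} + co2_{m} + nadh_{m}",
      ec = "1.1.1.41", path = "TCA cycle")
    A("OGDH", "akg_{m} + coa_{m} + nad_{m} -> succoa_{m} + co2_{m} + nadh_{m}",
      ec = "1.2.4.2", path = "2-oxoglutarate decarboxylation to succinyl-CoA")
    A("SCS", "succoa_{m} + adp_{m} + pi_{m} -> succ_{m} + coa_{m} + atp_{m}",
      ec = "6.2.1.5", path = "TCA cycle")
    A("SDH", "succ_{m} + q_{m} -> fum_{m} + qh2_{m}", ec = "1.3.5.1",
      path = "TCA cycle")
    A("FUM", "fum_{m} + h2o_{m} <-> mal_{m}", ec = "4.2.1.2",
      path = "TCA cycle")
    A("MDH", "mal_{m} + nad_{m} <-> oaa_{m} + nadh_{m} + h_{m}",
      ec = "1.1.1.37", path = "TCA cycle")
    A("CI", "nadh_{m} + 5 h_{m} + q_{m} -> nad_{m} + qh2_{m} + 4 h_{c}",
      kind = "transport", ec = "7.1.1.2", path = "oxidative phosphorylation")
    A("CIII", "qh2_{m} + 2 cytc_ox_{m} + 2 h_{m} -> q_{m} + 2 cytc_red_{m} + 4 h_{c}",
      kind = "transport", ec = "7.1.1.8", path = "oxidative phosphorylation")
    A("CIV", "2 cytc_red_{m} + 1/2 o2_{m} + 4 h_{m} -> 2 cytc_ox_{m} + h2o_{m} + 2 h_{c}",
      kind = "transport", ec = "7.1.1.9", path = "oxidative phosphorylation")
    A("ATPS", "adp_{m} + pi_{m} + 4 h_{c} -> atp_{m} + h2o_{m} + 3 h_{m}",
      kind = "transport", ec = "7.1.2.2", path = "oxidative phosphorylation")
    A("ANT", "atp_{m} + adp_{c} -> atp_{c} + adp_{m}", kind = "transport",
      path = "translocators")
    A("PIC", "pi_{c} + h_{c} -> pi_{m} + h_{m}", kind = "transport",
      path = "translocators")
    A("PYRT", "pyr_{c} + h_{c} -> pyr_{m} + h_{m}", kind = "transport",
      path = "translocators")
    A("T.mal", "mal_{c} <-> mal_{m}", kind = "transport",
      path = "malate/oxaloacetate shuttle")
    A("T.oaa", "oaa_{m} <-> oaa_{c}", kind = "transport",
      path = "malate/oxaloacetate shuttle")
    A("T.cit", "cit_{m} <-> cit_{c}", kind = "transport",
      path = "translocators")
    A("T.akg", "akg_{m} <-> akg_{c}", kind = "transport",
      path = "translocators")
    A("T.succ", "succ_{c} <-> succ_{m}", kind = "transport",
      path = "translocators")
    A("T.fum", "fum_{c} <-> fum_{m}", kind = "transport",
      path = "translocators")
    A("T.o2", "o2_{c} <-> o2_{m}", kind = "transport", path = "gas")
    A("T.co2", "co2_{m} <-> co2_{c}", kind = "transport", path = "gas")
    A("T.h2o", "h2o_{m} <-> h2o_{c}", kind = "transport", path = "water")
  }

  # ---- sucrose translocation, nutrients, environment ---------------------
  add("SWEET.mes", "sucr_mc -> sucr_apo", kind = "transport",
      genes = c("AT3G48740", "AT5G23660"), path = "sucrose transport")
  add("SUC.phloem", "sucr_apo + h_apo -> sucr_phl + h_phl",
      kind = "transport", genes = "AT1G22710", path = "sucrose transport")
  # unloading happens in the root's own apoplastic zone (sucr2), spatially
  # distinct from the loading zone even though the model keeps a single
  # apoplast compartment: translocation must transit the phloem
  add("SWEET.phloem", "sucr_phl -> sucr2_apo", kind = "transport",
      path = "sucrose transport")
  add("SUC.root", "sucr2_apo + h_apo -> sucr_rc + h_rc", kind = "transport",
      genes = c("AT1G71880", "AT3G19930"), path = "sucrose transport")
  add("T.HATPase.mes", "atp_mc + h2o_mc -> adp_mc + pi_mc + h_apo",
      kind = "transport", ec = "7.1.2.1", genes = "AT2G18960",
      path = "proton transport")
  add("T.HATPase.root", "atp_rc + h2o_rc -> adp_rc + pi_rc + h_env",
      kind = "transport", ec = "7.1.2.1", path = "proton transport")
  add("T.h.phl.mes", "h_phl -> h_mc", kind = "transport",
      path = "proton transport")
  add("T.h.phl.root", "h_phl -> h_rc", kind = "transport",
      path = "proton transport")
  # protons acquired with nutrients travel up with the root-to-shoot stream
  add("T.h.rp", "h_rc -> h_phl", kind = "transport",
      path = "proton transport")
  # symplastic nutrient/water path root -> phloem -> mesophyll
  for (nut in c("no3", "pi", "so4")) {
    add(sprintf("T.%s.rp", nut), sprintf("%s_rc -> %s_phl", nut, nut),
        kind = "transport", path = "nutrient transport")
    add(sprintf("T.%s.pm", nut), sprintf("%s_phl -> %s_mc", nut, nut),
        kind = "transport", path = "nutrient transport")
  }
  add("T.h2o.rp", "h2o_rc <-> h2o_phl", kind = "transport", path = "water")
  add("T.h2o.pm", "h2o_phl <-> h2o_mc", kind = "transport", path = "water")
  # apoplastic gas diffusion to the root
  add("T.o2.apo.m", "o2_mc <-> o2_apo", kind = "transport", path = "gas")
  add("T.o2.apo.r", "o2_apo <-> o2_rc", kind = "transport", path = "gas")
  add("T.co2.apo.m", "co2_mc <-> co2_apo", kind = "transport", path = "gas")
  add("T.co2.apo.r", "co2_rc <-> co2_apo", kind = "transport", path = "gas")
  # root-environment exchange (proton symport uptake)
  add("T.NO3.env", "no3_env + 2 h_env -> no3_rc + 2 h_rc",
      kind = "transport", genes = "AT1G12110", path = "nutrient transport")
  add("T.Pi.env", "pi_env + 2 h_env -> pi_rc + 2 h_rc", kind = "transport",
      path = "nutrient transport")
  add("T.SO4.env", "so4_env + 3 h_env -> so4_rc + 3 h_rc",
      kind = "transport", path = "nutrient transport")
  add("T.H2O.root", "h2o_env <-> h2o_rc", kind = "transport", path = "water")
  # mesophyll-environment exchange
  add("T.CO2.ext", "co2_mc -> co2_env", kind = "transport", path = "gas")
  add("T.CO2.ext_rev", "co2_env -> co2_mc", kind = "transport", path = "gas")
  add("T.O2.ext", "o2_mc <-> o2_env", kind = "transport", path = "gas")
  add("T.H2O.ext", "h2o_mc <-> h2o_env", kind = "transport", path = "water")
  add("T.hv.ext", "hv_env -> hv_mp", kind = "transport",
      path = "photosynthesis light reactions")
  add("T.starch.ext", "starch_env -> starch_mp", kind = "transport",
      path = "starch degradation")

  # ---- biomass: monomer lumps, deposits, growth --------------------------
  fr4 <- function(x) rq_format(rq(round(x * 1e4), 1e4))
  fr6 <- function(x) rq_format(rq(round(x * 1e6), 1e6))
  prot <- bs$composition$protein_mole_fractions
  for (tis in c("m", "r")) {
    c_ <- paste0(tis, "c")
    sid <- function(b) paste0(b, "_", c_)
    # protein polymerisation (charging + elongation cost 4.3 ATP/residue)
    st <- c(stats::setNames(paste0("-", fr4(prot)), sid(names(prot))),
            stats::setNames(c("-43/10", "1", "43/10", "43/10"),
                            c(sid("atp"), sid("prot_res"), sid("adp"),
                              sid("pi"))))
    add(paste0("PROTS_", c_), NULL, kind = "polymerization",
        path = "protein biosynthesis",
        adjust = c(sid("h2o"), sid("h")))
    rxn[[length(rxn)]]$stoich <- st
    # RNA lump: ribose from r5p, carbon from gap/CO2, amide N from gln
    rna_n <- sum(round(bs$composition$rna_base_fractions * 1e4) / 1e4 *
                   c(A = 5, U = 2, C = 3, G = 5)[
                     names(bs$composition$rna_base_fractions)])
    rna_c <- sum(round(bs$composition$rna_base_fractions * 1e4) / 1e4 *
                   c(A = 10, U = 9, C = 9, G = 10)[
                     names(bs$composition$rna_base_fractions)])
    extra_c <- rna_c - 5 - 3   # r5p + one gap
    st <- stats::setNames(
      c("-1", "-1", fr4(-extra_c), fr4(-rna_n), "-8", "1", fr4(rna_n),
        "8", "9"),
      c(sid("r5p"), sid("gap"), sid("co2"), sid("gln"), sid("atp"),
        sid("rna_res"), sid("glu"), sid("adp"), sid("pi")))
    add(paste0("RNAS_", c_), NULL, kind = "polymerization",
        path = "purine nucleotides de novo biosynthesis",
        adjust = c(sid("h2o"), sid("h"),
                   paste0(sid("nadh"), "~", sid("nad"))))
    rxn[[length(rxn)]]$stoich <- st
    # lipid assembly from glycerol-3P and fatty acids
    lw <- bs$composition$lipid_mass_fractions
    lmol <- lw / vapply(names(lw), function(id) formula_mass(.bm_f(id)), 0)
    lper <- round(lmol / lmol[["glyc_backbone"]] * 1e4) / 1e4
    fa <- setdiff(names(lper), "glyc_backbone")
    st <- c(stats::setNames("-1", sid("glyc3p")),
            stats::setNames(paste0("-", fr4(lper[fa])), sid(fa)),
            stats::setNames(c("1", "1"), c(sid("lipid_res"), sid("pi"))))
    add(paste0("LIPS_", c_), NULL, kind = "polymerization",
        path = "fatty acids biosynthesis",
        adjust = c(sid("h2o"), sid("h")))
    rxn[[length(rxn)]]$stoich <- st
    # deposits to the virtual vacuole
    v_ <- paste0("vac", tis)
    add(sprintf("T.dep.suc.%s", c_),
        sprintf("sucr_%s -> sucr_%s", c_, v_), kind = "transport",
        path = "vacuolar deposition")
    add(sprintf("T.dep.no3.%s", c_),
        sprintf("no3_%s -> no3_%s", c_, v_), kind = "transport",
        path = "vacuolar deposition")
    add(sprintf("T.dep.pi.%s", c_),
        sprintf("pi_%s -> pi_%s", c_, v_), kind = "transport",
        path = "vacuolar deposition")
  }
  # growth pseudo-reactions
  gam <- bs$gam_atp
  for (tis in c("m", "r")) {
    c_ <- paste0(tis, "c"); v_ <- paste0("vac", tis)
    dm <- if (tis == "m") bs$demands$mes else bs$demands$root
    st <- character(0)
    res_map <- c(cellulose = paste0("cell_res_", c_),
                 pectin = paste0("pect_res_", c_),
                 starch = "starch_mp",
                 sucrose = paste0("sucr_", v_),
                 protein = paste0("prot_res_", c_),
                 lipid = paste0("lipid_res_", c_),
                 RNA = paste0("rna_res_", c_))
    for (p in names(dm$residues)) {
      if (dm$residues[[p]] == 0) next
      if (p == "starch" && tis == "r") next
      st[res_map[[p]]] <- paste0("-", fr6(dm$residues[[p]]))
    }
    if (dm$dep_no3 > 0) st[paste0("no3_", v_)] <- paste0("-", fr6(dm$dep_no3))
    if (dm$dep_pi > 0) st[paste0("pi_", v_)] <- paste0("-", fr6(dm$dep_pi))
    if (gam > 0) {
      st[paste0("atp_", c_)] <- paste0("-", fr6(gam))
      st[paste0("h2o_", c_)] <- paste0("-", fr6(gam))
      st[paste0("adp_", c_)] <- fr6(gam)
      st[paste0("pi_", c_)] <- fr6(gam)
      st[paste0("h_", c_)] <- fr6(gam)
    }
    st[paste0("biomass_", ifelse(tis == "m", "mes", "root"), "_apo")] <- "1"
    add(paste0("growth_", ifelse(tis == "m", "mes", "root")), NULL,
        kind = "polymerization", path = "biomass growth")
    rxn[[length(rxn)]]$stoich <- st
  }
  add("growth_plant", NULL, kind = "polymerization", path = "biomass growth")
  rxn[[length(rxn)]]$stoich <- c(biomass_mes_apo = "-17/20",
                                 biomass_root_apo = "-3/20",
                                 biomass_plant_apo = "1")
  add("T.Biomass.ext", "biomass_plant_apo -> biomass_env",
      kind = "transport", path = "biomass growth")

  # ---- species assembly ---------------------------------------------------
  # formulas of derived residue/biomass species
  derived <- new.env(parent = emptyenv())
  res_formula <- function(key) {
    r <- bs$residues[[key]]
    structure(list(n = r$elements$n, d = r$elements$d, charge = r$charge),
              class = "elemental_formula")
  }
  for (c_ in c("mc", "rc")) {
    derived[[paste0("prot_res_", c_)]] <- res_formula("protein")
    derived[[paste0("lipid_res_", c_)]] <- res_formula("lipid")
    derived[[paste0("rna_res_", c_)]] <- res_formula("RNA")
  }
  # tissue biomass formula = exact weighted sum of growth inputs
  growth_formula <- function(st, skip) {
    ids <- setdiff(names(st), skip)
    coefs <- lapply(st[ids], rq_parse)
    s <- formula_weighted_sum(
      list(n = -vapply(coefs, `[[`, 0, "n"),
           d = vapply(coefs, `[[`, 0, "d")),
      lapply(ids, function(i) .pf_species_formula(i, derived)))
    structure(list(n = s$elements$n, d = s$elements$d, charge = s$charge),
              class = "elemental_formula")
  }
  for (k in seq_along(rxn)) {
    if (identical(rxn[[k]]$id, "growth_mes"))
      derived[["biomass_mes_apo"]] <- growth_formula(
        rxn[[k]]$stoich, c("biomass_mes_apo",
                           grep("^(atp|h2o|adp|pi|h)_mc$",
                                names(rxn[[k]]$stoich), value = TRUE)))
    if (identical(rxn[[k]]$id, "growth_root"))
      derived[["biomass_root_apo"]] <- growth_formula(
        rxn[[k]]$stoich, c("biomass_root_apo",
                           grep("^(atp|h2o|adp|pi|h)_rc$",
                                names(rxn[[k]]$stoich), value = TRUE)))
  }
  {
    s <- formula_weighted_sum(
      rq(c(17, 3), 20),
      list(derived[["biomass_mes_apo"]], derived[["biomass_root_apo"]]))
    derived[["biomass_plant_apo"]] <- structure(
      list(n = s$elements$n, d = s$elements$d, charge = s$charge),
      class = "elemental_formula")
  }
  formula_of <- function(id) .pf_species_formula(id, derived)

  # resolve lumped adjustments, build transformers
  trs <- vector("list", length(rxn))
  for (k in seq_along(rxn)) {
    r <- rxn[[k]]
    if (is.null(r$stoich)) {
      pe <- parse_equation(r$eq)
      st <- pe$stoich; rev <- pe$reversible
    } else {
      st <- r$stoich; rev <- FALSE
    }
    if (!is.null(r$adjust))
      st <- .adjust_stoich(r$id, st, r$adjust, formula_of)
    trs[[k]] <- transformer(r$id, st, kind = r$kind, reversible = rev,
                            ec = if (is.null(r$ec)) NA_character_ else r$ec,
                            genes = r$genes,
                            pathway = if (is.null(r$path)) NA_character_ else
                              r$path)
  }

  # species list from stoichiometries
  used <- sort(unique(unlist(lapply(trs, function(t) t$stoich$ids))))
  comp_of <- function(id) sub("^.*_(env|apo|phl|mc|mp|mm|rc|rm|vacm|vacr)$",
                              "\\1", id)
  sps <- lapply(used, function(id) {
    comp <- comp_of(id)
    vac <- comp %in% c("vacm", "vacr")
    ccomp <- if (vac) "vac" else comp
    base <- sub(sprintf("_(%s)$", comp), "", id)
    balanced <- ccomp != "env"
    f <- if (!is.null(derived[[id]])) derived[[id]] else {
      ent <- .MET[[base]]
      if (is.null(ent)) {
        if (balanced) stop("unknown metabolite: ", id)
        NULL
      } else parse_formula(ent[1], ent[2])
    }
    species(id, ccomp, formula = f, balanced = balanced)
  })
  net <- network(comps, sps, trs,
                 metadata = list(model = "plantflux reduced Arabidopsis model",
                                 biomass_mw_cmol = bs$mw_cmol))
  bal <- check_network_balance(net)
  bad <- bal[!bal$balanced, , drop = FALSE]
  if (nrow(bad))
    stop("unbalanced transformers in packaged model: ",
         paste(sprintf("%s (%s)", bad$id, bad$residuals), collapse = "; "),
         call. = FALSE)
  if (!is.null(cache_key)) .pf_model_cache[[cache_key]] <- net
  net
}

.pf_species_formula <- function(id, derived) {
  if (!is.null(derived[[id]])) return(derived[[id]])
  comp <- sub("^.*_(env|apo|phl|mc|mp|mm|rc|rm|vacm|vacr)$", "\\1", id)
  base <- sub(sprintf("_(%s)$", comp), "", id)
  ent <- .MET[[base]]
  if (is.null(ent)) stop("unknown metabolite: ", id, call. = FALSE)
  parse_formula(ent[1], ent[2])
}

#' Scenario presets for the packaged model
#'
#' Builds the light or dark constraint set.  The light preset caps biomass,
#' forbids starch degradation and net CO2 efflux, and couples
#' photorespiration to carboxylation (`pr * RPC = RPC2`); optional add-ons
#' select the cyclic-electron-flow treatment.  The dark preset zeroes
#' photon uptake, RuBisCO, photorespiration and starch synthesis and allows
#' starch consumption.
#'
#' @param name "light" or "dark".
#' @param pr photorespiration multiplier (default 0.25; 0 disables
#'   photorespiration via `RPC2 = 0, GLYK = 0`).
#' @param ratio optional FQR/FNR ratio in `[0, 0.5]` (adds
#'   `ratio*FNR - FQR = 0`).
#' @param variant optional add-on: `"fqr0"` (no cyclic flow) or
#'   `"atp_balance"` (`T.ADP.plastid - T.ATP.plastid = 0`).
#' @param cap upper bound on the biomass objective flux.
#' @param net optional network for id validation.
#' @return a `pf_scenario`.
#' @export
plant_scenario <- function(name = c("light", "dark"), pr = 0.25,
                           ratio = NULL, variant = NULL, cap = 5000,
                           net = NULL) {
  name <- match.arg(name)
  lines <- c("objective: max T.Biomass.ext",
             sprintf("T.Biomass.ext <= %s", format(cap)))
  if (name == "light") {
    lines <- c(lines, "SK = 0", "T.starch.ext = 0", "T.CO2.ext = 0",
               "T.CO2.ext_rev >= 0")
    if (pr > 0) {
      lines <- c(lines, sprintf("%s*RPC_plastide - RPC2_plastide = 0",
                                format(pr)))
    } else {
      lines <- c(lines, "RPC2_plastide = 0", "GLYK = 0")
    }
    if (!is.null(ratio)) {
      if (ratio < 0 || ratio > 0.5)
        stop("FQR/FNR ratio must lie in [0, 0.5]", call. = FALSE)
      lines <- c(lines, sprintf("%s*FNR - FQR = 0", format(ratio)))
    }
    if (!is.null(variant)) {
      variant <- match.arg(variant, c("fqr0", "atp_balance"))
      lines <- c(lines, switch(variant,
                               fqr0 = "FQR = 0",
                               atp_balance =
                                 "T.ADP.plastid - T.ATP.plastid = 0"))
    }
  } else {
    if (!is.null(ratio) || !is.null(variant))
      stop("ratio/variant add-ons apply to the light scenario only",
           call. = FALSE)
    lines <- c(lines, "PGM3_plastid = 0", "RPC_plastide = 0",
               "RPC2_plastide = 0", "GLYK = 0", "GDC = 0",
               "T.starch.ext >= 0", "T.hv.ext = 0")
  }
  parse_scenario(paste(lines, collapse = "\n"), net = net, name = name)
}
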