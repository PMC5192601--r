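# Biomass composition: macromolecular fractions, monomer tables, per-tissue
# pseudo-reaction demands and the derived whole-plant elemental formula.

#' Default biomass macromolecular composition
#'
#' Mass fractions of the whole-plant dry biomass and the monomer tables of
#' each polymer.  The protein table is a packaged average amino-acid
#' composition (mole fractions of residues); the lipid monomer table is
#' renormalised from printed fractions that sum to 99.706 %; RNA base
#' composition is mole fractions.
#'
#' @param polymer_fractions named mass fractions summing to 1.
#' @param shoot_fraction mass fraction of mesophyll (shoot) in whole-plant
#'   biomass; the remainder is root.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(
    polymer_fractions = c(cellulose = 0.20, pectin = 0.20, starch = 0.10,
                          sucrose = 0.12, protein = 0.25, lipid = 0.09,
                          RNA = 0.01, ash = 0.03),
    shoot_fraction = 0.85) {
  if (abs(sum(polymer_fractions) - 1) > 1e-9)
    stop("polymer fractions must sum to 1", call. = FALSE)
  if (shoot_fraction <= 0 || shoot_fraction >= 1)
    stop("shoot_fraction must lie in (0,1)", call. = FALSE)
  protein <- c(ala = 0.22, gly = 0.12, ser = 0.12, asp = 0.14, glu = 0.16,
               gln = 0.14, cys = 0.02, val = 0.08)  # mole fractions, residues
  lipid_raw <- c(hdca = 0.096, ocdcea = 0.206, hdcea = 0.347, ocdca = 0.024,
                 lnlc = 0.00006, glyc_backbone = 0.324)  # mass fractions
  lipid <- lipid_raw / sum(lipid_raw)
  rna <- c(A = 0.32, U = 0.26, C = 0.09, G = 0.33)   # mole fractions
  structure(list(polymer_fractions = polymer_fractions,
                 protein_mole_fractions = protein,
                 lipid_mass_fractions = lipid,
                 rna_base_fractions = rna,
                 shoot_fraction = shoot_fraction),
            class = "biomass_composition")
}

# free monomer formulas used in residue bookkeeping
.BM_FORMULA <- list(
  ala  = list(f = c(C = 3, H = 7, N = 1, O = 2), chg = 0),
  gly  = list(f = c(C = 2, H = 5, N = 1, O = 2), chg = 0),
  ser  = list(f = c(C = 3, H = 7, N = 1, O = 3), chg = 0),
  asp  = list(f = c(C = 4, H = 6, N = 1, O = 4), chg = -1),
  glu  = list(f = c(C = 5, H = 8, N = 1, O = 4), chg = -1),
  gln  = list(f = c(C = 5, H = 10, N = 2, O = 3), chg = 0),
  cys  = list(f = c(C = 3, H = 7, N = 1, O = 2, S = 1), chg = 0),
  val  = list(f = c(C = 5, H = 11, N = 1, O = 2), chg = 0),
  hdca   = list(f = c(C = 16, H = 31, O = 2), chg = -1),
  ocdca  = list(f = c(C = 18, H = 35, O = 2), chg = -1),
  hdcea  = list(f = c(C = 16, H = 29, O = 2), chg = -1),
  ocdcea = list(f = c(C = 18, H = 33, O = 2), chg = -1),
  lnlc   = list(f = c(C = 18, H = 31, O = 2), chg = -1),
  glyc_backbone = list(f = c(C = 3, H = 8, O = 3), chg = 0),
  # RNA residues: NMP - H2O, phosphodiester charge -1
  A = list(f = c(C = 10, H = 10, N = 5, O = 6, P = 1), chg = -1),
  G = list(f = c(C = 10, H = 10, N = 5, O = 7, P = 1), chg = -1),
  U = list(f = c(C = 9, H = 9, N = 2, O = 8, P = 1), chg = -1),
  C = list(f = c(C = 9, H = 10, N = 3, O = 7, P = 1), chg = -1)
)

.bm_f <- function(id) {
  e <- .BM_FORMULA[[id]]
  make_formula(e$f, e$chg)
}

# weighted residue formula: sum frac_i * (monomer_i - n_water_i * H2O),
# fractions given to 1e-4 precision; exact arithmetic on the rounded values.
.residue_formula <- function(ids, fracs, water_per_unit, charge_shift = 0) {
  fr <- round(fracs * 1e4)
  coefs <- rq(c(fr, -sum(fr * water_per_unit)), 1e4)
  fl <- c(lapply(ids, .bm_f), list(make_formula(c(H = 2, O = 1), 0)))
  s <- formula_weighted_sum(coefs, fl)
  chg <- rq_add(s$charge, rq_scalar(round(charge_shift * 1e4), 1e4))
  list(elements = s$elements, charge = chg)
}

.residue_mass <- function(res) {
  sum(.PERIODIC[names(res$elements$n)] * res$elements$n / res$elements$d)
}

#' Assemble the biomass specification from a composition
#'
#' Derives, per tissue (mesophyll and root) and for the whole plant:
#' the monomer/residue demand in mol per gram dry weight, the elemental
#' formula per C-mol and the molar mass per C-mol.  Starch is assigned
#' entirely to the mesophyll (the root has no plastid); the other polymers
#' are distributed so the whole-plant composition matches the input.  When
#' the composition carries a nonzero ash fraction, vacuolar nitrate and
#' phosphate deposit demands are calibrated so that the whole-plant N/C and
#' P/C ratios equal the reconstruction targets (0.144 and 0.033 per C).
#' Maintenance ATP is not charged to growth: the source design leaves its
#' magnitude unspecified, so proton-pump and biosynthetic costs emerge from
#' the network itself (an unforced cytosolic ATPase reaction exists).
#'
#' @param composition a `biomass_composition`.
#' @return object of class `biomass_spec` with `demands` (per-tissue named
#'   mol/g), `formula` (whole plant, per C-mol), `mw_cmol`, `gam_atp`,
#'   `residues` (residue formulas), `shoot_fraction`.
#' @export
compose_biomass <- function(composition = biomass_composition()) {
  pf <- composition$polymer_fractions
  sf <- composition$shoot_fraction
  # residue formulas --------------------------------------------------------
  prot <- composition$protein_mole_fractions
  prot_res <- .residue_formula(names(prot), prot, rep(1, length(prot)))
  lip_m <- composition$lipid_mass_fractions
  lip_mol <- lip_m / vapply(names(lip_m), function(id)
    formula_mass(.bm_f(id)), 0)          # mol per gram of lipid
  lip_per_glyc <- lip_mol / lip_mol[["glyc_backbone"]]
  esters <- sum(lip_per_glyc[setdiff(names(lip_per_glyc), "glyc_backbone")])
  lip_res <- .residue_formula(names(lip_per_glyc), lip_per_glyc,
                              ifelse(names(lip_per_glyc) == "glyc_backbone",
                                     0, 1))
  rna <- composition$rna_base_fractions
  rna_res <- .residue_formula(names(rna), rna, rep(0, length(rna)))
  residues <- list(
    cellulose = list(elements = list(n = c(C = 6, H = 10, O = 5),
                                     d = c(C = 1, H = 1, O = 1)),
                     charge = rq_scalar(0)),
    pectin = list(elements = list(n = c(C = 6, H = 8, O = 6),
                                  d = c(C = 1, H = 1, O = 1)),
                  charge = rq_scalar(0)),
    starch = list(elements = list(n = c(C = 6, H = 10, O = 5),
                                  d = c(C = 1, H = 1, O = 1)),
                  charge = rq_scalar(0)),
    sucrose = list(elements = list(n = c(C = 12, H = 22, O = 11),
                                   d = c(C = 1, H = 1, O = 1)),
                   charge = rq_scalar(0)),
    protein = prot_res, lipid = lip_res, RNA = rna_res)
  res_mass <- vapply(residues, .residue_mass, 0)
  # per-tissue polymer mass fractions --------------------------------------
  organic <- pf[setdiff(names(pf), "ash")]
  organic <- organic / sum(organic)      # fractions of the organic gram
  f_root <- organic
  f_root["starch"] <- 0
  if (sum(f_root) == 0) f_root <- organic   # degenerate (pure-starch) input
  else f_root <- f_root / sum(f_root)
  f_mes <- (organic - (1 - sf) * f_root) / sf
  if (any(f_mes < -1e-12))
    stop("tissue split infeasible for given composition", call. = FALSE)
  f_mes[f_mes < 0] <- 0
  demand_of <- function(fr) {            # mol residues per organic gram
    d <- fr / res_mass[names(fr)]
    stats::setNames(d, names(fr))
  }
  dem_mes <- demand_of(f_mes)
  dem_root <- demand_of(f_root)
  # deposit calibration (ash -> vacuolar NO3/HPO4) -------------------------
  target_nc <- rq_scalar(18, 125)   # 0.144 N per C
  target_pc <- rq_scalar(33, 1000)  # 0.033 P per C
  el_of <- function(dem) {
    coefs <- rq(round(dem * 1e6), 1e6)
    formula_weighted_sum(coefs, lapply(names(dem), function(p) {
      r <- residues[[p]]
      structure(list(n = r$elements$n, d = r$elements$d,
                     charge = rq_scalar(0)), class = "elemental_formula")
    }))
  }
  has_ash <- !is.na(pf["ash"]) && pf[["ash"]] > 0
  per_tissue <- function(dem) {
    s <- el_of(dem)
    gx <- function(sym) {
      i <- match(sym, names(s$elements$n))
      if (is.na(i)) rq_scalar(0) else rq_scalar(s$elements$n[i],
                                                s$elements$d[i])
    }
    C <- gx("C"); N <- gx("N"); P <- gx("P")
    dep_no3 <- dep_pi <- 0
    if (has_ash) {
      dn <- rq_sub(rq_mul(target_nc, C), N)
      dp <- rq_sub(rq_mul(target_pc, C), P)
      dep_no3 <- max(0, rq_as_numeric(dn))
      dep_pi <- max(0, rq_as_numeric(dp))
    }
    mass <- sum(.PERIODIC[names(s$elements$n)] * s$elements$n /
                  s$elements$d) +
      dep_no3 * (14.007 + 3 * 15.999) + dep_pi * (1.008 + 4 * 15.999 + 30.974)
    list(dem = dem, dep_no3 = dep_no3, dep_pi = dep_pi, mass = mass)
  }
  tm <- per_tissue(dem_mes); trt <- per_tissue(dem_root)
  # rescale so one unit of tissue biomass weighs one gram
  scale_t <- function(t) {
    k <- 1 / t$mass
    list(residues = round(t$dem * k * 1e6) / 1e6,
         dep_no3 = round(t$dep_no3 * k * 1e6) / 1e6,
         dep_pi = round(t$dep_pi * k * 1e6) / 1e6)
  }
  mes <- scale_t(tm); root <- scale_t(trt)
  # whole-plant formula (derived from the rounded per-gram demands) --------
  plant_counts <- function(w_mes, w_root) {
    ids <- names(mes$residues)
    coefs_n <- c(round(1e6 * (w_mes * mes$residues + w_root * root$residues)),
                 round(1e6 * (w_mes * mes$dep_no3 + w_root * root$dep_no3)),
                 round(1e6 * (w_mes * mes$dep_pi + w_root * root$dep_pi)))
    fl <- c(lapply(ids, function(p) {
      r <- residues[[p]]
      structure(list(n = r$elements$n, d = r$elements$d,
                     charge = rq_scalar(0)), class = "elemental_formula")
    }), list(make_formula(c(N = 1, O = 3), -1),
             make_formula(c(H = 1, O = 4, P = 1), -2)))
    formula_weighted_sum(rq(coefs_n, 1e6), fl)
  }
  tot <- plant_counts(sf, 1 - sf)
  Ci <- match("C", names(tot$elements$n))
  C_tot <- tot$elements$n[Ci] / tot$elements$d[Ci]
  per_c <- stats::setNames(
    unname((tot$elements$n / tot$elements$d) / C_tot),
    names(tot$elements$n))
  mw_cmol <- unname(1 / C_tot)   # one gram of biomass per C_tot mol C
  structure(list(
    demands = list(mes = mes, root = root),
    residues = residues,
    residue_mass = res_mass,
    formula_per_cmol = per_c,
    mw_cmol = mw_cmol,
    gam_atp = 0,
    shoot_fraction = sf,
    esters_per_glycerol = esters,
    composition = composition), class = "biomass_spec")
}

#' @export
print.biomass_spec <- function(x, ...) {
  f <- x$formula_per_cmol
  cat(sprintf("<biomass_spec> per C-mol: %s  (MW %.2f g/Cmol)\n",
              paste(sprintf("%s%.3f", names(f), f), collapse = " "),
              x$mw_cmol))
  invisible(x)
}
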