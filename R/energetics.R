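# Derived quantities from flux solutions: precursor ratios, plastid exchange
# fractions, ATP budgets, proton ledgers and the sucrose translocation audit.

.pf_flux <- function(sol, id) {
  v <- sol$fluxes[id]
  v[is.na(v)] <- 0
  unname(v)
}

# signed production rates of one species across all transformers
.species_contributions <- function(net, sol, species_id, sm = NULL) {
  if (is.null(sm)) sm <- stoich_matrix(net)
  row <- match(species_id, sm$species)
  if (is.na(row)) stop(sprintf("species '%s' not in matrix", species_id),
                       call. = FALSE)
  co <- sm$S$n[row, ] / sm$S$d[row, ]
  contrib <- co * sol$fluxes[sm$transformers]
  contrib[contrib != 0]
}

# total turnover = sum of positive production terms (gross); NA when the
# species is absent (toy fixtures lack some organelle pools)
.turnover <- function(net, sol, species_id, sm = NULL) {
  if (is.null(sm)) sm <- stoich_matrix(net)
  if (!(species_id %in% sm$species)) return(NA_real_)
  ctr <- .species_contributions(net, sol, species_id, sm)
  sum(ctr[ctr > 0])
}

#' Precursor turnover ratios of a flux solution
#'
#' Computes the ratio table: photon/CO2, photon/NO3, CO2/NO3 (all from
#' environment-boundary fluxes; CO2 is net uptake in the light and net
#' release in the dark), P/O per mitochondrion (ATP synthase flux over
#' terminal-oxidase O2 flux), ATP/NADPH and H+/ATP in the plastid,
#' ATP/NADH in the mesophyll mitochondrion, and the whole-plant respiratory
#' quotient RQ (net CO2 out / net O2 in).  Ratios with zero denominators
#' are reported as `NA` (undefined).
#'
#' @param net the packaged network; @param sol an optimal `flux_solution`.
#' @param sm optional precomputed `stoich_matrix`.
#' @return list of class `ratio_report`.
#' @export
precursor_ratios <- function(net, sol, sm = NULL) {
  stopifnot(sol$status == "optimal")
  if (is.null(sm)) sm <- stoich_matrix(net)
  rat <- function(a, b) if (is.na(a) || is.na(b) || abs(b) < 1e-12)
    NA_real_ else a / b
  co2_net_in <- .pf_flux(sol, "T.CO2.ext_rev") - .pf_flux(sol, "T.CO2.ext")
  o2_net_out <- .pf_flux(sol, "T.O2.ext")
  hv <- .pf_flux(sol, "T.hv.ext")
  no3 <- .pf_flux(sol, "T.NO3.env")
  po <- function(m) rat(.pf_flux(sol, paste0("ATPS_", m)),
                        0.5 * .pf_flux(sol, paste0("CIV_", m)))
  atp_mp <- .turnover(net, sol, "atp_mp", sm)
  nadph_mp <- .turnover(net, sol, "nadph_mp", sm)
  hlum <- .turnover(net, sol, "h_lum_mp", sm)
  atp_mm <- .pf_flux(sol, "ATPS_mm")
  nadh_mm <- .turnover(net, sol, "nadh_mm", sm)
  structure(list(
    photon_per_co2 = rat(hv, co2_net_in),
    photon_per_no3 = rat(hv, no3),
    co2_per_no3 = rat(abs(co2_net_in), no3),
    po_mes = po("mm"), po_root = po("rm"),
    atp_per_nadph_plastid = rat(atp_mp, nadph_mp),
    atp_per_nadh_mito = rat(atp_mm, nadh_mm),
    h_per_atp_plastid = rat(hlum, .pf_flux(sol, "ATPS_mp")),
    rq = rat(-co2_net_in, -o2_net_out),
    scenario = sol$scenario), class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("<ratio_report> scenario %s\n", x$scenario))
  for (nm in setdiff(names(x), "scenario"))
    cat(sprintf("  %-24s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else
                  format(signif(x[[nm]], 4))))
  invisible(x)
}

#' Plastid ATP/NADPH exchange fractions
#'
#' Fraction of the total plastid ATP turnover exchanged with the cytosol
#' through the nucleotide translocator (positive = import into the
#' plastid), and fraction of the NADPH turnover exported as reduced
#' equivalents through the malate/oxaloacetate shuttle (negative = export).
#'
#' @inheritParams precursor_ratios
#' @return list of class `exchange_fractions` with `atp_fraction`,
#'   `nadph_fraction`, `h_fraction` and the underlying turnovers.
#' @export
plastid_exchange_fractions <- function(net, sol, sm = NULL) {
  stopifnot(sol$status == "optimal")
  if (is.null(sm)) sm <- stoich_matrix(net)
  atp_t <- .turnover(net, sol, "atp_mp", sm)
  nadph_t <- .turnover(net, sol, "nadph_mp", sm)
  h_t <- .turnover(net, sol, "h_mp", sm)
  net_atp_in <- .pf_flux(sol, "T.ATP.plastid") - .pf_flux(sol, "T.ADP.plastid")
  net_nadph_out <- .pf_flux(sol, "MDHN_mp")  # shuttle export, NADPH equiv.
  net_h_in <- .pf_flux(sol, "T.h.mp")
  fr <- function(num, den) if (den < 1e-12) NA_real_ else num / den
  structure(list(atp_fraction = fr(net_atp_in, atp_t),
                 nadph_fraction = fr(-net_nadph_out, nadph_t),
                 h_fraction = fr(net_h_in, h_t),
                 atp_turnover = atp_t, nadph_turnover = nadph_t,
                 h_turnover = h_t, scenario = sol$scenario),
            class = "exchange_fractions")
}

#' @export
print.exchange_fractions <- function(x, ...) {
  cat(sprintf(paste0("<exchange_fractions> %s: T.ATP/ATP %+.3f  ",
                     "T.NADPH/NADPH %+.3f  T.H+/H+ %+.3f\n"),
              x$scenario, x$atp_fraction, x$nadph_fraction, x$h_fraction))
  invisible(x)
}

#' Itemised ATP budget of a compartment
#'
#' Production and consumption of ATP in one compartment, itemised by
#' transformer and expressed as percentages of the total (gross) turnover;
#' grouped into mitochondrial import, glycolysis/substrate-level, plastid
#' exchange, proton-pump (H+-ATPase) and other cata-/anabolic reactions.
#'
#' @inheritParams precursor_ratios
#' @param compartment compartment id (e.g. `"mc"`).
#' @return list of class `atp_budget`.
#' @export
atp_budget <- function(net, sol, compartment, sm = NULL) {
  stopifnot(sol$status == "optimal")
  if (is.null(sm)) sm <- stoich_matrix(net)
  sp <- paste0("atp_", compartment)
  if (!(sp %in% sm$species))
    stop(sprintf("no ATP species in compartment '%s'", compartment),
         call. = FALSE)
  ctr <- .species_contributions(net, sol, sp, sm)
  total <- sum(ctr[ctr > 0])
  group_of <- function(id) {
    if (grepl("^ANT_", id)) "mitochondrial exchange"
    else if (grepl("^T\\.(ATP|ADP)\\.plastid$", id)) "plastid exchange"
    else if (grepl("^T\\.HATPase", id)) "H+-ATPase"
    else if (id %in% paste0(c("PGK_", "PYK_"), compartment))
      "glycolysis"
    else "cata-/anabolic reactions"
  }
  items <- data.frame(id = names(ctr), flux = as.numeric(ctr),
                      share_pct = 100 * abs(ctr) / total,
                      side = ifelse(ctr > 0, "producing", "consuming"),
                      group = vapply(names(ctr), group_of, ""),
                      stringsAsFactors = FALSE)
  items <- items[order(-items$share_pct), ]
  rownames(items) <- NULL
  groups <- stats::aggregate(share_pct ~ group + side, items, sum)
  structure(list(compartment = compartment, turnover = total,
                 items = items, groups = groups, scenario = sol$scenario),
            class = "atp_budget")
}

#' @export
print.atp_budget <- function(x, ...) {
  cat(sprintf("<atp_budget> %s (%s): turnover %.4g\n", x$compartment,
              x$scenario, x$turnover))
  g <- x$groups[order(x$groups$side, -x$groups$share_pct), ]
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-9s %5.1f %%  %s\n", g$side[i], g$share_pct[i],
                g$group[i]))
  invisible(x)
}

# Identify the ledger proton species of each compartment: formula exactly H
# with charge +1; where a compartment holds several H+ pools (plastid stroma
# vs thylakoid lumen) the one named `h_<compartment>` is the ledger pool.
.proton_species <- function(net) {
  is_h <- vapply(net$species, function(sp) {
    f <- sp$formula
    !is.null(f) && length(f$n) == 1L && names(f$n) == "H" &&
      f$n == 1 && f$d == 1 && f$charge$n == f$charge$d
  }, TRUE)
  hs <- names(which(is_h))
  comps <- vapply(hs, function(id) net$species[[id]]$compartment, "")
  out <- character(0)
  for (cp in unique(comps)) {
    if (net$compartments[[cp]]$kind %in% c("environment", "vacuole_virtual"))
      next
    cand <- hs[comps == cp]
    pref <- cand[cand == paste0("h_", cp)]
    out[cp] <- if (length(pref)) pref else cand[1]
  }
  out
}

#' Compartmental proton ledger
#'
#' Itemises every proton-producing and proton-consuming process per
#' compartment, checks closure (production - consumption = 0 at steady
#' state), reports the counts of producing/consuming processes, and
#' normalises all turnovers by the proton turnover of the sink-tissue
#' (root-type) cytoplasm -- the reference compartment, chosen because its
#' activity is nearly invariant across light regimes.
#'
#' @inheritParams precursor_ratios
#' @param reference compartment id used for normalisation; default: the
#'   cytoplasm compartment that receives protons from the environment.
#' @return list of class `proton_ledger`.
#' @export
proton_ledger <- function(net, sol, sm = NULL, reference = NULL) {
  stopifnot(sol$status == "optimal")
  if (is.null(sm)) sm <- stoich_matrix(net)
  hsp <- .proton_species(net)
  if (!length(hsp))
    stop("no proton species identified in any compartment", call. = FALSE)
  env_h <- names(net$species)[vapply(net$species, function(sp)
    net$compartments[[sp$compartment]]$kind == "environment" &&
      grepl("^h_", sp$id), TRUE)]
  if (is.null(reference)) {
    # sink cytoplasm: receives protons from the environment via transport
    cand <- character(0)
    for (id in names(net$transformers)) {
      tr <- net$transformers[[id]]
      if (tr$kind != "transport") next
      if (!any(tr$stoich$ids %in% env_h & tr$stoich$n < 0)) next
      gain <- tr$stoich$ids[tr$stoich$n > 0 & tr$stoich$ids %in% hsp]
      for (g in gain) cand <- c(cand, net$species[[g]]$compartment)
    }
    cand <- unique(cand[vapply(cand, function(cp)
      net$compartments[[cp]]$kind == "cytoplasm", TRUE)])
    reference <- if (length(cand)) cand[1] else names(hsp)[1]
  }
  per <- lapply(names(hsp), function(cp) {
    ctr <- .species_contributions(net, sol, hsp[[cp]], sm)
    prod <- ctr[ctr > 0]; cons <- ctr[ctr < 0]
    list(compartment = cp,
         produced = sum(prod), consumed = -sum(cons),
         n_producing = length(prod), n_consuming = length(cons),
         closure = sum(ctr),
         items = sort(ctr, decreasing = TRUE))
  })
  names(per) <- names(hsp)
  ref <- per[[reference]]$produced
  for (cp in names(per)) per[[cp]]$relative_turnover <-
    if (ref > 0) per[[cp]]$produced / ref else NA_real_
  # net proton uptake from the environment (flux out of the env H+ pool)
  net_uptake <- 0
  for (id in names(net$transformers)) {
    tr <- net$transformers[[id]]
    k <- which(tr$stoich$ids %in% env_h)
    if (length(k))
      net_uptake <- net_uptake -
        sum(tr$stoich$n[k] / tr$stoich$d[k]) * .pf_flux(sol, id)
  }
  structure(list(compartments = per, reference = reference,
                 reference_turnover = ref,
                 net_env_uptake = net_uptake, scenario = sol$scenario),
            class = "proton_ledger")
}

#' @export
print.proton_ledger <- function(x, ...) {
  cat(sprintf("<proton_ledger> %s (normalised per root cytoplasm)\n",
              x$scenario))
  for (cp in names(x$compartments)) {
    p <- x$compartments[[cp]]
    cat(sprintf("  %-4s prod %8.3g cons %8.3g (x%5.2f ref)  %d/%d processes\n",
                cp, p$produced, p$consumed, p$relative_turnover,
                p$n_producing, p$n_consuming))
  }
  cat(sprintf("  net proton uptake from environment: %.4g\n",
              x$net_env_uptake))
  invisible(x)
}

#' Sucrose translocation audit
#'
#' Verifies the source-to-sink translocation mechanism on a solution:
#' net sucrose efflux mesophyll -> apoplast/phloem is positive and carried
#' by proton-independent (SWEET-type) steps; influx into phloem and root is
#' carried by sucrose-proton symport (>= 1 H+ co-consumed per sucrose); no
#' sucrose returns from the root; net direction is source -> sink.
#'
#' @inheritParams precursor_ratios
#' @return list of class `sucrose_audit` with `pass` and per-check details.
#' @export
sucrose_audit <- function(net, sol, sm = NULL) {
  stopifnot(sol$status == "optimal")
  if (is.null(sm)) sm <- stoich_matrix(net)
  checks <- list()
  note <- function(name, ok, value)
    checks[[name]] <<- list(ok = ok, value = value)
  h_ids <- grep("^h_", sm$species, value = TRUE)
  # net sucrose transport balance per cytoplasm compartment (deposits to the
  # virtual vacuole are biomass, not translocation, and are excluded)
  cyts <- names(net$compartments)[vapply(net$compartments, function(cp)
    cp$kind == "cytoplasm", TRUE)]
  phls <- names(net$compartments)[vapply(net$compartments, function(cp)
    cp$kind == "phloem", TRUE)]
  net_export <- function(comp) {
    tot <- 0
    for (id in sm$transformers) {
      tr <- net$transformers[[id]]
      if (tr$kind != "transport" || grepl("^T\\.dep\\.", id)) next
      k <- which(grepl("^sucr?2?_", tr$stoich$ids) &
                   vapply(tr$stoich$ids, function(s)
                     net$species[[s]]$compartment == comp, TRUE))
      if (!length(k)) next
      tot <- tot - sum(tr$stoich$n[k] / tr$stoich$d[k] * sol$fluxes[id])
    }
    tot
  }
  exp_cyt <- vapply(cyts, net_export, 0)
  src <- names(which(exp_cyt > 1e-9))
  snk <- names(which(exp_cyt < -1e-9))
  note("single_source_tissue", length(src) == 1L, length(src))
  note("single_sink_tissue", length(snk) == 1L, length(snk))
  note("source_export_positive", length(src) == 1L && exp_cyt[src] > 1e-9,
       if (length(src)) exp_cyt[src] else 0)
  note("sink_import_positive", length(snk) == 1L && exp_cyt[snk] < -1e-9,
       if (length(snk)) -exp_cyt[snk] else 0)
  # mechanism: efflux steps (SWEET-type) proton independent
  sweet_ids <- grep("^SWEET", sm$transformers, value = TRUE)
  suc_ids <- grep("^SUC", sm$transformers, value = TRUE)
  sweet_ok <- length(sweet_ids) > 0 && all(vapply(sweet_ids, function(id)
    !any(net$transformers[[id]]$stoich$ids %in% h_ids), TRUE))
  note("efflux_proton_independent", sweet_ok, length(sweet_ids))
  # mechanism: influx steps co-consume >= 1 proton per sucrose
  sym_ok <- length(suc_ids) > 0 && all(vapply(suc_ids, function(id) {
    tr <- net$transformers[[id]]
    ks <- which(grepl("^sucr?2?_", tr$stoich$ids) & tr$stoich$n < 0)
    if (!length(ks)) return(FALSE)
    donor <- net$species[[tr$stoich$ids[ks[1]]]]$compartment
    # the co-consumed proton must come from the same (donor) compartment
    kh <- which(tr$stoich$ids %in% h_ids & tr$stoich$n < 0 &
                  vapply(tr$stoich$ids, function(sid)
                    net$species[[sid]]$compartment == donor, TRUE))
    if (!length(kh)) return(FALSE)
    suc_in <- -sum(tr$stoich$n[ks] / tr$stoich$d[ks])
    h_in <- -sum(tr$stoich$n[kh] / tr$stoich$d[kh])
    h_in >= suc_in
  }, TRUE))
  note("influx_proton_symport", sym_ok, length(suc_ids))
  # no sucrose re-export from the sink tissue through any transporter
  reexp <- 0
  if (length(snk) == 1L) {
    for (id in sm$transformers) {
      tr <- net$transformers[[id]]
      if (tr$kind != "transport" || grepl("^T\\.dep\\.", id)) next
      k <- which(grepl("^sucr?2?_", tr$stoich$ids) &
                   vapply(tr$stoich$ids, function(s)
                     net$species[[s]]$compartment == snk, TRUE))
      if (length(k) && any(tr$stoich$n[k] < 0))
        reexp <- reexp + max(0, sol$fluxes[id])
    }
  }
  note("no_sink_reexport", reexp < 1e-9, reexp)
  structure(list(pass = all(vapply(checks, `[[`, TRUE, "ok")),
                 checks = checks, scenario = sol$scenario,
                 net_export = exp_cyt),
            class = "sucrose_audit")
}

#' @export
print.sucrose_audit <- function(x, ...) {
  cat(sprintf("<sucrose_audit> %s: %s\n", x$scenario,
              if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$checks))
    cat(sprintf("  [%s] %-26s %.4g\n",
                if (x$checks[[nm]]$ok) "ok" else "FAIL", nm,
                as.numeric(x$checks[[nm]]$value)))
  invisible(x)
}

# ---- subsystem probes (desk-scale theoretical ratios) ----------------------

# Build a sub-LP restricted to given transformers, with free exchange of the
# listed boundary species, optional fixed fluxes; pfba-style minimal-flux
# solve.  Returns named fluxes including boundary exchanges ("EX_<species>",
# positive = production by the subsystem).
.subsystem_solve <- function(net, transformers, boundary, fixed = list()) {
  sm <- stoich_matrix(net)
  cols <- match(transformers, sm$transformers)
  if (anyNA(cols)) stop("unknown transformer in subsystem", call. = FALSE)
  keep_rows <- which(rowSums(abs(sm$S$n[, cols, drop = FALSE])) > 0)
  S <- sm$S$n[keep_rows, cols, drop = FALSE] /
    sm$S$d[keep_rows, cols, drop = FALSE]
  spn <- sm$species[keep_rows]
  n <- length(cols); m <- length(spn)
  bix <- match(boundary, spn)
  bix <- bix[!is.na(bix)]
  nb <- length(bix)
  nz <- which(S != 0, arr.ind = TRUE)
  ri <- nz[, 1]; rj <- nz[, 2]; rx <- S[nz]
  ri <- c(ri, bix); rj <- c(rj, n + seq_len(nb)); rx <- c(rx, rep(-1, nb))
  # internal species must close; boundary species get a free exchange column
  lb <- c(ifelse(sm$reversible[cols], -Inf, 0), rep(-Inf, nb))
  ub <- rep(Inf, n + nb)
  ids <- c(sm$transformers[cols], paste0("EX_", spn[bix]))
  for (nm in names(fixed)) {
    k <- match(nm, ids)
    if (is.na(k)) stop("fixed flux not in subsystem: ", nm, call. = FALSE)
    lb[k] <- fixed[[nm]]; ub[k] <- fixed[[nm]]
  }
  # internal (non-boundary) rows are equality zero
  sense <- rep("E", m); rhs <- rep(0, m)
  # minimise total |v| subject to the fixed fluxes (pfba-style single stage)
  nv <- n + nb
  ri2 <- ri; rj2 <- rj; rx2 <- rx
  row0 <- m
  for (k in seq_len(nv)) {
    row0 <- row0 + 1L
    ri2 <- c(ri2, row0, row0); rj2 <- c(rj2, k, nv + k); rx2 <- c(rx2, -1, 1)
    sense <- c(sense, "G"); rhs <- c(rhs, 0)
    row0 <- row0 + 1L
    ri2 <- c(ri2, row0, row0); rj2 <- c(rj2, k, nv + k); rx2 <- c(rx2, 1, 1)
    sense <- c(sense, "G"); rhs <- c(rhs, 0)
  }
  prob <- list(ncol = 2L * nv, rows = list(i = ri2, j = rj2, x = rx2),
               sense = sense, rhs = rhs,
               lb = c(lb, rep(0, nv)), ub = c(ub, rep(Inf, nv)),
               objectives = list(list(c = c(numeric(nv), rep(1, nv)),
                                      maximize = FALSE)))
  res <- lp_solve_batch(list(prob))[[1]][[1]]
  if (res$status != "optimal")
    stop("subsystem solve failed: ", res$status, call. = FALSE)
  stats::setNames(unlist(res$x)[seq_len(nv)], ids)
}

#' Calvin-Benson cycle demand ratio (desk-scale probe)
#'
#' Restricts the model to the plastid Calvin-Benson subnetwork with
#' photorespiration off, fixes one unit of net CO2 fixation, solves the
#' minimal steady-state flux, and reports total ATP consumed per NADPH
#' consumed (theoretical value 3:2 = 1.5).
#'
#' @param net the packaged model.
#' @return list with `atp`, `nadph`, `ratio`.
#' @export
cbc_demand_ratio <- function(net = build_model()) {
  cbc <- c("RPC_plastide", "PGK_mp", "GAPDH_mp", "TPI_mp", "FBA_mp",
           "FBP_mp", "TKT1_mp", "FBA2_mp", "SBP_mp", "TKT2_mp", "RPI_mp",
           "RPE_mp", "PRK")
  boundary <- c("co2_mp", "gap_mp", "atp_mp", "adp_mp", "pi_mp",
                "nadph_mp", "nadp_mp", "h_mp", "h2o_mp")
  v <- .subsystem_solve(net, cbc, boundary,
                        fixed = list(EX_co2_mp = -1))
  atp <- -v[["EX_atp_mp"]]
  nadph <- -v[["EX_nadph_mp"]]
  list(atp = atp, nadph = nadph, ratio = atp / nadph)
}

#' Linear electron transport ATP:NADPH yield (desk-scale probe)
#'
#' Runs the photosynthetic light-reaction subnetwork with cyclic flow (FQR)
#' fixed to zero and one unit of FNR flux and reports ATP synthase output
#' per NADPH produced (1.0 under the packaged stoichiometry: 4 lumenal H+
#' per NADPH and 4 H+ per ATP).
#'
#' @param net the packaged model.
#' @return list with `atp`, `nadph`, `ratio`.
#' @export
let_yield_ratio <- function(net = build_model()) {
  lr <- c("PSII", "B6F", "PSI", "FNR", "FQR", "ATPS_mp")
  boundary <- c("hv_mp", "h2o_mp", "o2_mp", "nadp_mp", "nadph_mp",
                "adp_mp", "atp_mp", "pi_mp", "h_mp")
  v <- .subsystem_solve(net, lr, boundary,
                        fixed = list(FQR = 0, FNR = 1))
  atp <- v[["ATPS_mp"]]
  nadph <- v[["EX_nadph_mp"]]
  list(atp = atp, nadph = nadph, ratio = atp / nadph)
}

#' Plastid ATP synthase proton-to-ATP coefficient ratio
#'
#' Reads the packaged stoichiometry: lumenal protons consumed per ATP
#' formed by the plastid ATP synthase.
#' @param net the packaged model.
#' @export
plastid_h_per_atp <- function(net = build_model()) {
  tr <- net$transformers[["ATPS_mp"]]
  h <- -tr$stoich$n[match("h_lum_mp", tr$stoich$ids)] /
    tr$stoich$d[match("h_lum_mp", tr$stoich$ids)]
  atp <- tr$stoich$n[match("atp_mp", tr$stoich$ids)] /
    tr$stoich$d[match("atp_mp", tr$stoich$ids)]
  h / atp
}

#' Locate the self-sufficiency crossing of the plastid ATP balance
#'
#' Scans the FQR/FNR ratio and brackets the ratio at which the net plastid
#' ATP exchange fraction crosses zero (negative slope expected).
#'
#' @param net the packaged model.
#' @param ratios scan grid.
#' @param pr_multiplier photorespiration multiplier.
#' @return list with the scan `table`, `bracket` (c(lo, hi)) and `estimate`
#'   (linear interpolation), or `NULL` bracket if no crossing.
#' @export
atp_crossing <- function(net, ratios = seq(0, 0.5, by = 0.05),
                         pr_multiplier = 0.25) {
  scan <- scan_fqr_fnr(net, ratios, pr_multiplier)
  tb <- scan$table
  est <- bracket <- NULL
  fr <- tb$atp_fraction
  for (k in seq_len(nrow(tb) - 1)) {
    if (!is.na(fr[k]) && !is.na(fr[k + 1]) &&
        fr[k] > 0 && fr[k + 1] <= 0) {
      bracket <- c(tb$ratio[k], tb$ratio[k + 1])
      est <- tb$ratio[k] + (tb$ratio[k + 1] - tb$ratio[k]) *
        fr[k] / (fr[k] - fr[k + 1])
      break
    }
  }
  list(table = tb, bracket = bracket, estimate = est)
}
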