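# Synthetic fixtures with verified ground truth: random balanced networks
# with planted conserved moieties and internal cycles, LPs with constructed
# optima certified by a dual solution, and a miniature three-tissue plant.
# All generators are pure functions of their seed.

#' Specification for a synthetic network
#'
#' @param seed integer seed.
#' @param n_species number of core (balanced) species.
#' @param n_reactions number of random conversion reactions.
#' @param planted_moieties number of planted carrier pairs (each adds two
#'   species `Mk`, `Mk*` whose sum is conserved).
#' @param planted_cycles number of planted independent internal cycles.
#' @param exchange_count number of exchange (source/sink) transformers.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_species = 8L, n_reactions = 10L,
                           planted_moieties = 1L, planted_cycles = 1L,
                           exchange_count = 2L) {
  stopifnot(n_species >= 2, n_reactions >= 1, planted_moieties >= 0,
            planted_cycles >= 0, exchange_count >= 1)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_reactions = as.integer(n_reactions),
                 planted_moieties = as.integer(planted_moieties),
                 planted_cycles = as.integer(planted_cycles),
                 exchange_count = as.integer(exchange_count)),
            class = "synthetic_spec")
}

#' Generate a random balanced network with planted structure
#'
#' Core species are built over abstract elements (`E1`, `E2`, ...) so that
#' every reaction is elementally balanced by construction: each reaction
#' converts one species into another of identical composition class, or
#' splits/joins compositions additively.  Planted moiety pairs are carrier
#' couples (`Mk`/`Mk*`) attached to random reactions (consumed on one side,
#' regenerated on the other), so the pair total is conserved.  Planted
#' cycles are duplicated-route loops (a second, distinct path with the same
#' net conversion), each raising the internal nullspace dimension by one.
#' Ground truth is verified by direct substitution before returning.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `network` (a `pf_network`) and `truth` (planted
#'   moieties as weight vectors; `inner_df` = number of planted cycles).
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in 0:19) {
    sp2 <- spec
    sp2$seed <- spec$seed + 1000L * attempt
    out <- .gen_network_once(sp2)
    if (!is.null(out)) {
      if (attempt > 0)
        message(sprintf("gen_network: degenerate draw, advanced seed to %d",
                        sp2$seed))
      return(out)
    }
  }
  stop("gen_network: could not realise spec in 20 attempts", call. = FALSE)
}

.gen_network_once <- function(spec) {
  set.seed(spec$seed)
  ns <- spec$n_species
  # Abstract compositions: species S_i carries (i x E1, 1 x E2); the monomer
  # M0 carries one E1.  A conversion S_a -> S_b +/- (a-b) M0 is balanced by
  # construction.  Because every conversion is E-balanced, ANY undirected
  # cycle among conversion edges would be an internal flux cycle; the
  # conversions are therefore drawn as edges of a random tree, so the
  # planted cycles are exactly the internal cycles.
  comps <- list(compartment("env", kind = "environment"),
                compartment("cell", kind = "cytoplasm"))
  sp <- list(species("M0", "cell", make_formula(c(E1 = 1))))
  for (i in seq_len(ns))
    sp[[length(sp) + 1L]] <- species(paste0("S", i), "cell",
                                     make_formula(c(E1 = i, E2 = 1)))
  trs <- list()
  rid <- 0L
  addr <- function(st, reversible = FALSE, kind = "reaction") {
    rid <<- rid + 1L
    trs[[length(trs) + 1L]] <<- transformer(sprintf("R%02d", rid), st,
                                            kind = kind,
                                            reversible = reversible)
  }
  # random spanning tree (random attachment order)
  order_ <- sample.int(ns)
  tree <- matrix(0L, 0, 2)
  for (i in 2:ns) {
    a <- order_[sample.int(i - 1L, 1L)]
    b <- order_[i]
    tree <- rbind(tree, sort(c(a, b)))
  }
  n_conv <- min(spec$n_reactions, nrow(tree))
  used <- tree[seq_len(n_conv), , drop = FALSE]
  for (k in seq_len(n_conv)) {
    a <- used[k, 1]; b <- used[k, 2]
    if (stats::runif(1) < 0.5) { t <- a; a <- b; b <- t }
    st <- stats::setNames(c(-1, 1), paste0("S", c(a, b)))
    d <- b - a
    if (d != 0) st["M0"] <- -d
    addr(st, reversible = stats::runif(1) < 0.3)
  }
  # planted moiety pairs Mk/Mk*: the loaded form donates an E1 monomer
  # internally (Mk -> Mk* + M0) and is re-loaded at the boundary
  # (Mk* + X_M -> Mk, an exchange step, so the pair cannot close an
  # internal cycle).  The pair total is conserved by every transformer.
  if (spec$planted_moieties > 0)
    sp[[length(sp) + 1L]] <- species("X_M", "env", balanced = FALSE)
  truth_moieties <- list()
  for (k in seq_len(spec$planted_moieties)) {
    ca <- paste0("M", k); cb <- paste0("M", k, "s")
    sp[[length(sp) + 1L]] <- species(ca, "cell",
                                     make_formula(c(E3 = k, E1 = 1)))
    sp[[length(sp) + 1L]] <- species(cb, "cell", make_formula(c(E3 = k)))
    addr(stats::setNames(c(-1, 1, 1), c(ca, cb, "M0")))
    addr(stats::setNames(c(-1, -1, 1), c(cb, "X_M", ca)),
         kind = "transport")
    truth_moieties[[length(truth_moieties) + 1L]] <-
      stats::setNames(c(1, 1), c(ca, cb))
  }
  # exchanges: M0 source plus sinks (surplus requested reactions become
  # extra exchange sinks; exchange columns never contribute to inner df)
  sp[[length(sp) + 1L]] <- species("X_in", "env", balanced = FALSE)
  sp[[length(sp) + 1L]] <- species("X_out", "env", balanced = FALSE)
  addr(c(X_in = -1, M0 = 1), kind = "transport")
  n_sink <- max(1L, spec$exchange_count - 1L) +
    max(0L, spec$n_reactions - n_conv)
  for (k in seq_len(n_sink)) {
    tgt <- paste0("S", sample.int(ns, 1))
    addr(stats::setNames(c(-1, 1), c(tgt, "X_out")), kind = "transport")
  }
  # planted cycles: an exact duplicate of an internal conversion
  internal <- which(vapply(trs, function(t)
    t$kind == "reaction" && startsWith(t$stoich$ids[1], "S"), TRUE))
  if (!length(internal)) return(NULL)
  for (k in seq_len(spec$planted_cycles)) {
    pick <- trs[[internal[1 + (k - 1) %% length(internal)]]]
    st <- stats::setNames(pick$stoich$n / pick$stoich$d, pick$stoich$ids)
    trs[[length(trs) + 1L]] <- transformer(sprintf("C%02d", k), st,
                                           kind = "reaction",
                                           reversible = TRUE)
  }
  net <- network(comps, sp, trs)
  # verify ground truth by direct substitution
  sm <- stoich_matrix(net)
  for (w in truth_moieties) {
    wv <- numeric(length(sm$species))
    wv[match(names(w), sm$species)] <- w
    resid <- as.numeric(t(wv) %*% (sm$S$n / sm$S$d))
    if (any(abs(resid) > 0))
      stop("generator postcondition failed: planted moiety not conserved",
           call. = FALSE)
  }
  dof <- degrees_of_freedom(sm)
  if (dof$inner != spec$planted_cycles) return(NULL)  # degenerate: redraw
  list(network = net,
       truth = list(moieties = truth_moieties,
                    inner_df = spec$planted_cycles))
}

#' Generate an LP with a constructed known optimum
#'
#' Builds a bounded feasible network LP whose optimum is known by
#' construction: a linear chain with one capped uptake and a maximised
#' terminal flux, with random positive conversion yields.  The optimal
#' vertex saturates the uptake cap; the certifying dual is the chain of
#' yield products.  Verified by substitution before returning.
#'
#' @param seed integer seed; @param size number of chained reactions (>= 2).
#' @return list with `network`, `scenario`, `truth` (list: `optimum`,
#'   `vertex` named flux vector, `dual` bound).
#' @export
gen_lp <- function(seed = 1L, size = 4L) {
  stopifnot(size >= 2)
  set.seed(seed)
  comps <- list(compartment("env", kind = "environment"),
                compartment("cell", kind = "cytoplasm"))
  # yields as small rationals p/q <= 2
  pq <- cbind(sample(1:4, size, TRUE), sample(2:4, size, TRUE))
  sp <- list(species("N0", "env", balanced = FALSE))
  for (i in seq_len(size)) sp[[length(sp) + 1L]] <-
    species(paste0("A", i), "cell", make_formula(c(E1 = 1)))
  sp[[length(sp) + 1L]] <- species("Nend", "env", balanced = FALSE)
  trs <- list(transformer("up", c(N0 = -1, A1 = 1), kind = "transport"))
  for (i in seq_len(size - 1L)) {
    st <- stats::setNames(c("-1", sprintf("%d/%d", pq[i, 1], pq[i, 2])),
                          paste0("A", c(i, i + 1L)))
    trs[[length(trs) + 1L]] <- transformer(sprintf("r%d", i), st)
  }
  trs[[length(trs) + 1L]] <- transformer("out",
                                         c(stats::setNames(-1, paste0("A", size)),
                                           Nend = 1), kind = "transport")
  net <- network(comps, sp, trs)
  cap <- sample(5:20, 1)
  sc <- parse_scenario(sprintf("objective: max out\nup <= %d", cap), net,
                       name = sprintf("genlp_seed%d", seed))
  yield <- prod(pq[seq_len(size - 1L), 1] / pq[seq_len(size - 1L), 2])
  vertex <- c(up = cap)
  acc <- cap
  for (i in seq_len(size - 1L)) {
    vertex[sprintf("r%d", i)] <- acc
    acc <- acc * pq[i, 1] / pq[i, 2]
  }
  vertex["out"] <- acc
  optimum <- cap * yield
  # direct verification: S v = 0 and objective value
  sm <- stoich_matrix(net)
  v <- vertex[sm$transformers]
  resid <- max(abs(as.numeric((sm$S$n / sm$S$d) %*% v)))
  if (resid > 1e-9 || abs(acc - optimum) > 1e-9)
    stop("generator postcondition failed for LP fixture", call. = FALSE)
  list(network = net, scenario = sc,
       truth = list(optimum = optimum, vertex = vertex,
                    dual = list(cap = cap, shadow_price = yield)))
}

#' Miniature three-tissue plant fixture
#'
#' A ~30-transformer source/connector/sink model sharing the full model's
#' mechanism: photon-driven sugar synthesis in the source, SWEET-type
#' proton-independent efflux, sucrose-proton symport influx, plasma-membrane
#' H+-ATPase, respiration and biomass formation in source and sink.  Runs
#' through every analysis stage in well under a second.
#'
#' @param seed unused (construction is deterministic); kept for interface
#'   symmetry with the other generators.
#' @return a `pf_network`.
#' @export
toy_plant <- function(seed = NULL) {
  comps <- list(
    compartment("env", kind = "environment", ph_rank = 1L),
    compartment("apo", kind = "apoplast", ph_rank = 1L),
    compartment("src", kind = "cytoplasm", ph_rank = 3L),
    compartment("con", kind = "phloem", ph_rank = 3L),
    compartment("snk", kind = "cytoplasm", ph_rank = 3L))
  met <- function(base, comp, f, chg = 0)
    species(paste0(base, "_", comp), comp, make_formula(f, chg))
  sp <- list(
    species("hv_env", "env", balanced = FALSE),
    species("co2_env", "env", balanced = FALSE),
    species("o2_env", "env", balanced = FALSE),
    species("h2o_env", "env", balanced = FALSE),
    species("h_env", "env", balanced = FALSE),
    species("bm_env", "env", balanced = FALSE),
    met("hv", "src", numeric(0)),
    met("suc", "src", c(C = 12, H = 22, O = 11)),
    met("suc", "apo", c(C = 12, H = 22, O = 11)),
    met("suc", "con", c(C = 12, H = 22, O = 11)),
    met("suc", "snk", c(C = 12, H = 22, O = 11)),
    met("h", "src", c(H = 1), 1), met("h", "apo", c(H = 1), 1),
    met("h", "con", c(H = 1), 1), met("h", "snk", c(H = 1), 1),
    met("atp", "src", c(C = 10, H = 12, N = 5, O = 13, P = 3), -4),
    met("adp", "src", c(C = 10, H = 12, N = 5, O = 10, P = 2), -3),
    met("pi", "src", c(H = 1, O = 4, P = 1), -2),
    met("atp", "snk", c(C = 10, H = 12, N = 5, O = 13, P = 3), -4),
    met("adp", "snk", c(C = 10, H = 12, N = 5, O = 10, P = 2), -3),
    met("pi", "snk", c(H = 1, O = 4, P = 1), -2),
    met("co2", "src", c(C = 1, O = 2)), met("o2", "src", c(O = 2)),
    met("h2o", "src", c(H = 2, O = 1)),
    met("co2", "snk", c(C = 1, O = 2)), met("o2", "snk", c(O = 2)),
    met("h2o", "snk", c(H = 2, O = 1)),
    met("o2", "apo", c(O = 2)), met("co2", "apo", c(C = 1, O = 2)),
    met("bm", "src", c(C = 12, H = 22, O = 11)),
    met("bm", "snk", c(C = 12, H = 22, O = 11)))
  r <- list()
  add <- function(id, eq, kind = "reaction") {
    pe <- parse_equation(eq)
    r[[length(r) + 1L]] <<- transformer(id, pe$stoich, kind = kind,
                                        reversible = pe$reversible)
  }
  add("T.hv", "hv_env -> hv_src", "transport")
  add("T.co2.src", "co2_env <-> co2_src", "transport")
  add("T.o2.src", "o2_env <-> o2_src", "transport")
  add("T.h2o.src", "h2o_env <-> h2o_src", "transport")
  # photosynthesis lump: 12 CO2 + 11 H2O + 60 hv -> sucrose + 12 O2
  add("PS", "12 co2_src + 11 h2o_src + 60 hv_src -> suc_src + 12 o2_src")
  # photophosphorylation lump: 2 hv drive 1 ATP
  add("PP", "2 hv_src + adp_src + pi_src + h_src -> atp_src + h2o_src")
  # respiration lump with substrate-level ATP yield 30 per sucrose
  add("RESP.src", paste("suc_src + 12 o2_src + 30 adp_src + 30 pi_src + 30 h_src ->",
                        "12 co2_src + 30 atp_src + 41 h2o_src"))
  add("RESP.snk", paste("suc_snk + 12 o2_snk + 30 adp_snk + 30 pi_snk + 30 h_snk ->",
                        "12 co2_snk + 30 atp_snk + 41 h2o_snk"))
  # biomass: sucrose + ATP cost, per tissue
  add("GROW.src", "suc_src + 2 atp_src + 2 h2o_src -> bm_src + 2 adp_src + 2 pi_src + 2 h_src",
      "polymerization")
  add("GROW.snk", "suc_snk + 2 atp_snk + 2 h2o_snk -> bm_snk + 2 adp_snk + 2 pi_snk + 2 h_snk",
      "polymerization")
  add("T.bm.src", "bm_src -> bm_env", "transport")
  add("T.bm.snk", "bm_snk -> bm_env", "transport")
  add("ATPM.src", "atp_src + h2o_src -> adp_src + pi_src + h_src")
  add("ATPM.snk", "atp_snk + h2o_snk -> adp_snk + pi_snk + h_snk")
  # sucrose translocation: SWEET efflux, proton symport influx
  add("SWEET.src", "suc_src -> suc_apo", "transport")
  add("SUC.con", "suc_apo + h_apo -> suc_con + h_con", "transport")
  add("SWEET.con", "suc_con -> suc_apo", "transport")
  add("SUC.snk", "suc_apo + h_apo -> suc_snk + h_snk", "transport")
  add("HATP.src", "atp_src + h2o_src -> adp_src + pi_src + h_apo", "transport")
  add("HATP.snk", "atp_snk + h2o_snk -> adp_snk + pi_snk + h_env", "transport")
  add("T.h.con.snk", "h_con <-> h_snk", "transport")
  add("T.h.con.src", "h_con -> h_src", "transport")
  # the sink (root-like) tissue takes up protons from the acidic medium
  add("T.h.env.snk", "h_env -> h_snk", "transport")
  # sink gas/water paths
  add("T.o2.apo", "o2_src <-> o2_apo", "transport")
  add("T.o2.snk", "o2_apo <-> o2_snk", "transport")
  add("T.co2.apo", "co2_snk <-> co2_apo", "transport")
  add("T.co2.apo2", "co2_apo <-> co2_src", "transport")
  add("T.h2o.snk", "h2o_env <-> h2o_snk", "transport")
  net <- tryCatch(network(comps, sp, r), error = function(e) stop(e))
  net
}

#' Scenario presets for the toy plant
#' @param name "light" or "dark" (dark zeroes photon uptake; the toy has no
#'   starch, so dark growth is infeasible by design — it exists to exercise
#'   infeasibility handling).
#' @param net optional toy network for validation.
#' @export
toy_scenario <- function(name = c("light", "dark"), net = NULL) {
  name <- match.arg(name)
  lines <- c("objective: max T.bm.snk", "T.bm.snk <= 10")
  if (name == "dark") lines <- c(lines, "T.hv = 0")
  parse_scenario(paste(lines, collapse = "\n"), net = net,
                 name = paste0("toy_", name))
}
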