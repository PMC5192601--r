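# Flux balance analysis: scenario mini-language, LP formulation, pfba, FVA,
# FQR/FNR parameter scans.  LPs are solved with the bundled SciPy/HiGHS
# helper; formulation, staging and certification happen here.

.LP_INF <- 1e30

# ---- scenario -------------------------------------------------------------

#' Create a flux scenario
#'
#' A scenario holds the objective `Z = c'v`, flux bounds and additional
#' linear constraints applied on top of `S v = 0` and the reversibility
#' bounds of the network.
#'
#' @param name label.
#' @param objective named numeric weights (typically one biomass flux).
#' @param maximize logical.
#' @param bounds named list: flux id -> c(lb, ub).
#' @param constraints list of `list(terms = <named character rationals>,
#'   rel = "="|"<="|">=", rhs = <character rational>)`.
#' @export
scenario_new <- function(name = "custom", objective = numeric(0),
                         maximize = TRUE, bounds = list(),
                         constraints = list()) {
  structure(list(name = name, objective = objective, maximize = maximize,
                 bounds = bounds, constraints = constraints),
            class = "pf_scenario")
}

#' Parse the scenario constraint mini-language
#'
#' One statement per line: either `objective: max FLUX`, or a linear
#' statement `<combo> (=|<=|>=) <number>` where `<combo>` is a signed sum of
#' `coef*FLUX` or bare `FLUX` terms.  Coefficients and right-hand sides are
#' kept exact (decimals are exact base-10 fractions).  Single-flux
#' statements with unit coefficient become bounds (intersected with the
#' network's reversibility bounds); everything else becomes a constraint
#' row.
#'
#' @param text scenario text (lines; `#` comments allowed).
#' @param net optional `pf_network` used to validate flux ids.
#' @param name scenario label.
#' @return a `pf_scenario`.
#' @export
parse_scenario <- function(text, net = NULL, name = "parsed") {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  sc <- scenario_new(name = name)
  known <- if (!is.null(net)) names(net$transformers) else NULL
  check_id <- function(id, lineno) {
    if (!is.null(known) && !(id %in% known))
      stop(sprintf("line %d: unknown flux '%s'", lineno, id), call. = FALSE)
    id
  }
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^objective\\s*:", line)) {
      m <- regmatches(line, regexec(
        "^objective\\s*:\\s*(max|min)\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) != 3L)
        stop(sprintf("line %d: malformed objective statement", ln),
             call. = FALSE)
      sc$objective <- stats::setNames(1, check_id(m[3], ln))
      sc$maximize <- m[2] == "max"
      next
    }
    m <- regmatches(line, regexec("^(.*?)(<=|>=|=)\\s*([-+0-9./eE]+)\\s*$",
                                  line))[[1]]
    if (length(m) != 4L)
      stop(sprintf("line %d: malformed statement '%s'", ln, line),
           call. = FALSE)
    rel <- m[3]
    rhs <- tryCatch(rq_parse(m[4]), error = function(e)
      stop(sprintf("line %d: bad number '%s'", ln, m[4]), call. = FALSE))
    lhs <- trimws(m[2])
    # tokenize signed terms
    toks <- regmatches(lhs, gregexpr(
      "[+-]?\\s*(?:[0-9][0-9./eE+-]*\\s*\\*\\s*)?[A-Za-z_][A-Za-z0-9._!]*",
      lhs, perl = TRUE))[[1]]
    toks <- trimws(toks)
    if (!length(toks) || nchar(paste(gsub("\\s", "", toks), collapse = "")) !=
        nchar(gsub("\\s", "", lhs)))
      stop(sprintf("line %d: cannot parse terms in '%s'", ln, lhs),
           call. = FALSE)
    terms <- character(0)
    for (tk in toks) {
      sign <- if (startsWith(tk, "-")) -1 else 1
      tk <- sub("^[+-]\\s*", "", tk)
      parts <- strsplit(tk, "\\s*\\*\\s*")[[1]]
      if (length(parts) == 2L) {
        coef <- rq_parse(parts[1]); id <- parts[2]
      } else {
        coef <- rq_scalar(1); id <- parts[1]
      }
      check_id(id, ln)
      coef$n <- coef$n * sign
      if (id %in% names(terms)) {
        coef <- rq_add(rq_parse(terms[[id]]), coef)
      }
      terms[id] <- rq_format(coef)
    }
    if (length(terms) == 1L && terms[[1]] == "1") {
      id <- names(terms)[1]
      b <- sc$bounds[[id]]
      if (is.null(b)) b <- c(-Inf, Inf)
      val <- rq_as_numeric(rhs)
      if (rel %in% c("=", "<=")) b[2] <- min(b[2], val)
      if (rel %in% c("=", ">=")) b[1] <- max(b[1], val)
      sc$bounds[[id]] <- b
    } else {
      sc$constraints[[length(sc$constraints) + 1L]] <-
        list(terms = terms, rel = rel, rhs = rq_format(rhs))
    }
  }
  sc
}

#' Serialise a scenario back to the mini-language
#' @param sc a `pf_scenario`.
#' @export
format_scenario <- function(sc) {
  out <- character(0)
  if (length(sc$objective))
    out <- c(out, sprintf("objective: %s %s",
                          if (sc$maximize) "max" else "min",
                          names(sc$objective)[1]))
  for (id in names(sc$bounds)) {
    b <- sc$bounds[[id]]
    if (is.finite(b[1]) && is.finite(b[2]) && b[1] == b[2]) {
      out <- c(out, sprintf("%s = %s", id, format(b[1])))
    } else {
      if (is.finite(b[1])) out <- c(out, sprintf("%s >= %s", id, format(b[1])))
      if (is.finite(b[2])) out <- c(out, sprintf("%s <= %s", id, format(b[2])))
    }
  }
  for (cn in sc$constraints) {
    lhs <- paste(vapply(seq_along(cn$terms), function(k) {
      co <- cn$terms[[k]]; id <- names(cn$terms)[k]
      pre <- if (k == 1) "" else if (startsWith(co, "-")) " - " else " + "
      if (k > 1) co <- sub("^-", "", co)
      if (co == "1") paste0(pre, id) else paste0(pre, co, "*", id)
    }, ""), collapse = "")
    out <- c(out, sprintf("%s %s %s", lhs,
                          if (cn$rel == "=") "=" else cn$rel, cn$rhs))
  }
  paste(out, collapse = "\n")
}

#' @export
print.pf_scenario <- function(x, ...) {
  cat(sprintf("<pf_scenario> %s\n%s\n", x$name, format_scenario(x)))
  invisible(x)
}

# ---- LP backend -----------------------------------------------------------

.pf_python <- function() {
  opt <- getOption("plantflux.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found for the LP backend", call. = FALSE)
}

.pf_lpserve <- function() {
  p <- system.file("python", "lpserve.py", package = "plantflux")
  if (!nzchar(p)) stop("lpserve.py helper not found", call. = FALSE)
  p
}

# problems: list of list(ncol, rows=list(i,j,x), sense, rhs, lb, ub,
#                        objectives=list(list(c, maximize)))
lp_solve_batch <- function(problems) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- list(problems = lapply(problems, function(p) {
    list(ncol = jsonlite::unbox(p$ncol),
         rows = list(i = as.integer(p$rows$i), j = as.integer(p$rows$j),
                     x = as.numeric(p$rows$x)),
         sense = as.character(p$sense), rhs = as.numeric(p$rhs),
         lb = pmax(p$lb, -.LP_INF), ub = pmin(p$ub, .LP_INF),
         objectives = lapply(p$objectives, function(o)
           list(c = as.numeric(o$c), maximize = jsonlite::unbox(isTRUE(o$maximize)))))
  }))
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = FALSE)
  ret <- system2(.pf_python(), c(.pf_lpserve(), fin, fout),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout) || length(attr(ret, "status")))
    stop("LP backend failed: ", paste(ret, collapse = "\n"), call. = FALSE)
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

# Build the base LP for a network+scenario.
# Returns list(ncol, ids, rows, sense, rhs, lb, ub, c, maximize)
build_lp <- function(net, scenario, sm = NULL) {
  if (is.null(sm)) sm <- stoich_matrix(net)
  ids <- sm$transformers
  n <- length(ids)
  lb <- ifelse(sm$reversible, -Inf, 0)
  ub <- rep(Inf, n)
  for (id in names(scenario$bounds)) {
    k <- match(id, ids)
    if (is.na(k)) stop(sprintf("unknown flux '%s' in scenario bounds", id),
                       call. = FALSE)
    b <- scenario$bounds[[id]]
    lb[k] <- max(lb[k], b[1]); ub[k] <- min(ub[k], b[2])
  }
  if (any(lb > ub))
    warning("scenario bounds cross for: ",
            paste(ids[lb > ub], collapse = ", "))
  Sd <- sm$S$n / sm$S$d
  nz <- which(Sd != 0, arr.ind = TRUE)
  rows <- list(i = nz[, 1], j = nz[, 2], x = Sd[nz])
  m <- length(sm$species)
  sense <- rep("E", m)
  rhs <- rep(0, m)
  for (cn in scenario$constraints) {
    m <- m + 1L
    for (k in seq_along(cn$terms)) {
      id <- names(cn$terms)[k]
      col <- match(id, ids)
      if (is.na(col))
        stop(sprintf("unknown flux '%s' in scenario constraint", id),
             call. = FALSE)
      rows$i <- c(rows$i, m); rows$j <- c(rows$j, col)
      rows$x <- c(rows$x, rq_as_numeric(rq_parse(cn$terms[[k]])))
    }
    sense <- c(sense, switch(cn$rel, "=" = "E", "<=" = "L", ">=" = "G"))
    rhs <- c(rhs, rq_as_numeric(rq_parse(cn$rhs)))
  }
  cvec <- numeric(n)
  for (id in names(scenario$objective)) {
    col <- match(id, ids)
    if (is.na(col)) stop(sprintf("unknown objective flux '%s'", id),
                         call. = FALSE)
    cvec[col] <- scenario$objective[[id]]
  }
  list(ncol = n, ids = ids, rows = rows, sense = sense, rhs = rhs,
       lb = lb, ub = ub, c = cvec, maximize = isTRUE(scenario$maximize),
       n_species_rows = length(sm$species))
}

.lp_to_problem <- function(lp, objectives = NULL) {
  if (is.null(objectives))
    objectives <- list(list(c = lp$c, maximize = lp$maximize))
  list(ncol = lp$ncol, rows = lp$rows, sense = lp$sense, rhs = lp$rhs,
       lb = lp$lb, ub = lp$ub, objectives = objectives)
}

.as_solution <- function(res, lp, scenario_name = "") {
  status <- res$status
  if (status != "optimal")
    return(structure(list(status = status, objective_value = NA_real_,
                          fluxes = NULL, variability = NULL,
                          duality_gap = NA_real_, scenario = scenario_name),
                     class = "flux_solution"))
  x <- as.numeric(unlist(res$x))
  names(x) <- lp$ids
  gap <- NA_real_
  if (!is.null(res$dual_objective) && !is.na(res$dual_objective)) {
    gap <- abs(res$objective - res$dual_objective) /
      max(1, abs(res$objective))
  }
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = x, variability = NULL, duality_gap = gap,
                 scenario = scenario_name),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s (%s): objective %s\n", x$scenario,
              x$status,
              if (is.na(x$objective_value)) "-" else
                format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Solve a flux balance problem
#'
#' Maximises (or minimises) the scenario objective over
#' `{v : S v = 0, bounds, scenario constraints}`.  The solution carries the
#' relative primal-dual gap as an optimality certificate.
#'
#' @param net a `pf_network`.
#' @param scenario a `pf_scenario` (see [scenario_new()], [parse_scenario()]).
#' @param sm optional precomputed `stoich_matrix`.
#' @return a `flux_solution` with `status`, `objective_value`, `fluxes`.
#' @export
solve_fba <- function(net, scenario, sm = NULL) {
  lp <- build_lp(net, scenario, sm = sm)
  res <- lp_solve_batch(list(.lp_to_problem(lp)))[[1]][[1]]
  sol <- .as_solution(res, lp, scenario$name)
  if (sol$status == "optimal") .check_steady_state(net, sol, sm = sm)
  sol
}

.check_steady_state <- function(net, sol, sm = NULL, tol = 1e-6) {
  if (is.null(sm)) sm <- stoich_matrix(net)
  Sd <- sm$S$n / sm$S$d
  resid <- as.numeric(Sd %*% sol$fluxes[sm$transformers])
  scale <- max(1, max(abs(sol$fluxes)))
  if (max(abs(resid)) > tol * scale)
    warning(sprintf("steady-state residual %.3g exceeds tolerance",
                    max(abs(resid))))
  invisible(max(abs(resid)))
}

#' Parsimonious FBA
#'
#' Two-stage LP: fix the scenario optimum, then minimise the total absolute
#' flux.  All reported ratios and ledgers in this package are computed from
#' pfba solutions so that degenerate optima (e.g. futile cycles) do not leak
#' into reported numbers.
#'
#' @inheritParams solve_fba
#' @param tol relative slack allowed on the stage-1 objective.
#' @return a `flux_solution`; `objective_value` is the stage-1 optimum,
#'   `total_flux` the minimised L1 norm.
#' @export
pfba <- function(net, scenario, sm = NULL, tol = 1e-9) {
  if (is.null(sm)) sm <- stoich_matrix(net)
  lp <- build_lp(net, scenario, sm = sm)
  stage1 <- lp_solve_batch(list(.lp_to_problem(lp)))[[1]][[1]]
  if (stage1$status != "optimal")
    return(.as_solution(stage1, lp, scenario$name))
  zstar <- stage1$objective
  n <- lp$ncol
  # augmented LP: variables [v, t], t >= |v|, minimise sum t
  lp2 <- lp
  lp2$ncol <- 2L * n
  lp2$lb <- c(lp$lb, rep(0, n))
  lp2$ub <- c(lp$ub, rep(Inf, n))
  m0 <- max(c(lp$rows$i, 0)) # rows so far
  nextrow <- max(length(lp$sense), m0)
  ri <- lp$rows$i; rj <- lp$rows$j; rx <- lp$rows$x
  sense <- lp$sense; rhs <- lp$rhs
  # objective-fixing row: c'v >= z* - slack (maximise) / <= z* + slack
  nextrow <- nextrow + 1L
  nzc <- which(lp$c != 0)
  ri <- c(ri, rep(nextrow, length(nzc))); rj <- c(rj, nzc)
  rx <- c(rx, lp$c[nzc])
  slack <- tol * max(1, abs(zstar))
  if (lp$maximize) {
    sense <- c(sense, "G"); rhs <- c(rhs, zstar - slack)
  } else {
    sense <- c(sense, "L"); rhs <- c(rhs, zstar + slack)
  }
  # t - v >= 0 and t + v >= 0
  for (k in seq_len(n)) {
    nextrow <- nextrow + 1L
    ri <- c(ri, nextrow, nextrow); rj <- c(rj, k, n + k)
    rx <- c(rx, -1, 1); sense <- c(sense, "G"); rhs <- c(rhs, 0)
    nextrow <- nextrow + 1L
    ri <- c(ri, nextrow, nextrow); rj <- c(rj, k, n + k)
    rx <- c(rx, 1, 1); sense <- c(sense, "G"); rhs <- c(rhs, 0)
  }
  lp2$rows <- list(i = ri, j = rj, x = rx)
  lp2$sense <- sense; lp2$rhs <- rhs
  obj2 <- list(c = c(numeric(n), rep(1, n)), maximize = FALSE)
  res2 <- lp_solve_batch(list(.lp_to_problem(lp2, list(obj2))))[[1]][[1]]
  if (res2$status != "optimal")
    stop("pfba stage 2 failed with status ", res2$status, call. = FALSE)
  x <- as.numeric(unlist(res2$x))[seq_len(n)]
  # clean numerical dust
  x[abs(x) < 1e-9] <- 0
  names(x) <- lp$ids
  sol <- structure(list(status = "optimal", objective_value = zstar,
                        fluxes = x, variability = NULL,
                        duality_gap = .as_solution(stage1, lp)$duality_gap,
                        total_flux = res2$objective,
                        scenario = scenario$name),
                   class = "flux_solution")
  .check_steady_state(net, sol, sm = sm)
  sol
}

#' Flux variability analysis
#'
#' Per-flux minimum and maximum holding the objective at
#' `>= fraction * optimum` (for maximisation scenarios).
#'
#' @inheritParams solve_fba
#' @param fraction fraction of the optimum to hold (in (0, 1]).
#' @param transformers subset of flux ids (default: all).
#' @return data.frame with columns id, min, max.
#' @export
fva <- function(net, scenario, fraction = 1, transformers = NULL, sm = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(sm)) sm <- stoich_matrix(net)
  lp <- build_lp(net, scenario, sm = sm)
  has_obj <- any(lp$c != 0)
  if (has_obj) {
    base <- lp_solve_batch(list(.lp_to_problem(lp)))[[1]][[1]]
    if (base$status != "optimal")
      stop("FVA base problem status: ", base$status, call. = FALSE)
    zstar <- base$objective
    nextrow <- length(lp$sense) + 1L
    nzc <- which(lp$c != 0)
    lp$rows$i <- c(lp$rows$i, rep(nextrow, length(nzc)))
    lp$rows$j <- c(lp$rows$j, nzc)
    lp$rows$x <- c(lp$rows$x, lp$c[nzc])
    off <- 1e-9 * max(1, abs(zstar))
    if (lp$maximize) {
      lp$sense <- c(lp$sense, "G"); lp$rhs <- c(lp$rhs, fraction * zstar - off)
    } else {
      lp$sense <- c(lp$sense, "L"); lp$rhs <- c(lp$rhs, fraction * zstar + off)
    }
  }
  if (is.null(transformers)) transformers <- lp$ids
  cols <- match(transformers, lp$ids)
  if (anyNA(cols)) stop("unknown flux id in FVA request", call. = FALSE)
  objectives <- list()
  for (k in cols) {
    cv <- numeric(lp$ncol); cv[k] <- 1
    objectives[[length(objectives) + 1L]] <- list(c = cv, maximize = FALSE)
    objectives[[length(objectives) + 1L]] <- list(c = cv, maximize = TRUE)
  }
  res <- lp_solve_batch(list(.lp_to_problem(lp, objectives)))[[1]]
  mins <- maxs <- numeric(length(cols))
  for (q in seq_along(cols)) {
    rmin <- res[[2 * q - 1L]]; rmax <- res[[2 * q]]
    mins[q] <- if (rmin$status == "optimal") rmin$objective else
      if (rmin$status == "unbounded") -Inf else NA_real_
    maxs[q] <- if (rmax$status == "optimal") rmax$objective else
      if (rmax$status == "unbounded") Inf else NA_real_
  }
  data.frame(id = transformers, min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

#' Blocked transformers
#'
#' Transformers whose flux is forced to zero (FVA min and max both zero)
#' under steady state, reversibility bounds and, optionally, a scenario's
#' constraints.
#'
#' @param net a `pf_network`.
#' @param scenario optional `pf_scenario`; `NULL` probes the bare network.
#' @param tol numeric zero tolerance.
#' @return character vector of transformer ids.
#' @export
blocked_transformers <- function(net, scenario = NULL, tol = 1e-9) {
  if (is.null(scenario)) scenario <- scenario_new(name = "none",
                                                  objective = numeric(0))
  ranges <- fva(net, scenario)
  if (anyNA(ranges$min) || anyNA(ranges$max))
    stop("infeasible base problem in blocked-transformer probe",
         call. = FALSE)
  ranges$id[abs(ranges$min) <= tol & abs(ranges$max) <= tol &
              is.finite(ranges$min) & is.finite(ranges$max)]
}

#' Scan the cyclic/non-cyclic electron flow ratio
#'
#' Solves pfba on the light scenario across a grid of FQR/FNR ratios
#' (constraint `r*FNR - FQR = 0`) at a fixed photorespiration multiplier,
#' and reports the plastid ATP/NADPH exchange fractions per ratio.
#'
#' @param net the packaged plant model.
#' @param ratios numeric vector in [0, 0.5].
#' @param pr_multiplier photorespiration coupling multiplier (RPC2 =
#'   pr_multiplier * RPC).
#' @return list with `table` (data.frame: ratio, status, objective,
#'   atp_fraction, nadph_fraction, photon_per_co2) and `solutions`.
#' @export
scan_fqr_fnr <- function(net, ratios = seq(0, 0.5, by = 0.1),
                         pr_multiplier = 0.25) {
  stopifnot(all(ratios >= 0), all(ratios <= 0.5 + 1e-12))
  sm <- stoich_matrix(net)
  sols <- vector("list", length(ratios))
  rows <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    sc <- plant_scenario("light", ratio = ratios[k], pr = pr_multiplier)
    sol <- tryCatch(pfba(net, sc, sm = sm), error = function(e) e)
    if (inherits(sol, "error") || sol$status != "optimal") {
      rows[[k]] <- data.frame(ratio = ratios[k], status = "infeasible",
                              objective = NA_real_, atp_fraction = NA_real_,
                              nadph_fraction = NA_real_,
                              photon_per_co2 = NA_real_)
      next
    }
    sols[[k]] <- sol
    ex <- plastid_exchange_fractions(net, sol)
    rr <- precursor_ratios(net, sol)
    rows[[k]] <- data.frame(ratio = ratios[k], status = "optimal",
                            objective = sol$objective_value,
                            atp_fraction = ex$atp_fraction,
                            nadph_fraction = ex$nadph_fraction,
                            photon_per_co2 = rr$photon_per_co2)
  }
  list(table = do.call(rbind, rows), solutions = sols)
}
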