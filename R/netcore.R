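# Core data model: compartmentalised stoichiometric networks.

.COMPARTMENT_KINDS <- c("environment", "apoplast", "cytoplasm", "plastid",
                        "mitochondrion", "phloem", "vacuole_virtual")
.TRANSFORMER_KINDS <- c("reaction", "transport", "polymerization")

#' Define a compartment
#'
#' @param id token, unique within a network.
#' @param name human-readable name.
#' @param kind one of environment, apoplast, cytoplasm, plastid,
#'   mitochondrion, phloem, vacuole_virtual.
#' @param parent optional id of the enclosing compartment.
#' @param ph_rank integer ordinal pH rank (lower = more acidic), used only
#'   for gradient-direction audits.
#' @export
compartment <- function(id, name = id, kind, parent = NA_character_,
                        ph_rank = 0L) {
  kind <- match.arg(kind, .COMPARTMENT_KINDS)
  list(id = id, name = name, kind = kind, parent = parent,
       ph_rank = as.integer(ph_rank))
}

#' Define a species
#'
#' @param id token unique within the network; by convention
#'   `<metabolite>_<compartment>`.
#' @param compartment compartment id.
#' @param formula an `elemental_formula`, or `NULL` for unbalanced species of
#'   unknown composition.
#' @param balanced logical; `FALSE` marks an external species treated as an
#'   infinite source or sink (exempt from steady-state rows).
#' @param name,annotations optional metadata.
#' @export
species <- function(id, compartment, formula = NULL, balanced = TRUE,
                    name = id, annotations = list(), strict = TRUE) {
  if (strict && balanced && is.null(formula))
    stop(sprintf("balanced species '%s' must have a formula", id),
         call. = FALSE)
  list(id = id, name = name, compartment = compartment, formula = formula,
       balanced = isTRUE(balanced), annotations = annotations)
}

#' Define a transformer (reaction, transport step or polymerisation)
#'
#' @param id token unique within the network.
#' @param stoich named list/vector of rational coefficients (negative =
#'   consumed); values may be integers or exact strings (`"1/2"`, `"0.25"`).
#' @param kind reaction | transport | polymerization.
#' @param reversible logical.
#' @param ec,genes,pathway optional annotation.
#' @export
transformer <- function(id, stoich, kind = "reaction", reversible = FALSE,
                        ec = NA_character_, genes = character(0),
                        pathway = NA_character_) {
  kind <- match.arg(kind, .TRANSFORMER_KINDS)
  ids <- names(stoich)
  if (is.null(ids) || any(ids == ""))
    stop("stoichiometry must be a named vector/list", call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("transformer '%s': duplicate species in stoichiometry", id),
         call. = FALSE)
  if (is.character(stoich)) {
    parsed <- lapply(stoich, rq_parse)
    co <- list(n = vapply(parsed, `[[`, 0, "n"),
               d = vapply(parsed, `[[`, 0, "d"))
  } else {
    co <- rq(as.numeric(stoich))
  }
  keep <- co$n != 0
  if (!any(keep))
    stop(sprintf("transformer '%s' has no nonzero coefficient", id),
         call. = FALSE)
  list(id = id, kind = kind,
       stoich = list(ids = ids[keep], n = unname(co$n[keep]),
                     d = unname(co$d[keep])),
       reversible = isTRUE(reversible), ec = ec, genes = genes,
       pathway = pathway)
}

#' Parse a reaction equation string into a stoichiometry
#'
#' Syntax: `"2 h2o_c + pq_c -> o2_c + ..."` with `->` (irreversible) or
#' `<->` (reversible); coefficients are optional and may be exact decimals or
#' fractions (`"1/2 o2_c"`).
#' @param eq equation string.
#' @return list(stoich = named character vector, reversible = logical)
#' @keywords internal
parse_equation <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, "<->|->")[[1]]
  if (length(sides) != 2L)
    stop(sprintf("equation must have one arrow: %s", eq), call. = FALSE)
  take <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(stats::setNames(character(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- character(0)
    for (term in terms) {
      m <- regexec("^(?:([0-9][0-9./]*|[0-9]*\\.[0-9]+)\\s+)?(\\S+)$", term)[[1]]
      if (m[1] == -1) stop(sprintf("malformed term '%s'", term), call. = FALSE)
      g <- regmatches(term, regexec("^(?:([0-9][0-9./]*|[0-9]*\\.[0-9]+)\\s+)?(\\S+)$", term))[[1]]
      coef <- if (g[2] == "") "1" else g[2]
      sp <- g[3]
      val <- rq_parse(coef)
      if (sign < 0) val$n <- -val$n
      if (sp %in% names(out)) {
        cur <- rq_parse(out[[sp]])
        val <- rq_add(cur, val)
      }
      out[sp] <- rq_format(val)
    }
    out
  }
  lhs <- take(sides[1], -1)
  rhs <- take(sides[2], +1)
  st <- lhs
  for (sp in names(rhs)) {
    if (sp %in% names(st)) {
      v <- rq_add(rq_parse(st[[sp]]), rq_parse(rhs[[sp]]))
      st[sp] <- rq_format(v)
    } else st[sp] <- rhs[[sp]]
  }
  list(stoich = st, reversible = rev)
}

#' Assemble a network
#'
#' Validates id uniqueness, resolution of all references, the
#' single-environment rule and formula completeness of balanced species.
#'
#' @param compartments,species,transformers lists of the respective objects.
#' @param metadata free-form list.
#' @return object of class `pf_network`.
#' @export
network <- function(compartments, species, transformers, metadata = list()) {
  cids <- vapply(compartments, `[[`, "", "id")
  sids <- vapply(species, `[[`, "", "id")
  tids <- vapply(transformers, `[[`, "", "id")
  for (lbl in list(c("compartment", "cids"), c("species", "sids"),
                   c("transformer", "tids"))) {
    v <- get(lbl[2])
    if (anyDuplicated(v))
      stop(sprintf("duplicate %s id: %s", lbl[1],
                   paste(unique(v[duplicated(v)]), collapse = ", ")),
           call. = FALSE)
  }
  kinds <- vapply(compartments, `[[`, "", "kind")
  if (sum(kinds == "environment") != 1L)
    stop("network must have exactly one environment compartment",
         call. = FALSE)
  for (sp in species) {
    if (!(sp$compartment %in% cids))
      stop(sprintf("species '%s' references undeclared compartment '%s'",
                   sp$id, sp$compartment), call. = FALSE)
  }
  for (tr in transformers) {
    missing <- setdiff(tr$stoich$ids, sids)
    if (length(missing))
      stop(sprintf("transformer '%s' references unknown species: %s",
                   tr$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  net <- structure(
    list(compartments = stats::setNames(compartments, cids),
         species = stats::setNames(species, sids),
         transformers = stats::setNames(transformers, tids),
         metadata = metadata),
    class = "pf_network")
  net
}

#' @export
print.pf_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("<pf_network> %d compartments, %d species (%d balanced),",
                     " %d transformers\n  reactions %d | transports %d |",
                     " polymerizations %d | reversible %d\n"),
              s$compartments, s$species, s$balanced_species, s$transformers,
              s$reactions, s$transports, s$polymerizations, s$reversible))
  invisible(x)
}

species_compartment <- function(net, sid) net$species[[sid]]$compartment

#' Is a transformer an exchange step?
#'
#' Exchange transformers touch at least one unbalanced (external) species or
#' the environment compartment; they are excluded from internal-cycle
#' analysis.
#' @param net a `pf_network`; @param tid transformer id.
#' @export
is_exchange <- function(net, tid) {
  tr <- net$transformers[[tid]]
  any(vapply(tr$stoich$ids, function(s) {
    sp <- net$species[[s]]
    !sp$balanced || net$compartments[[sp$compartment]]$kind == "environment"
  }, TRUE))
}

#' Elemental and charge balance of one transformer
#'
#' Residuals are computed in exact rational arithmetic:
#' residual(element) = sum over species of coefficient x count.  A
#' transformer referencing an unbalanced species without a formula is exempt
#' (`exempt = TRUE`) and reported as balanced with a flag, mirroring the
#' treatment of infinite source/sink species.
#'
#' @param t a transformer object (or id present in `net`).
#' @param net the network supplying the species table.
#' @return list of class `balance_report`: `transformer`, `element_residuals`
#'   (named character, exact), `charge_residual`, `balanced`, `exempt`.
#' @export
check_balance <- function(t, net) {
  if (is.character(t)) {
    if (!t %in% names(net$transformers))
      stop(sprintf("unknown transformer '%s'", t), call. = FALSE)
    t <- net$transformers[[t]]
  }
  sps <- lapply(t$stoich$ids, function(s) {
    if (!s %in% names(net$species))
      stop(sprintf("transformer '%s' references unknown species '%s'",
                   t$id, s), call. = FALSE)
    net$species[[s]]
  })
  missing_formula <- vapply(sps, function(sp) is.null(sp$formula), TRUE)
  if (any(missing_formula)) {
    # species of unknown composition (external infinite sources/sinks, or
    # foreign imports without formula annotation) exempt the transformer
    return(structure(list(transformer = t$id,
                          element_residuals = character(0),
                          charge_residual = "0", balanced = TRUE,
                          exempt = TRUE),
                     class = "balance_report"))
  }
  coefs <- list(n = t$stoich$n, d = t$stoich$d)
  sums <- formula_weighted_sum(coefs, lapply(sps, `[[`, "formula"))
  res <- rq_format(sums$elements)
  names(res) <- names(sums$elements$n)
  chg <- rq_format(sums$charge)
  structure(list(transformer = t$id,
                 element_residuals = res[res != "0"],
                 charge_residual = chg,
                 balanced = length(res[res != "0"]) == 0L && chg == "0",
                 exempt = FALSE),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance> %s: %s%s\n", x$transformer,
              if (x$balanced) "balanced" else "UNBALANCED",
              if (x$exempt) " (exempt: external species without formula)" else ""))
  if (!x$balanced) {
    if (length(x$element_residuals))
      cat("  element residuals:",
          paste(sprintf("%s=%s", names(x$element_residuals),
                        x$element_residuals), collapse = ", "), "\n")
    if (x$charge_residual != "0")
      cat("  charge residual:", x$charge_residual, "\n")
  }
  invisible(x)
}

#' Balance check over a whole network
#'
#' @param net a `pf_network`.
#' @return data.frame with one row per transformer: id, balanced, exempt,
#'   residual summary string.
#' @export
check_network_balance <- function(net) {
  rows <- lapply(net$transformers, function(tr) {
    b <- check_balance(tr, net)
    data.frame(id = tr$id, balanced = b$balanced, exempt = b$exempt,
               residuals = paste(
                 c(sprintf("%s=%s", names(b$element_residuals),
                           b$element_residuals),
                   if (b$charge_residual != "0")
                     sprintf("charge=%s", b$charge_residual)),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary counts of a network
#'
#' Reports transformer counts by kind, species balanced/unbalanced split and
#' the number of distinct gene ids (the analogue of a reconstruction metrics
#' table).
#' @param net a `pf_network`.
#' @export
network_summary <- function(net) {
  tk <- vapply(net$transformers, `[[`, "", "kind")
  bal <- vapply(net$species, function(s) s$balanced, TRUE)
  genes <- unique(unlist(lapply(net$transformers, `[[`, "genes")))
  list(compartments = length(net$compartments),
       species = length(net$species),
       balanced_species = sum(bal),
       unbalanced_species = sum(!bal),
       transformers = length(net$transformers),
       reactions = sum(tk == "reaction"),
       transports = sum(tk == "transport"),
       polymerizations = sum(tk == "polymerization"),
       reversible = sum(vapply(net$transformers, `[[`, TRUE, "reversible")),
       genes = length(genes))
}

#' Structural validation of a network
#'
#' Checks the full invariant set: reference resolution, id uniqueness (both
#' enforced at construction), every balanced species used by at least one
#' transformer, transport transformers spanning >= 2 compartments, reaction
#' transformers confined to one compartment, vacuole influx-only.
#' @param net a `pf_network`.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_network <- function(net) {
  bad <- character(0)
  used <- unique(unlist(lapply(net$transformers, function(t) t$stoich$ids)))
  for (sp in net$species) {
    if (sp$balanced && !(sp$id %in% used))
      bad <- c(bad, sprintf("balanced species '%s' unused", sp$id))
  }
  for (tr in net$transformers) {
    comps <- unique(vapply(tr$stoich$ids, function(s)
      net$species[[s]]$compartment, ""))
    if (tr$kind == "transport" && length(comps) < 2L)
      bad <- c(bad, sprintf("transport '%s' spans one compartment", tr$id))
    if (tr$kind == "reaction" && length(comps) > 1L)
      bad <- c(bad, sprintf("reaction '%s' spans compartments: %s", tr$id,
                            paste(comps, collapse = ",")))
    vac <- vapply(tr$stoich$ids, function(s)
      net$compartments[[net$species[[s]]$compartment]]$kind == "vacuole_virtual",
      TRUE)
    if (any(vac & tr$stoich$n < 0) && !tr$reversible &&
        tr$kind != "polymerization")
      bad <- c(bad, sprintf("'%s' withdraws from virtual vacuole", tr$id))
    if (any(vac) && tr$reversible)
      bad <- c(bad, sprintf("reversible '%s' touches virtual vacuole", tr$id))
  }
  bal <- check_network_balance(net)
  ub <- bal[!bal$balanced, , drop = FALSE]
  if (nrow(ub))
    bad <- c(bad, sprintf("unbalanced transformer '%s' (%s)", ub$id,
                          ub$residuals))
  bad
}

#' Write a network as a human-readable TSV table pair
#'
#' @param net a `pf_network`; @param path base path; writes
#'   `<path>.species.tsv` and `<path>.transformers.tsv`.
#' @export
write_network_tsv <- function(net, path) {
  sp <- do.call(rbind, lapply(net$species, function(s) data.frame(
    id = s$id, compartment = s$compartment,
    formula = if (is.null(s$formula)) "" else format_formula(s$formula),
    charge = if (is.null(s$formula)) "" else rq_format(s$formula$charge),
    balanced = s$balanced, stringsAsFactors = FALSE)))
  tr <- do.call(rbind, lapply(net$transformers, function(t) {
    co <- rq_format(list(n = t$stoich$n, d = t$stoich$d))
    data.frame(id = t$id, kind = t$kind,
               stoichiometry = paste(sprintf("%s:%s", t$stoich$ids, co),
                                     collapse = " "),
               reversible = t$reversible, ec = t$ec,
               genes = paste(t$genes, collapse = ";"),
               pathway = t$pathway, stringsAsFactors = FALSE)
  }))
  utils::write.table(sp, paste0(path, ".species.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(tr, paste0(path, ".transformers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
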