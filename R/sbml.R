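# SBML Level 3 core import/export.  Exact rational stoichiometries, formulas
# and charges ride along in a dedicated attribute namespace so that a
# write/read round trip is lossless; foreign SBML without those attributes is
# rationalised from the floating-point values.

.PF_NS <- "https://plantflux.invalid/sbml"
.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

#' Write a network as SBML Level 3
#'
#' Compartments, species (with formula and charge), reactions with exact
#' stoichiometry, reversibility, EC numbers, gene ids and pathway tags are
#' serialised.  Serialisation is deterministic: the same network yields a
#' byte-identical file.
#'
#' @param net a `pf_network`.
#' @param path output file path.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(q) sprintf("%.17g", q)
  out <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
           sprintf(paste0('<sbml xmlns="%s" xmlns:pf="%s" level="3"',
                          ' version="1">'), .SBML_NS, .PF_NS),
           sprintf('  <model id="%s" name="%s">',
                   "plantflux_model",
                   esc(if (!is.null(net$metadata$model)) net$metadata$model
                       else "plantflux network")))
  out <- c(out, "    <listOfCompartments>")
  for (cp in net$compartments) {
    out <- c(out, sprintf(
      paste0('      <compartment id="%s" name="%s" constant="true"',
             ' pf:kind="%s"%s pf:phRank="%d"/>'),
      cp$id, esc(cp$name), cp$kind,
      if (is.na(cp$parent)) "" else sprintf(' pf:parent="%s"', cp$parent),
      cp$ph_rank))
  }
  out <- c(out, "    </listOfCompartments>", "    <listOfSpecies>")
  for (sp in net$species) {
    fattr <- if (is.null(sp$formula)) "" else sprintf(
      ' pf:formula="%s" pf:charge="%s"',
      format_formula(sp$formula), rq_format(sp$formula$charge))
    out <- c(out, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' boundaryCondition="%s" hasOnlySubstanceUnits="false"',
             ' constant="false"%s/>'),
      sp$id, esc(sp$name), sp$compartment,
      if (sp$balanced) "false" else "true", fattr))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfReactions>")
  for (tr in net$transformers) {
    attrs <- sprintf(' pf:kind="%s"', tr$kind)
    if (!is.na(tr$ec)) attrs <- paste0(attrs, sprintf(' pf:ec="%s"', tr$ec))
    if (length(tr$genes)) attrs <- paste0(
      attrs, sprintf(' pf:genes="%s"', paste(tr$genes, collapse = " ")))
    if (!is.na(tr$pathway)) attrs <- paste0(
      attrs, sprintf(' pf:pathway="%s"', esc(tr$pathway)))
    out <- c(out, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false"%s>',
      gsub("!", "_x_", tr$id), tolower(tr$reversible), attrs))
    co <- tr$stoich$n / tr$stoich$d
    for (side in c(-1, 1)) {
      sel <- which(sign(co) == side)
      if (!length(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      out <- c(out, sprintf("        <%s>", tag))
      for (k in sel) {
        out <- c(out, sprintf(
          paste0('          <speciesReference species="%s"',
                 ' stoichiometry="%s" constant="true" pf:rational="%s"/>'),
          tr$stoich$ids[k], num(abs(co[k])),
          rq_format(list(n = abs(tr$stoich$n[k]), d = tr$stoich$d[k]))))
      }
      out <- c(out, sprintf("        </%s>", tag))
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  con <- file(path, "wb")
  writeLines(out, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read an SBML Level 2/3 core file
#'
#' Reconstructs a `pf_network`.  Exact rational annotations written by
#' [write_sbml()] are honoured; otherwise floating-point stoichiometries are
#' rationalised (continued fractions, tolerance 1e-9) and species
#' formula/charge are taken from `fbc` attributes when present.
#'
#' @param path SBML file.
#' @return a `pf_network`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  att <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    v
  }
  comps <- lapply(xml2::xml_find_all(doc, ".//s:compartment", ns), function(nd) {
    kind <- att(nd, "kind")
    if (is.na(kind)) kind <- "cytoplasm"
    rank <- att(nd, "phRank")
    parent <- att(nd, "parent")
    compartment(att(nd, "id"),
                name = ifelse(is.na(att(nd, "name")), att(nd, "id"),
                              att(nd, "name")),
                kind = kind, parent = parent,
                ph_rank = if (is.na(rank)) 0L else as.integer(rank))
  })
  cids <- vapply(comps, `[[`, "", "id")
  sps <- lapply(xml2::xml_find_all(doc, ".//s:species", ns), function(nd) {
    id <- att(nd, "id")
    comp <- att(nd, "compartment")
    if (is.na(comp) || !(comp %in% cids))
      stop(sprintf("species '%s' references undeclared compartment '%s'",
                   id, comp), call. = FALSE)
    bc <- identical(att(nd, "boundaryCondition"), "true")
    ftxt <- att(nd, "formula")
    if (is.na(ftxt)) ftxt <- att(nd, "chemicalFormula")  # fbc fallback
    chg <- att(nd, "charge")
    f <- if (is.na(ftxt) && is.na(chg)) NULL else
      parse_formula(ifelse(is.na(ftxt), "", ftxt),
                    ifelse(is.na(chg), "0", chg))
    species(id, comp, formula = f, balanced = !bc,
            name = ifelse(is.na(att(nd, "name")), id, att(nd, "name")),
            strict = FALSE)
  })
  # foreign SBML may not declare an environment compartment; append an
  # empty one so the single-environment invariant holds
  kinds <- vapply(comps, `[[`, "", "kind")
  if (!any(kinds == "environment"))
    comps <- c(comps, list(compartment("ENV_", kind = "environment")))
  trs <- lapply(xml2::xml_find_all(doc, ".//s:reaction", ns), function(nd) {
    id <- gsub("_x_", "!", att(nd, "id"))
    kind <- att(nd, "kind"); if (is.na(kind)) kind <- "reaction"
    genes <- att(nd, "genes")
    genes <- if (is.na(genes)) character(0) else
      strsplit(genes, " ", fixed = TRUE)[[1]]
    st <- character(0)
    for (side in c("Reactants", "Products")) {
      refs <- xml2::xml_find_all(nd, sprintf(".//s:listOf%s/s:speciesReference",
                                             side), ns)
      sgn <- if (side == "Reactants") -1 else 1
      for (ref in refs) {
        rat <- att(ref, "rational")
        q <- if (!is.na(rat)) rq_parse(rat) else
          rq_from_double(as.numeric(att(ref, "stoichiometry")))
        q$n <- q$n * sgn
        sid <- att(ref, "species")
        if (sid %in% names(st))
          q <- rq_add(rq_parse(st[[sid]]), q)
        st[sid] <- rq_format(q)
      }
    }
    transformer(id, st, kind = kind,
                reversible = identical(att(nd, "reversible"), "true"),
                ec = att(nd, "ec"), genes = genes,
                pathway = att(nd, "pathway"))
  })
  network(comps, sps, trs)
}
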