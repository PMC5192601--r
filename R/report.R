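# Report orchestration: one run directory per scenario with flux table,
# ratio/exchange/budget/ledger/audit reports, a manifest and a log.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run a scenario and emit the full report set
#'
#' Solves pfba under the scenario and writes, into `outdir`: `fluxes.tsv`
#' (id, flux, and FVA min/max when `fva = TRUE`), `ratios.json`,
#' `exchange_fractions.json`, `atp_budget_<comp>.tsv`, `proton_ledger.tsv`,
#' `sucrose_audit.json`, `manifest.json` and `run.log`.
#'
#' @param net a `pf_network` (default: packaged model).
#' @param scenario a `pf_scenario`.
#' @param outdir output directory (created; must not be a file).
#' @param fva logical: add flux variability ranges (slower).
#' @return invisibly, the list of generated artefacts.
#' @export
run_report <- function(net, scenario, outdir, fva = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat("", file = logf)
  t0 <- Sys.time()
  sm <- stoich_matrix(net)
  logline("scenario: %s", scenario$name)
  sol <- pfba(net, scenario, sm = sm)
  logline("status: %s  objective: %.10g  duality_gap: %.3g  total_flux: %.6g",
          sol$status, sol$objective_value,
          if (is.null(sol$duality_gap)) NA else sol$duality_gap,
          if (is.null(sol$total_flux)) NA else sol$total_flux)
  if (sol$status != "optimal")
    stop(sprintf("scenario '%s' is %s", scenario$name, sol$status),
         call. = FALSE)
  fl <- data.frame(id = names(sol$fluxes), flux = as.numeric(sol$fluxes),
                   stringsAsFactors = FALSE)
  if (fva) {
    vr <- fva(net, scenario, sm = sm)
    fl$min <- vr$min[match(fl$id, vr$id)]
    fl$max <- vr$max[match(fl$id, vr$id)]
  }
  .write_tsv(fl, file.path(outdir, "fluxes.tsv"))
  rr <- precursor_ratios(net, sol, sm)
  .write_json(unclass(rr), file.path(outdir, "ratios.json"))
  ex <- tryCatch(plastid_exchange_fractions(net, sol, sm),
                 error = function(e) NULL)
  if (!is.null(ex))
    .write_json(unclass(ex), file.path(outdir, "exchange_fractions.json"))
  for (comp in intersect(c("mc", "rc"), sub("^atp_", "",
                                            grep("^atp_", sm$species,
                                                 value = TRUE)))) {
    b <- atp_budget(net, sol, comp, sm)
    .write_tsv(b$items, file.path(outdir, sprintf("atp_budget_%s.tsv", comp)))
  }
  pl <- proton_ledger(net, sol, sm)
  led <- do.call(rbind, lapply(pl$compartments, function(p) data.frame(
    compartment = p$compartment, produced = p$produced,
    consumed = p$consumed, relative_turnover = p$relative_turnover,
    n_producing = p$n_producing, n_consuming = p$n_consuming,
    closure = p$closure, stringsAsFactors = FALSE)))
  .write_tsv(led, file.path(outdir, "proton_ledger.tsv"))
  aud <- sucrose_audit(net, sol, sm)
  .write_json(list(pass = aud$pass,
                   checks = lapply(aud$checks, function(ck)
                     list(ok = ck$ok, value = as.numeric(ck$value)))),
              file.path(outdir, "sucrose_audit.json"))
  manifest <- list(
    package = "plantflux",
    version = as.character(utils::packageVersion("plantflux")),
    r_version = R.version.string,
    scenario = scenario$name,
    scenario_text = format_scenario(scenario),
    network = list(species = length(net$species),
                   transformers = length(net$transformers)),
    config_hash = .pf_hash(format_scenario(scenario)),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  .write_json(manifest, file.path(outdir, "manifest.json"))
  logline("artefacts written to %s", outdir)
  invisible(list(solution = sol, outdir = outdir))
}

# small stable string hash (djb2), avoids a digest dependency
.pf_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
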