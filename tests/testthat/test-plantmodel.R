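# packaged plant model: construction invariants and scenario presets

test_that("build is deterministic and passes all structural checks", {
  net <- pf_model()
  net2 <- build_model(biomass = compose_biomass())  # bypasses the cache
  expect_identical(names(net$transformers), names(net2$transformers))
  expect_identical(lapply(net$transformers, `[[`, "stoich"),
                   lapply(net2$transformers, `[[`, "stoich"))
  expect_length(validate_network(net), 0L)
  expect_length(dead_ends(net), 0L)
})

test_that("every non-exchange transformer is elementally and charge balanced", {
  net <- pf_model()
  bal <- check_network_balance(net)
  expect_true(all(bal$balanced))
  expect_true(all(bal$exempt == vapply(bal$id, function(id)
    is_exchange(net, id) &&
      any(vapply(net$transformers[[id]]$stoich$ids, function(s)
        is.null(net$species[[s]]$formula), TRUE)), TRUE)))
})

test_that("the named scenario fluxes exist verbatim", {
  net <- pf_model()
  needed <- c("RPC_plastide", "RPC2_plastide", "GLYK", "GDC", "SK",
              "PGM3_plastid", "FQR", "FNR", "T.Biomass.ext", "T.starch.ext",
              "T.hv.ext", "T.CO2.ext", "T.CO2.ext_rev", "T.ATP.plastid",
              "T.ADP.plastid")
  expect_true(all(needed %in% names(net$transformers)))
})

test_that("plastid ATP synthase uses 4 lumenal protons per ATP", {
  expect_identical(plastid_h_per_atp(pf_model()), 4)
})

test_that("GAP and maltose are the only carbon carriers across the envelope", {
  net <- pf_model()
  carbonless <- c("co2", "hco3")
  offenders <- character(0)
  for (id in names(net$transformers)) {
    tr <- net$transformers[[id]]
    if (tr$kind != "transport") next
    comps <- vapply(tr$stoich$ids, function(s) net$species[[s]]$compartment, "")
    if (!("mp" %in% comps) || !("mc" %in% comps)) next
    for (k in seq_along(tr$stoich$ids)) {
      sid <- tr$stoich$ids[k]
      f <- net$species[[sid]]$formula
      base <- sub("_(mc|mp)$", "", sid)
      if (!is.null(f) && "C" %in% names(f$n) && f$n[["C"]] > 1 &&
          !(base %in% c("gap", "malt")) &&
          !(base %in% c("atp", "adp", "glu", "gln", "akg", "mal", "oaa",
                        "glyclt", "glyc")))
        offenders <- c(offenders, paste(id, sid))
    }
  }
  # only the translocators/shuttles the reconstruction declares may carry
  # carbon; no hexose/pentose phosphates cross the envelope
  expect_length(offenders, 0L)
})

test_that("scenario presets reproduce the published constraint rows", {
  net <- pf_model()
  dk <- plant_scenario("dark", net = net)
  for (id in c("PGM3_plastid", "RPC_plastide", "RPC2_plastide", "GLYK",
               "GDC", "T.hv.ext"))
    expect_identical(dk$bounds[[id]], c(0, 0), label = id)
  expect_identical(dk$bounds[["T.starch.ext"]][1], 0)
  expect_identical(dk$bounds[["T.Biomass.ext"]][2], 5000)
  lt <- plant_scenario("light", variant = "fqr0", net = net)
  expect_identical(lt$bounds[["FQR"]], c(0, 0))
  expect_identical(lt$bounds[["SK"]], c(0, 0))
  expect_identical(lt$bounds[["T.starch.ext"]], c(0, 0))
  expect_identical(lt$bounds[["T.CO2.ext"]], c(0, 0))
  coupl <- lt$constraints[[1]]
  expect_identical(coupl$terms[["RPC_plastide"]], "1/4")
  expect_identical(coupl$terms[["RPC2_plastide"]], "-1")
  # pr = 0 turns photorespiration off via explicit zeroes
  lt0 <- plant_scenario("light", pr = 0, ratio = 0, net = net)
  expect_identical(lt0$bounds[["RPC2_plastide"]], c(0, 0))
  expect_identical(lt0$bounds[["GLYK"]], c(0, 0))
  expect_error(plant_scenario("light", ratio = 0.7), "0, 0.5")
  expect_error(plant_scenario("dark", ratio = 0.3), "light")
})

test_that("both presets solve to the biomass cap with certified optima", {
  l <- pf_light(); d <- pf_dark()
  expect_identical(l$status, "optimal")
  expect_identical(d$status, "optimal")
  expect_equal(l$objective_value, 5000, tolerance = 1e-6)
  expect_equal(d$objective_value, 5000, tolerance = 1e-6)
  expect_lt(l$duality_gap, 1e-6)
  expect_lt(d$duality_gap, 1e-6)
})

test_that("forward/reverse transporter pairs never both carry flux", {
  for (sol in list(pf_light(), pf_dark())) {
    f <- sol$fluxes
    pairs <- list(c("T.CO2.ext", "T.CO2.ext_rev"),
                  c("T.ATP.plastid", "T.ADP.plastid"))
    for (p in pairs)
      expect_true(min(f[p[1]], f[p[2]]) < 1e-6,
                  label = paste(p, collapse = "/"))
  }
})

test_that("dark FVA: RuBisCO and cyclic electron flow are forced to zero", {
  net <- pf_model()
  vr <- fva(net, plant_scenario("dark", net = net),
            transformers = c("RPC_plastide", "FQR", "FNR", "PSII"))
  expect_true(all(abs(vr[vr$id %in% c("RPC_plastide", "FQR", "PSII"),
                         c("min", "max")]) < 1e-9))
  # FNR stays active in reverse in darkness: oxidative-PPP NADPH reduces
  # ferredoxin for nitrite/sulphate reduction (source text; the add-on
  # claim that FNR is fully blocked in the dark contradicts it)
  expect_lt(vr[vr$id == "FNR", "min"], -1e-6)
  expect_true(vr[vr$id == "FNR", "max"] <= 1e-9)
})
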