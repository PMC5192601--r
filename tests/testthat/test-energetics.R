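# derived reports: ratios, exchange fractions, budgets, ledgers, audits

test_that("hand-built solution gives photon/CO2 = 16", {
  net <- pf_model()
  sol <- structure(list(status = "optimal",
                        fluxes = stats::setNames(
                          numeric(length(net$transformers)),
                          names(net$transformers)),
                        scenario = "hand"), class = "flux_solution")
  sol$fluxes["T.hv.ext"] <- 16
  sol$fluxes["T.CO2.ext_rev"] <- 1
  rr <- precursor_ratios(net, sol)
  expect_equal(rr$photon_per_co2, 16)
  expect_true(is.na(rr$photon_per_no3))   # zero denominator -> undefined
})

test_that("mitochondrial NADH-only oxidation has P/O = 5", {
  # exercise only complex I/III/IV + synthase of the mesophyll mitochondrion
  net <- pf_model()
  v <- plantflux:::.subsystem_solve(
    net, c("CI_mm", "CIII_mm", "CIV_mm", "ATPS_mm"),
    boundary = c("nadh_mm", "nad_mm", "o2_mm", "h2o_mm", "adp_mm", "atp_mm",
                 "pi_mm", "h_mm", "h_mc"),
    fixed = list(CI_mm = 1))
  po <- v[["ATPS_mm"]] / (0.5 * v[["CIV_mm"]])
  expect_equal(po, 5, tolerance = 1e-9)
})

test_that("toy exchange fractions: zero translocator flux, pure import", {
  net <- pf_model()
  z <- structure(list(status = "optimal",
                      fluxes = stats::setNames(
                        numeric(length(net$transformers)),
                        names(net$transformers)),
                      scenario = "hand"), class = "flux_solution")
  z$fluxes["ATPS_mp"] <- 1   # some turnover, no exchange
  ex0 <- plastid_exchange_fractions(net, z)
  expect_equal(ex0$atp_fraction, 0)
  z$fluxes["ATPS_mp"] <- 0
  z$fluxes["T.ATP.plastid"] <- 2   # all plastid ATP imported
  ex1 <- plastid_exchange_fractions(net, z)
  expect_equal(ex1$atp_fraction, 1)
})

test_that("atp_budget: single producer/consumer is 100 % both sides", {
  tp <- toy_plant()
  sol <- pfba(tp, toy_scenario("light", tp))
  b <- atp_budget(tp, sol, "src")
  prod <- b$items[b$items$side == "producing", ]
  expect_equal(sum(prod$share_pct), 100)
  cons <- b$items[b$items$side == "consuming", ]
  expect_equal(sum(cons$share_pct), 100, tolerance = 1e-6)
  expect_error(atp_budget(tp, sol, "nowhere"), "compartment")
})

test_that("proton ledger closes in every compartment of the toy", {
  tp <- toy_plant()
  sol <- pfba(tp, toy_scenario("light", tp))
  pl <- proton_ledger(tp, sol)
  for (cp in names(pl$compartments))
    expect_lt(abs(pl$compartments[[cp]]$closure),
              1e-6 * max(1, pl$compartments[[cp]]$produced), label = cp)
  expect_identical(pl$reference, "snk")
})

test_that("sucrose audit passes on the toy and flags a broken symporter", {
  tp <- toy_plant()
  sol <- pfba(tp, toy_scenario("light", tp))
  aud <- sucrose_audit(tp, sol)
  expect_true(aud$pass)
  # reversed symporter stoichiometry (antiport: proton released on uptake)
  bad <- tp
  bad$transformers[["SUC.snk"]] <- transformer(
    "SUC.snk", c(suc_apo = -1, h_snk = -1, suc_snk = 1, h_apo = 1),
    kind = "transport")
  sol2 <- pfba(bad, toy_scenario("light", bad))
  aud2 <- sucrose_audit(bad, sol2)
  expect_false(aud2$pass)
  expect_false(aud2$checks$influx_proton_symport$ok)
})

test_that("CBC demand and linear-ET yield probes hit theory exactly", {
  net <- pf_model()
  cb <- cbc_demand_ratio(net)
  expect_equal(cb$ratio, 1.5, tolerance = 1e-9)
  expect_equal(cb$atp, 3, tolerance = 1e-9)
  expect_equal(cb$nadph, 2, tolerance = 1e-9)
  ly <- let_yield_ratio(net)
  expect_equal(ly$ratio, 1.0, tolerance = 1e-9)
})

test_that("full starch oxidation at zero growth has RQ exactly 1", {
  net <- pf_model()
  sc <- plant_scenario("dark", net = net)
  sc$bounds[["T.Biomass.ext"]] <- c(0, 0)
  sc$bounds[["T.starch.ext"]] <- c(1, 1)
  sol <- pfba(net, sc)
  rr <- precursor_ratios(net, sol)
  expect_equal(rr$rq, 1, tolerance = 1e-6)   # C6H10O5 + 6 O2 -> 6 CO2 + 5 H2O
})
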