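# scenario mini-language, FBA, pfba, FVA, blocked transformers

test_that("scenario parser: bounds, coefficient rows, errors, round trip", {
  net <- fx_diamond()
  sc <- parse_scenario("objective: max out\nin <= 5000\n0.37*r1 - r2 = 0",
                       net)
  expect_identical(sc$bounds[["in"]][2], 5000)
  expect_length(sc$constraints, 1L)
  expect_identical(sc$constraints[[1]]$terms[["r1"]], "37/100")
  expect_identical(sc$constraints[[1]]$terms[["r2"]], "-1")
  expect_error(parse_scenario("FOO = 1", net), "unknown flux 'FOO'")
  expect_error(parse_scenario("objective: maximise out", net), "malformed")
  rt <- parse_scenario(format_scenario(sc), net, name = sc$name)
  expect_identical(rt[-1], sc[-1])
})

test_that("solve_fba on the chain and infeasible detection", {
  net <- fx_chain()
  sc <- parse_scenario("objective: max v3\nv1 <= 10", net)
  sol <- solve_fba(net, sc)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(10, 10, 10))
  expect_lt(sol$duality_gap, 1e-6)    # certified optimum
  bad <- parse_scenario("objective: max v3\nv1 >= 5\nv1 <= 1", net)
  expect_identical(suppressWarnings(solve_fba(net, bad))$status, "infeasible")
  # unbounded reported honestly
  unb <- parse_scenario("objective: max v3", net)
  expect_identical(solve_fba(net, unb)$status, "unbounded")
})

test_that("pfba removes futile cycles and preserves the optimum", {
  cs <- fx_compartments()
  net <- network(cs,
                 list(species("x", "env", balanced = FALSE),
                      species("A", "c", make_formula(c(C = 1))),
                      species("B", "c", make_formula(c(C = 1))),
                      species("y", "env", balanced = FALSE)),
                 list(transformer("in", c(x = -1, A = 1), kind = "transport"),
                      transformer("ab", c(A = -1, B = 1)),
                      transformer("ba", c(B = -1, A = 1)),   # futile pair
                      transformer("out", c(B = -1, y = 1), kind = "transport")))
  sc <- parse_scenario("objective: max out\nin <= 4", net)
  p <- pfba(net, sc)
  expect_equal(p$objective_value, solve_fba(net, sc)$objective_value)
  expect_equal(unname(p$fluxes[c("ab", "ba")]), c(4, 0))
  expect_equal(p$total_flux, 12)
})

test_that("fva: chain degenerate, diamond branches range [0, total]", {
  net <- fx_chain()
  sc <- parse_scenario("objective: max v3\nv1 <= 10", net)
  vr <- fva(net, sc, fraction = 1)
  expect_equal(vr$min, vr$max)
  netd <- fx_diamond()
  scd <- parse_scenario("objective: max out\nin <= 6", netd)
  vd <- fva(netd, scd)
  expect_equal(vd[vd$id == "r1", c("min", "max")],
               data.frame(min = 0, max = 6, row.names = 2L))
})

test_that("blocked transformers: no-source irreversible reaction", {
  cs <- fx_compartments()
  net <- network(cs,
                 list(species("A", "c", make_formula(c(C = 1))),
                      species("B", "c", make_formula(c(C = 1))),
                      species("y", "env", balanced = FALSE)),
                 list(transformer("r", c(A = -1, B = 1)),
                      transformer("out", c(B = -1, y = 1), kind = "transport"),
                      transformer("outA", c(A = -1, y = 1), kind = "transport")))
  expect_setequal(blocked_transformers(net), c("r", "out", "outA"))
})

test_that("planted LP optima and the vertex-enumeration oracle agree", {
  for (seed in 1:20) {
    size <- 2 + seed %% 5
    g <- gen_lp(seed = seed, size = size)
    sol <- solve_fba(g$network, g$scenario)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective_value, g$truth$optimum, tolerance = 1e-6,
                 label = sprintf("seed %d", seed))
    expect_lt(sol$duality_gap, 1e-6)
    if (length(g$network$transformers) <= 8) {
      orc <- oracle_lp_optimum(g$network, g$scenario)
      expect_equal(sol$objective_value, orc$optimum, tolerance = 1e-6)
    }
  }
})

test_that("tightening a bound below the optimal vertex lowers the optimum", {
  g <- gen_lp(seed = 9, size = 4)
  sc2 <- g$scenario
  cap <- sc2$bounds[["up"]][2]
  sc2$bounds[["up"]][2] <- cap / 2
  sol2 <- solve_fba(g$network, sc2)
  expect_lt(sol2$objective_value, g$truth$optimum)
  expect_equal(sol2$objective_value, g$truth$optimum / 2, tolerance = 1e-6)
})
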