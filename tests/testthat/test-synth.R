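# synthetic generators: determinism, planted ground truth, toy plant

test_that("generators are pure functions of the seed", {
  g1 <- suppressMessages(gen_network(synthetic_spec(seed = 4)))
  g2 <- suppressMessages(gen_network(synthetic_spec(seed = 4)))
  expect_identical(lapply(g1$network$transformers, `[[`, "stoich"),
                   lapply(g2$network$transformers, `[[`, "stoich"))
  l1 <- gen_lp(seed = 4); l2 <- gen_lp(seed = 4)
  expect_identical(l1$truth, l2$truth)
  expect_identical(format_scenario(l1$scenario), format_scenario(l2$scenario))
})

test_that("planted moieties and cycles are recovered (ground truth holds)", {
  for (seed in 1:10) {
    spec <- synthetic_spec(seed = seed, planted_moieties = 1 + seed %% 3,
                           planted_cycles = seed %% 4)
    g <- suppressMessages(gen_network(spec))
    expect_identical(degrees_of_freedom(g$network)$inner,
                     spec$planted_cycles)
    cm <- conserved_moieties(g$network)
    keys <- lapply(cm$moieties, function(w) sort(names(w)))
    for (w in g$truth$moieties)
      expect_true(list(sort(names(w))) %in% keys,
                  label = sprintf("seed %d moiety %s", seed,
                                  paste(names(w), collapse = "/")))
  }
})

test_that("generated networks are balanced over abstract elements", {
  g <- suppressMessages(gen_network(synthetic_spec(seed = 2)))
  bal <- check_network_balance(g$network)
  expect_true(all(bal$balanced))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_species = 0), "n_species")
  expect_error(gen_lp(size = 1), "size")
})

test_that("toy plant runs all analysis stages quickly and consistently", {
  t0 <- Sys.time()
  tp <- toy_plant()
  expect_length(validate_network(tp), 0L)
  expect_length(dead_ends(tp), 0L)
  expect_length(blocked_transformers(tp), 0L)
  sol <- pfba(tp, toy_scenario("light", tp))
  expect_identical(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_true(sucrose_audit(tp, sol)$pass)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 15)
})

test_that("removing the sucrose-proton symporter starves the sink", {
  tp <- toy_plant()
  tp$transformers[["SUC.snk"]] <- NULL
  sc <- parse_scenario("objective: max T.bm.snk\nT.bm.snk >= 1", tp)
  expect_identical(solve_fba(tp, sc)$status, "infeasible")
})
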