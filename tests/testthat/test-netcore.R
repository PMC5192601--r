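# network core: balance checking, invariants, summaries

test_that("balance check: hydrolysis, photolysis half-reaction, broken case", {
  cs <- fx_compartments()
  sp <- list(
    species("sucr", "c", make_formula(c(C = 12, H = 22, O = 11))),
    species("h2o", "c", make_formula(c(H = 2, O = 1))),
    species("glc", "c", make_formula(c(C = 6, H = 12, O = 6))),
    species("fru", "c", make_formula(c(C = 6, H = 12, O = 6))),
    species("h", "c", make_formula(c(H = 1), 1)),
    species("o2", "c", make_formula(c(O = 2))),
    species("e", "c", make_formula(charge = -1)),   # massless electron
    species("x", "env", balanced = FALSE))
  tr <- list(
    transformer("INV", c(sucr = -1, h2o = -1, glc = 1, fru = 1)),
    transformer("BAD", c(sucr = -1, h2o = -1, glc = 1)),
    transformer("PHOTO", c(h2o = -2, o2 = 1, h = 4, e = 4)),
    transformer("EX", c(x = -1, sucr = 1), kind = "transport"))
  net <- network(cs, sp, tr)
  expect_true(check_balance("INV", net)$balanced)
  bad <- check_balance("BAD", net)
  expect_false(bad$balanced)
  expect_identical(bad$element_residuals[["C"]], "-6")
  expect_identical(bad$element_residuals[["H"]], "-12")
  expect_identical(bad$element_residuals[["O"]], "-6")
  # water photolysis balances with the electron carried as charge -1
  expect_true(check_balance("PHOTO", net)$balanced)
  # exchange with formula-less external species is exempt, flagged
  ex <- check_balance("EX", net)
  expect_true(ex$exempt)
  expect_error(check_balance(transformer("Z", c(nope = -1)), net),
               "unknown species")
})

test_that("network invariants are enforced at construction", {
  cs <- fx_compartments()
  a <- species("A", "c", make_formula(c(C = 1)))
  expect_error(network(cs, list(a, a), list(transformer("t", c(A = -1, A2 = 1)))),
               "duplicate species")
  expect_error(network(list(cs[[2]]), list(a),
                       list(transformer("t", c(A = -1)))),
               "environment")
  expect_error(species("B", "c", NULL, balanced = TRUE), "formula")
  expect_error(transformer("t", c(A = 0)), "nonzero")
})

test_that("equation parser handles coefficients, fractions and direction", {
  pe <- parse_equation("2 h2o_c + 1/2 o2_c <-> x_c + 0.25 y_c")
  expect_true(pe$reversible)
  expect_identical(pe$stoich[["h2o_c"]], "-2")
  expect_identical(pe$stoich[["o2_c"]], "-1/2")
  expect_identical(pe$stoich[["y_c"]], "1/4")
  expect_false(parse_equation("a_c -> b_c")$reversible)
  expect_error(parse_equation("a_c + b_c"), "arrow")
})

test_that("network_summary counts kinds, balance split and genes", {
  net <- fx_kinase()
  s <- network_summary(net)
  expect_identical(s$reactions, 2L)
  expect_identical(s$species, 9L)
  expect_identical(s$balanced_species, 7L)
  expect_identical(s$transports, 5L)
  empty <- network(list(compartment("env", kind = "environment")),
                   list(species("z", "env", balanced = FALSE)), list(
                     transformer("t", c(z = 1), kind = "transport")))
  s0 <- network_summary(empty)
  expect_identical(s0$reactions, 0L)
  expect_identical(s0$balanced_species, 0L)
})

test_that("validation catches unused species and misclassified transformers", {
  cs <- fx_compartments()
  net <- network(cs,
                 list(species("A", "c", make_formula(c(C = 1))),
                      species("B", "c", make_formula(c(C = 1))),
                      species("x", "env", balanced = FALSE)),
                 list(transformer("t1", c(A = -1, x = 1), kind = "transport"),
                      transformer("t2", c(x = -1, A = 1), kind = "transport")))
  v <- validate_network(net)
  expect_true(any(grepl("'B' unused", v)))
  net2 <- network(cs,
                  list(species("A", "c", make_formula(c(C = 1))),
                       species("x", "env", balanced = FALSE)),
                  list(transformer("t1", c(A = -1, x = 1), kind = "reaction"),
                       transformer("t2", c(x = -1, A = 1), kind = "transport")))
  expect_true(any(grepl("spans compartments", validate_network(net2))))
})

test_that("TSV export writes both tables", {
  net <- fx_kinase()
  base <- file.path(tempdir(), "kinase")
  write_network_tsv(net, base)
  sp <- read.delim(paste0(base, ".species.tsv"))
  tr <- read.delim(paste0(base, ".transformers.tsv"))
  expect_identical(nrow(sp), 9L)
  expect_identical(nrow(tr), 7L)
  expect_true(any(grepl("glc:-1", tr$stoichiometry)))
})
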