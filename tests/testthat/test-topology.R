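# topology kernel: df, nullspace, moieties, routes, dead ends, EFMs

test_that("degrees of freedom on hand fixtures", {
  expect_identical(degrees_of_freedom(fx_chain()),
                   list(total = 1L, inner = 0L, outer = 1L))
  d <- degrees_of_freedom(fx_diamond())
  expect_identical(d$inner, 1L)
  expect_identical(d$total, 2L)
  # empty matrix edge case
  empty <- network(list(compartment("env", kind = "environment")),
                   list(species("z", "env", balanced = FALSE)),
                   list(transformer("t", c(z = 1), kind = "transport")))
  sm <- stoich_matrix(empty)
  expect_identical(dim(sm$S$n), c(0L, 1L))
})

test_that("stoich matrix reproduces coefficients; chain nullspace is (1,1,1)", {
  sm <- stoich_matrix(fx_chain())
  expect_identical(sm$S$n["A", ], c(v1 = 1, v2 = -1, v3 = 0))
  B <- nullspace_basis(sm)
  expect_identical(dim(B), c(3L, 1L))
  expect_true(all(B[, 1] == c(1, 1, 1)))
})

test_that("nullspace residual is exactly zero on random synthetic networks", {
  for (seed in 1:10) {
    g <- suppressMessages(gen_network(synthetic_spec(seed = seed)))
    sm <- stoich_matrix(g$network)
    B <- nullspace_basis(sm)
    d <- degrees_of_freedom(sm)
    expect_identical(ncol(B), d$total)
    expect_identical(d$inner + d$outer, d$total)
    if (ncol(B))
      expect_true(max(abs((sm$S$n / sm$S$d) %*% B)) == 0)
  }
})

test_that("conserved moieties: kinase ATP/ADP pair, exact left-null", {
  cm <- conserved_moieties(fx_kinase())
  keys <- lapply(cm$moieties, function(w) sort(names(w)))
  expect_true(list(c("adp", "atp")) %in% keys)
  sm <- stoich_matrix(fx_kinase())
  for (w in cm$moieties) {
    wv <- numeric(length(sm$species))
    wv[match(names(w), sm$species)] <- w
    expect_true(max(abs(t(wv) %*% (sm$S$n / sm$S$d))) == 0)
    expect_true(all(w > 0))
  }
})

test_that("moiety enumeration raises a resource error instead of truncating", {
  g <- suppressMessages(gen_network(synthetic_spec(seed = 5,
                                                   planted_moieties = 3)))
  expect_error(conserved_moieties(g$network, max_rays = 1L), "limit")
})

test_that("dead ends respect reversibility", {
  cs <- fx_compartments()
  net <- network(cs,
                 list(species("x", "env", balanced = FALSE),
                      species("A", "c", make_formula(c(C = 1))),
                      species("B", "c", make_formula(c(C = 1))),
                      species("C1", "c", make_formula(c(C = 1)))),
                 list(transformer("in", c(x = -1, A = 1), kind = "transport"),
                      transformer("r1", c(A = -1, B = 1)),
                      transformer("r2", c(B = -1, C1 = 1), reversible = TRUE)))
  de <- dead_ends(net)
  expect_false("C1" %in% de)     # reversible consumer/producer
  net2 <- network(cs,
                  list(species("x", "env", balanced = FALSE),
                       species("A", "c", make_formula(c(C = 1))),
                       species("B", "c", make_formula(c(C = 1)))),
                  list(transformer("in", c(x = -1, A = 1), kind = "transport"),
                       transformer("r1", c(A = -1, B = 1))))
  expect_identical(dead_ends(net2), "B")
})

test_that("parallel routes: duplicated reaction gives one internal cycle", {
  pr <- parallel_routes(fx_diamond())
  expect_identical(pr$n, 1L)
  r <- pr$routes[[1]]
  expect_identical(sort(names(r)), c("r1", "r2"))
  expect_identical(sum(r), 0)
  # synthetic ground truth
  for (k in 0:3) {
    g <- suppressMessages(gen_network(synthetic_spec(seed = 7 + k,
                                                     planted_cycles = k)))
    expect_identical(parallel_routes(g$network)$n, k)
  }
})

test_that("elementary modes match hand counts and the brute-force oracle", {
  expect_length(elementary_modes(fx_chain()), 1L)
  expect_length(elementary_modes(fx_diamond()), 2L)
  for (seed in c(1, 2, 3)) {
    g <- suppressMessages(gen_network(synthetic_spec(
      seed = seed, n_species = 4, n_reactions = 3, planted_moieties = 1,
      planted_cycles = 1, exchange_count = 2)))
    net <- g$network
    sm <- stoich_matrix(net)
    if (length(sm$transformers) > 12) next
    got <- elementary_modes(net)
    want <- oracle_efms(net)
    key <- function(v) paste(sort(names(v)), collapse = ",")
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("elementary modes enforce the resource guard", {
  g <- suppressMessages(gen_network(synthetic_spec(seed = 11)))
  expect_error(elementary_modes(g$network, max_modes = 1L), "limit|max_modes")
})
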