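# Shared fixtures, built in code.

fx_compartments <- function() {
  list(compartment("env", kind = "environment"),
       compartment("c", kind = "cytoplasm"))
}

# linear chain Ein -> A -> B -> Eout
fx_chain <- function() {
  network(fx_compartments(),
          list(species("Ein", "env", balanced = FALSE),
               species("A", "c", make_formula(c(C = 1))),
               species("B", "c", make_formula(c(C = 1))),
               species("Eout", "env", balanced = FALSE)),
          list(transformer("v1", c(Ein = -1, A = 1), kind = "transport"),
               transformer("v2", c(A = -1, B = 1)),
               transformer("v3", c(B = -1, Eout = 1), kind = "transport")))
}

# diamond: A -> B two ways
fx_diamond <- function() {
  network(fx_compartments(),
          list(species("Ain", "env", balanced = FALSE),
               species("A", "c", make_formula(c(C = 1))),
               species("B", "c", make_formula(c(C = 1))),
               species("Bout", "env", balanced = FALSE)),
          list(transformer("in", c(Ain = -1, A = 1), kind = "transport"),
               transformer("r1", c(A = -1, B = 1)),
               transformer("r2", c(A = -1, B = 1)),
               transformer("out", c(B = -1, Bout = 1), kind = "transport")))
}

# kinase fixture: glc + ATP -> g6p + ADP ; ADP + Pi + H -> ATP + H2O
fx_kinase <- function() {
  network(fx_compartments(),
          list(species("glc", "c", make_formula(c(C = 6, H = 12, O = 6))),
               species("g6p", "c", make_formula(c(C = 6, H = 11, O = 9, P = 1), -2)),
               species("atp", "c", make_formula(c(C = 10, H = 12, N = 5, O = 13, P = 3), -4)),
               species("adp", "c", make_formula(c(C = 10, H = 12, N = 5, O = 10, P = 2), -3)),
               species("pi", "c", make_formula(c(H = 1, O = 4, P = 1), -2)),
               species("h", "c", make_formula(c(H = 1), 1)),
               species("h2o", "c", make_formula(c(H = 2, O = 1))),
               species("glc_e", "env", balanced = FALSE),
               species("g6p_e", "env", balanced = FALSE)),
          list(transformer("HEX", c(glc = -1, atp = -1, g6p = 1, adp = 1, h = 1)),
               transformer("REG", c(adp = -1, pi = -1, h = -1, atp = 1, h2o = 1)),
               transformer("IN", c(glc_e = -1, glc = 1), kind = "transport"),
               transformer("OUT", c(g6p = -1, g6p_e = 1), kind = "transport"),
               transformer("PIIN", c(g6p_e = -1, pi = 1), kind = "transport"),
               transformer("WOUT", c(h2o = -1, g6p_e = 1), kind = "transport"),
               transformer("HIN", c(g6p_e = -1, h = 1), kind = "transport")))
}

# session cache so expensive pfba solutions are shared across test files
pf_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})

pf_model <- function() pf_cache("model", build_model())

pf_light <- function() pf_cache("light", {
  net <- pf_model()
  pfba(net, plant_scenario("light", ratio = 0.37, net = net))
})

pf_dark <- function() pf_cache("dark", {
  net <- pf_model()
  pfba(net, plant_scenario("dark", net = net))
})

pf_sm <- function() pf_cache("sm", stoich_matrix(pf_model()))
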