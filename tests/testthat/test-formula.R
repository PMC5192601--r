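# elemental formulas

test_that("parse_formula handles integers, rationals and charge", {
  suc <- parse_formula("C12H22O11", 0)
  expect_identical(unname(suc$n), c(12, 22, 11))
  expect_identical(names(suc$n), c("C", "H", "O"))
  h <- parse_formula("H", 1)
  expect_identical(unname(h$n), 1)
  expect_identical(plantflux:::rq_format(h$charge), "1")
  bm <- parse_formula("CH1.592O0.834N0.144P0.033", 0)
  expect_identical(bm$n[["H"]] / bm$d[["H"]], 1.592)
  expect_identical(bm$n[["H"]], 199)   # exact rational 199/125
  expect_identical(bm$d[["H"]], 125)
  glucan <- parse_formula("CH5/3O5/6")
  expect_identical(glucan$n[["H"]], 5)
  expect_identical(glucan$d[["H"]], 3)
})

test_that("parse -> print -> parse is idempotent", {
  canon <- function(f) list(n = f$n[order(names(f$n))],
                            d = f$d[order(names(f$d))])
  for (tx in c("C6H12O6", "CH1.592O0.834N0.144P0.033", "C53H80O2", "H",
               "E1E22")) {
    f1 <- parse_formula(tx)
    f2 <- parse_formula(format_formula(f1))
    expect_identical(canon(f1), canon(f2), label = tx)
    expect_identical(format_formula(f1), format_formula(f2), label = tx)
  }
})

test_that("unknown symbols and malformed text are rejected with the token", {
  expect_error(parse_formula("C6Qx2"), "Qx|malformed")
  expect_error(make_formula(c(Zz = 1)), "Zz")
})

test_that("formula mass uses standard atomic masses", {
  expect_equal(formula_mass(parse_formula("C6H12O6")), 180.156, tolerance = 1e-6)
  expect_equal(formula_mass(parse_formula("C12H22O11")), 342.297, tolerance = 1e-6)
  expect_error(formula_mass(make_formula(c(E1 = 2))), "abstract")
})
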