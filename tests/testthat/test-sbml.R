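# SBML import/export

test_that("write/read round trip is lossless and deterministic", {
  for (netf in list(fx_kinase, toy_plant)) {
    net <- netf()
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(net, f)
    back <- read_sbml(f)
    expect_identical(names(back$transformers), names(net$transformers))
    expect_identical(lapply(back$transformers, `[[`, "stoich"),
                     lapply(net$transformers, `[[`, "stoich"))
    expect_identical(vapply(back$transformers, `[[`, "", "kind"),
                     vapply(net$transformers, `[[`, "", "kind"))
    expect_identical(vapply(back$transformers, `[[`, TRUE, "reversible"),
                     vapply(net$transformers, `[[`, TRUE, "reversible"))
    expect_identical(vapply(back$species, function(s) s$balanced, TRUE),
                     vapply(net$species, function(s) s$balanced, TRUE))
    f2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(net, f2)
    expect_identical(readLines(f), readLines(f2))   # byte-identical rebuild
  }
})

test_that("round trip preserves transport count of the toy plant", {
  tp <- toy_plant()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(tp, f)
  back <- read_sbml(f)
  n_tp <- sum(vapply(tp$transformers, `[[`, "", "kind") == "transport")
  expect_identical(sum(vapply(back$transformers, `[[`, "", "kind") ==
                         "transport"), n_tp)
})

test_that("species in an undeclared compartment is a load error naming it", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="m"><listOfCompartments>',
    '    <compartment id="c" constant="true"/>',
    '  </listOfCompartments><listOfSpecies>',
    '    <species id="ghost" compartment="nowhere" boundaryCondition="false"',
    '             hasOnlySubstanceUnits="false" constant="false"/>',
    '  </listOfSpecies><listOfReactions/></model></sbml>'), f)
  expect_error(read_sbml(f), "ghost")
  expect_error(read_sbml(tempfile()), "no such file")
})

test_that("foreign float stoichiometry is rationalised", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="m"><listOfCompartments>',
    '    <compartment id="env" constant="true"/>',
    '    <compartment id="c" constant="true"/>',
    '  </listOfCompartments><listOfSpecies>',
    '    <species id="a" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '    <species id="x" compartment="env" boundaryCondition="true" hasOnlySubstanceUnits="false" constant="false"/>',
    '  </listOfSpecies><listOfReactions>',
    '    <reaction id="r" reversible="false" fast="false">',
    '      <listOfReactants><speciesReference species="a" stoichiometry="0.33333333333333331" constant="true"/></listOfReactants>',
    '      <listOfProducts><speciesReference species="x" stoichiometry="1" constant="true"/></listOfProducts>',
    '    </reaction></listOfReactions></model></sbml>'), f)
  net <- read_sbml(f)   # a synthetic environment compartment is appended
  st <- net$transformers[["r"]]$stoich
  k <- match("a", st$ids)
  expect_identical(st$n[k], -1)
  expect_identical(st$d[k], 3)   # 0.3333... rationalised to 1/3
})
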