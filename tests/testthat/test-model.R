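test_that("TSV loader builds and validates a minimal chain", {
  m <- chain_model()
  expect_s3_class(m, "sm_model")
  expect_equal(nrow(m$mets), 2)
  expect_equal(nrow(m$rxns), 3)
  expect_equal(sum(m$rxns$is_exchange), 2)
  expect_equal(m$objective_id, "EX_B")
})

test_that("model TSV round-trips ids, stoichiometries and bounds exactly", {
  m <- toy_wt()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(m, f)
  m2 <- load_model_table(f, objective_id = "BIOMASS")
  expect_identical(m2$rxns$id, m$rxns$id)
  expect_identical(m2$rxns$lb, m$rxns$lb)  # reversible lb = -1000 preserved
  expect_identical(m2$rxns$ub, m$rxns$ub)
  for (id in m$rxns$id)
    expect_identical(sort(m2$stoich[[id]]), sort(m$stoich[[id]]),
                     info = id)
  expect_no_error(validate_model(m2))
})

test_that("malformed equations and duplicate ids are format errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tsubsystem",
               "BAD\t1 PEP_c + -> OAA_c\t0\t10\tx"), f)
  expect_error(load_model_table(f), "BAD")
  writeLines(c("id\tequation\tlb\tub\tsubsystem",
               "R1\t1 A_c -> 1 B_c\t0\t10\tx",
               "R1\t1 B_c -> 1 A_c\t0\t10\tx"), f)
  expect_error(load_model_table(f), "duplicate")
  writeLines(c("id\tequation\tlb\tub\tsubsystem",
               "R1\t1 A -> 1 B_c\t0\t10\tx"), f)
  expect_error(load_model_table(f), "suffix")
  expect_error(load_model_table(tempfile()), "not found")
})

test_that("validation rejects broken models and cofactor leaks", {
  m <- toy_wt()
  m$rxns$lb[1] <- 2000
  expect_error(validate_model(m), "bound")
  m <- toy_wt()
  m$stoich[["MDH"]] <- c(GHOST_c = 1)
  expect_error(validate_model(m), "GHOST")
  # an exchange draining a cofactor breaks pool closure
  m <- toy_wt()
  m$mets <- rbind(m$mets, tibble::tibble(id = "NADH_e", name = "NADH_e",
                                         compartment = "e"))
  expect_error(add_reaction(m, "EX_nadh", "1 NADH_c ->", 0, 10),
               "cofactor")
})

test_that("minimal SBML with fbc bounds reads to the same model", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini"><listOfParameters>',
    '<parameter id="lb_m10" value="-10"/><parameter id="ub_1000" value="1000"/>',
    '<parameter id="lb_0" value="0"/>',
    '</listOfParameters><listOfSpecies>',
    '<species id="A_e" compartment="e"/><species id="B_e" compartment="e"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="EX_A" reversible="true" lowerFluxBound="lb_m10" upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="AB" reversible="false" lowerFluxBound="lb_0" upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_e" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="EX_B" reversible="false" lowerFluxBound="lb_0" upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="B_e" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- load_model_table(f, dialect = "sbml", objective_id = "EX_B")
  expect_equal(nrow(m$rxns), 3)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_A"], -10)
  expect_equal(unname(m$stoich[["AB"]]["A_e"]), -1)
  expect_equal(solve_fba(m)$objective_value, 10)
})

test_that("the shipped example model equals the generated toy network", {
  f <- system.file("extdata", "toy_reductive_tca.tsv",
                   package = "succinoflux")
  m <- load_model_table(f, objective_id = "BIOMASS")
  ref <- toy_wt()
  expect_identical(m$rxns$id, ref$rxns$id)
  expect_identical(m$rxns$lb, ref$rxns$lb)
  for (id in ref$rxns$id)
    expect_identical(sort(m$stoich[[id]]), sort(ref$stoich[[id]]), info = id)
  expect_equal(solve_fba(m)$objective_value,
               solve_fba(ref)$objective_value)
})

test_that("stoichiometric matrix and transport classification are coherent", {
  m <- toy_wt()
  S <- s_matrix(m)
  expect_equal(dim(S), c(nrow(m$mets), nrow(m$rxns)))
  expect_equal(unname(S["OAA_c", "MDH"]), -1)
  expect_equal(unname(S["MAL_c", "MDH"]), 1)
  tr <- is_transport_reaction(m)
  expect_true(tr[["PYRX"]])
  expect_false(any(tr[c("GLY1", "MDH", "EX_suc", "BIOMASS", "FDH")]))
})
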