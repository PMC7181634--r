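test_that("FBA solves the chain and the hand-derived succinate optima", {
  ch <- chain_model()
  f <- solve_fba(ch)
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 10)

  # wild-type toy network, glucose 10, no maintenance, maximize succinate:
  # 20 PEP / 20 NADH from glycolysis; each succinate costs one NADH at MDH
  # and one quinol at FRD; residual pyruvate feeds formate -> quinol, so
  # 3x <= 40 and the optimum is 40/3
  m <- toy_wt(atpm_lower_bound = 0)
  m$objective_id <- "EX_suc"
  expect_equal(solve_fba(m)$objective_value, 40 / 3, tolerance = 1e-9)

  # production genotype: the formate route is dead (acetyl-CoA has no
  # sink), so NADH forces succinate = glucose uptake = 10
  p <- knockout_reactions(m, palk_knockouts())
  expect_equal(solve_fba(p)$objective_value, 10, tolerance = 1e-9)

  # all exchanges closed -> nothing to grow on
  closed <- toy_wt(glc_uptake = 0, gol_uptake = 0, co2_uptake = 0,
                   atpm_lower_bound = 0)
  expect_equal(solve_fba(closed)$objective_value, 0)
})

test_that("optimal distributions are at steady state with closed cofactor pools", {
  for (model in list(toy_wt(), toy_palk(),
                     set_medium(toy_palk(), c(EX_glc = 5, EX_gol = 10)))) {
    d <- solve_pfba(model)
    S <- s_matrix(model)
    resid <- S %*% d$fluxes[colnames(S)]
    expect_lt(max(abs(resid)), 1e-6)
    for (cof in c("NAD_c", "NADH_c", "MQ_c", "MQH2_c", "ADP_c", "ATP_c"))
      expect_lt(abs(sum(S[cof, ] * d$fluxes[colnames(S)])), 1e-6)
  }
})

test_that("media and knockouts have value semantics and validate ids", {
  m <- toy_wt()
  m2 <- set_medium(m, c(EX_glc = 5, EX_gol = 10))
  expect_equal(m2$rxns$lb[m2$rxns$id == "EX_glc"], -5)
  expect_equal(m2$rxns$lb[m2$rxns$id == "EX_gol"], -10)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_glc"], -10)  # original untouched
  expect_identical(set_medium(m, stats::setNames(numeric(0), character(0))), m)
  expect_error(set_medium(m, c(MDH = 5)), "not an exchange")
  expect_error(set_medium(m, c(EX_bogus = 5)), "unknown")

  expect_identical(knockout_reactions(m, character(0)), m)
  expect_error(knockout_reactions(m, "NOPE"), "unknown")
  dead <- knockout_reactions(m, "BIOMASS")
  expect_equal(solve_fba(dead)$objective_value, 0)
})

test_that("byproduct knockouts silence lactate and acetate export", {
  p <- toy_palk()
  fr <- run_fva(p, growth_fraction = 0, reactions = c("EX_lac", "EX_act"))
  expect_equal(fr$vmax, c(0, 0))
})

test_that("pFBA is minimal among alternative optima and kills the 2-cycle", {
  ch <- chain_model()
  pf <- solve_pfba(ch)
  expect_equal(unname(pf$fluxes[c("EX_A", "AB", "EX_B")]), c(-10, 10, 10))
  expect_equal(total_abs_flux(pf), 30)

  p <- toy_palk()
  pf <- solve_pfba(p)
  expect_equal(unname(pf$fluxes["CYC1"]), 0)
  expect_equal(unname(pf$fluxes["CYC2"]), 0)
  # alternative optima found with random secondary objectives are never
  # shorter in total flux
  set.seed(5)
  S <- s_matrix(p)
  lb <- p$rxns$lb; ub <- p$rxns$ub
  i <- match("BIOMASS", p$rxns$id)
  lb[i] <- pf$objective_value
  for (k in 1:10) {
    r <- succinoflux:::lp_solve(stats::rnorm(ncol(S)), S, rep(0, nrow(S)),
                                lb, ub, maximize = TRUE)
    expect_lte(pf$total_abs_flux, sum(abs(r$x)) + 1e-6)
  }
  expect_equal(total_abs_flux(pf), sum(abs(pf$fluxes)))  # brute-force sum
})

test_that("FVA envelopes are sound and tighten with the flux cap", {
  ch <- chain_model()
  fr <- run_fva(ch, growth_fraction = 1)
  expect_equal(fr$vmin, c(-10, 10, 10))
  expect_equal(fr$vmax, c(-10, 10, 10))

  p <- toy_palk()
  # unconstrained cycle spans its bounds; cap or cycle removal collapses it
  fr_free <- run_fva(p, 0.95, reactions = c("CYC1", "CYC2"))
  expect_equal(fr_free$vmin, c(-1000, -1000))
  expect_equal(fr_free$vmax, c(1000, 1000))
  fr_cap <- run_fva(p, 0.95, flux_cap_fraction = 0.10,
                    reactions = c("CYC1", "CYC2"))
  expect_true(all(abs(c(fr_cap$vmin, fr_cap$vmax)) < 12))
  fr_ll <- run_fva(p, 0.95, loopless = TRUE, reactions = c("CYC1", "CYC2"))
  expect_true(all(abs(c(fr_ll$vmin, fr_ll$vmax)) < 1e-9))

  # soundness: 100 independent random feasible points stay inside
  fr <- run_fva(p, 0.95)
  pts <- random_feasible_points(p, 0.95, n = 100, seed = 7)
  idx <- match(fr$reaction_id, p$rxns$id)
  expect_true(all(pts[idx, ] >= fr$vmin - 1e-6))
  expect_true(all(pts[idx, ] <= fr$vmax + 1e-6))

  # the parsimonious point at full growth satisfies the 95% constraint and
  # the cap, so it lies inside the capped envelope
  pf <- solve_pfba(p)
  fr95 <- run_fva(p, 0.95, flux_cap_fraction = 0.10)
  v <- pf$fluxes[fr95$reaction_id]
  expect_true(all(v >= fr95$vmin - 1e-6 & v <= fr95$vmax + 1e-6))
})

test_that("cycle removal zeroes pure loops, preserves exchanges, idempotent", {
  p <- toy_palk()
  d <- solve_pfba(p)
  k <- 17
  d$fluxes["CYC1"] <- k; d$fluxes["CYC2"] <- -k  # inject a pure loop
  clean <- remove_thermodynamic_cycles(d, p)
  expect_equal(unname(clean$fluxes["CYC1"]), 0)
  expect_equal(unname(clean$fluxes["CYC2"]), 0)
  ex <- p$rxns$id[p$rxns$is_exchange]
  expect_identical(clean$fluxes[ex], d$fluxes[ex])       # bit-identical
  expect_identical(clean$objective_value, d$objective_value)
  other <- setdiff(names(d$fluxes), c("CYC1", "CYC2"))
  expect_equal(clean$fluxes[other], d$fluxes[other], tolerance = 1e-9)
  again <- remove_thermodynamic_cycles(clean, p)
  expect_equal(again$fluxes, clean$fluxes, tolerance = 1e-9)
})

test_that("FBA/pFBA/FVA agree with an independent constraint-based oracle", {
  p <- toy_palk()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_cobra_json(p, f)
  out <- system2("python", c(shQuote(test_path("oracle_cobra.py")),
                             shQuote(f), "0.95"),
                 stdout = TRUE, stderr = FALSE)
  o <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(solve_fba(p)$objective_value, o$fba_objective,
               tolerance = 1e-5)
  expect_equal(solve_pfba(p)$total_abs_flux, o$pfba_total_abs_flux,
               tolerance = 1e-5)
  fr <- run_fva(p, 0.95)
  for (id in setdiff(fr$reaction_id, c("CYC1", "CYC2"))) {
    expect_equal(fr$vmin[fr$reaction_id == id], o$fva[[id]][1],
                 tolerance = 1e-5, info = id)
    expect_equal(fr$vmax[fr$reaction_id == id], o$fva[[id]][2],
                 tolerance = 1e-5, info = id)
  }
})
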