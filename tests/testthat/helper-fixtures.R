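# Shared fixtures: models are cheap to build, so no memoization.

toy_wt <- function(...) build_toy_model(...)

toy_palk <- function(...) {
  knockout_reactions(build_toy_model(...), palk_knockouts())
}

# three-reaction linear chain: uptake of A, conversion to B, export of B
chain_model <- function(uptake = 10) {
  tsv <- sprintf(paste("id\tequation\tlb\tub\tsubsystem",
                       "EX_A\t1 A_e ->\t%g\t1000\texchange",
                       "AB\t1 A_e -> 1 B_e\t0\t1000\tcore",
                       "EX_B\t1 B_e ->\t0\t1000\texchange", sep = "\n"),
                 -uptake)
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(tsv, f)
  load_model_table(f, objective_id = "EX_B")
}

# random feasible steady-state points via LPs with random objectives under
# the same constraint set as an FVA call (independent envelope probe)
random_feasible_points <- function(model, growth_fraction, n = 20,
                                   seed = 1) {
  set.seed(seed)
  fba <- solve_fba(model)
  lb <- model$rxns$lb; ub <- model$rxns$ub
  i <- match(model$objective_id, model$rxns$id)
  lb[i] <- max(lb[i], growth_fraction * fba$objective_value)
  S <- s_matrix(model)
  replicate(n, {
    r <- succinoflux:::lp_solve(stats::rnorm(ncol(S)), S, rep(0, nrow(S)),
                                lb, ub, maximize = sample(c(TRUE, FALSE), 1))
    stopifnot(r$status == "optimal")
    r$x
  })
}

# export a model as COBRA-schema JSON for the independent python oracle
write_model_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i)
    list(id = model$mets$id[i], name = model$mets$name[i],
         compartment = model$mets$compartment[i]))
  rxns <- lapply(seq_len(nrow(model$rxns)), function(i) {
    id <- model$rxns$id[i]
    list(id = id, name = id,
         metabolites = as.list(model$stoich[[id]]),
         lower_bound = model$rxns$lb[i], upper_bound = model$rxns$ub[i],
         gene_reaction_rule = "",
         objective_coefficient = as.numeric(id == model$objective_id))
  })
  jsonlite::write_json(
    list(id = "toy", version = "1",
         compartments = list(c = "cytosol", e = "extracellular"),
         metabolites = mets, reactions = rxns, genes = list()),
    path, auto_unbox = TRUE, digits = NA)
  path
}
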