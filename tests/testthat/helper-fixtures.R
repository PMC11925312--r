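# Small fixture models built in code.

# linear chain: EX_A (uptake <= cap) -> A_c -> B_c -> EX_B
chain_model <- function(uptake = 10) {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "B_e"),
    name = c("A ext", "A", "B", "B ext"),
    compartment = c("e", "c", "c", "e"),
    formula = c("C2H4", "C2H4", "C2H4", "C2H4"),
    charge = 0L, stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "At", "AB", "Bt", "EX_B"),
    name = c("A exchange", "A transport", "A to B", "B transport",
             "B exchange"),
    lower_bound = c(-uptake, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000),
    gpr = c("", "TPT1", "G1", "TPT2", ""),
    subsystem = "", category = "Other",
    is_pseudo = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    objective_coefficient = c(0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_e = -1), At = c(A_e = -1, A_c = 1),
             AB = c(A_c = -1, B_c = 1), Bt = c(B_c = -1, B_e = 1),
             EX_B = c(B_e = -1))
  metabolic_model("chain", mets, rxns, st)
}

# random bounded network over a handful of metabolites; guaranteed feasible
# (zero flux always feasible) and bounded (finite bounds everywhere)
random_lp_model <- function(seed, n_rxn = 6, n_met = 3) {
  set.seed(seed)
  mets <- data.frame(id = paste0("m", seq_len(n_met), "_c"),
                     name = "", compartment = "c", formula = "C",
                     charge = 0L, stringsAsFactors = FALSE)
  lb <- round(runif(n_rxn, -8, 0), 1)
  ub <- round(runif(n_rxn, 0.5, 8), 1)  # zero flux always feasible
  rxns <- data.frame(
    id = paste0("r", seq_len(n_rxn)), name = "", lower_bound = lb,
    upper_bound = ub, gpr = "", subsystem = "", category = "Other",
    is_pseudo = FALSE, objective_coefficient = 0, stringsAsFactors = FALSE)
  st <- lapply(seq_len(n_rxn), function(j) {
    k <- sample(1:min(3, n_met), 1)
    who <- sample(mets$id, k)
    setNames(round(runif(k, -2, 2), 1), who)
  })
  rxns$objective_coefficient[sample(n_rxn, 2)] <- round(runif(2, 0.5, 2), 1)
  metabolic_model(paste0("rand", seed), mets, rxns,
                  setNames(st, rxns$id))
}

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- make_toy_gem()
      tab <- make_protein_tables(m)
      pc <- build_pc_model(m, tab$proteins, tab$complexes)
      cache <<- list(model = m, tables = tab, pc = pc)
    }
    cache
  }
})

# a prepared sample + fit + context on the toy model, cached per session
toy_context <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- toy_fixture()
      panel <- sample_donor_proteomes(fx$tables,
                                      synthetic_spec(n_donors = 3, seed = 7))
      prep <- prepare_samples(panel$raw_matrix, panel$hb_table)
      p <- normalize_to_budget(prep$samples[[1]], fx$pc$proteins,
                               fx$pc$budget)
      fit <- fit_proteome(fx$pc, p)
      ctx <- build_context_model(fx$pc, fit)
      cache <<- list(panel = panel, prep = prep, p_data = p, fit = fit,
                     ctx = ctx)
    }
    cache
  }
})

model_lp_parts <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(A = S, b = rep(0, nrow(S)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       reactions = model$reactions$id)
}
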