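test_that("protein molar mass follows residue masses plus one water", {
  # glycine: 75.07 g/mol as free amino acid
  expect_equal(protein_molar_mass("G") * 1e6, 75.07, tolerance = 1e-3)
  # peptide-bond identity: mass(GG) = 2 mass(G) - mass(H2O)
  expect_equal(protein_molar_mass("GG"),
               2 * protein_molar_mass("G") - 18.01528e-6,
               tolerance = 1e-12)
  expect_error(protein_molar_mass(""), "empty")
  expect_error(protein_molar_mass("GAZG"), "position 3")
})

test_that("complex derivation expands OR branches and honors curated overrides", {
  m <- make_toy_gem()
  proteins <- make_protein_tables(m)$proteins
  derived <- derive_complexes(m, proteins)
  catal <- derived$catalysis
  # isozyme pair: two single-subunit complexes for GLYC
  glyc <- catal$complex_id[catal$reaction_id == "GLYC"]
  expect_length(glyc, 2)
  subs <- derived$complexes$subunits[match(glyc, derived$complexes$complex_id)]
  expect_setequal(unlist(lapply(subs, names)), c("PKLR", "PKM"))
  # AND conjunction: one heterodimer with copy number 1 each
  nak <- catal$complex_id[catal$reaction_id == "NAKATPASE"]
  expect_length(nak, 1)
  s <- derived$complexes$subunits[[match(nak, derived$complexes$complex_id)]]
  expect_identical(sort(names(s)), c("ATP1A1", "ATP1B1"))
  expect_true(all(s == 1))
  # curated {2,2} record overrides the derived composition
  curated <- data.frame(complex_id = "CPLX_NAK22",
                        subunits = "ATP1A1:2;ATP1B1:2",
                        reaction_ids = "NAKATPASE", direction = "fwd",
                        stringsAsFactors = FALSE)
  over <- derive_complexes(m, proteins, curated = curated)
  nak2 <- over$catalysis$complex_id[over$catalysis$reaction_id == "NAKATPASE"]
  expect_identical(nak2, "CPLX_NAK22")
  s2 <- over$complexes$subunits[[match(nak2, over$complexes$complex_id)]]
  expect_true(all(s2 == 2))
  # complex molar mass is the copy-weighted subunit sum
  w <- setNames(proteins$molar_mass, proteins$gene)
  expect_equal(over$complexes$molar_mass[match(nak2,
                                               over$complexes$complex_id)],
               2 * w[["ATP1A1"]] + 2 * w[["ATP1B1"]], tolerance = 1e-12)
})

test_that("rate constants scale with molar mass to the 3/4 power", {
  m <- chain_model()
  proteins <- protein_table(gene = c("TPT1", "TPT2", "G1"),
                            molar_mass_da = c(5e4, 5e4, 5e4))
  cx <- derive_complexes(m, proteins)
  budget <- budget_config()
  # all complexes at the mean mass: k equals k_avg = 2.34e5 / hr
  rates <- estimate_rate_constants(cx, model = m, budget = budget)
  expect_equal(unique(rates$k_fwd), 2.34e5, tolerance = 1e-12)
  expect_equal(unique(rates$r_fwd), 1, tolerance = 1e-12)
  # irreversible reactions get k_rev = 0; reversible keep it
  expect_true(all(rates$k_rev == 0))  # chain reactions have v_lb = 0
  m2 <- m
  m2$reactions$lower_bound[m2$reactions$id == "AB"] <- -10
  rates2 <- estimate_rate_constants(cx, model = m2, budget = budget)
  expect_gt(rates2$k_rev[rates2$reaction_id == "AB"], 0)
  # a complex 16x the mean mass gets 16^(3/4) = 8 times k_avg
  proteins3 <- protein_table(gene = c("TPT1", "TPT2", "G1"),
                             molar_mass_da = c(2e4, 2e4, 16 * 13e3))
  cx3 <- derive_complexes(m, proteins3)
  mbar <- mean(cx3$complexes$molar_mass)
  heavy <- cx3$complexes$complex_id[cx3$complexes$molar_mass ==
                                      max(cx3$complexes$molar_mass)]
  rates3 <- estimate_rate_constants(cx3, model = m, budget = budget)
  kh <- rates3$k_fwd[rates3$complex_id == heavy][1]
  mh <- max(cx3$complexes$molar_mass)
  expect_equal(kh, budget$k_avg * (mh / mbar)^0.75, tolerance = 1e-12)
})

test_that("building a one-reaction PC model adds the expected variables", {
  m <- chain_model()
  m$reactions$gpr <- c("", "", "GA and GB", "", "")
  m$genes <- data.frame(symbol = c("GA", "GB"), accession = "",
                        stringsAsFactors = FALSE)
  proteins <- protein_table(gene = c("GA", "GB"),
                            molar_mass_da = c(3e4, 4e4),
                            is_hemoglobin = FALSE)
  pc <- build_pc_model(m, proteins)
  added <- setdiff(pc$reactions$id, m$reactions$id)
  # 2 protein dilutions + 2 protein sinks + 1 complex + 1 enzyme entity
  # + 1 capacity sink + 3 budget reactions
  expect_setequal(added, c("prot_GA", "prot_GB", "sink_prot_GA",
                           "sink_prot_GB", "cplx_CPLX_GA_GB",
                           "enz_fwd_AB", "sink_capf_AB", "budget_total",
                           "budget_hb", "budget_la"))
  expect_identical(length(pc$enzymatic_reactions), 1L)
})

test_that("zero enzyme abundance forces zero flux through its reaction", {
  fx <- toy_fixture()
  pc <- fx$pc
  pc <- set_bounds(pc, "enz_fwd_GLCt", upper = 0)
  if ("enz_rev_GLCt" %in% pc$reactions$id) {
    pc <- set_bounds(pc, "enz_rev_GLCt", upper = 0)
  }
  pc$budget <- NULL  # plain LP on the augmented stoichiometry
  rng <- fva(pc, 0, reactions = "GLCt")
  expect_equal(rng$min, 0, tolerance = 1e-8)
  expect_equal(rng$max, 0, tolerance = 1e-8)
})

test_that("with open budgets and huge k_avg, PC-FBA equals base FBA", {
  m <- make_toy_gem()
  tab <- make_protein_tables(m)
  open <- budget_config(p_hb_lb = 0, k_avg = 1e12)
  pc <- build_pc_model(m, tab$proteins,
                       derive_complexes(m, tab$proteins), budget = open)
  expect_equal(fba(pc, objective = "NAKATPASE")$objective_value,
               fba(m)$objective_value, tolerance = 1e-6)
})

test_that("hemoglobin and low-abundance budgets partition the proteome mass", {
  fx <- toy_fixture()
  sol <- fba(fx$pc, objective = "NAKATPASE")
  f <- sol$fluxes
  w <- setNames(fx$pc$proteins$molar_mass, fx$pc$proteins$gene)
  hb <- fx$pc$proteins$is_hemoglobin
  p <- f[paste0("prot_", names(w))]
  expect_equal(unname(f["budget_hb"]), sum(p[hb] * w[hb]),
               tolerance = 1e-6)
  expect_equal(unname(f["budget_la"]), sum(p[!hb] * w[!hb]),
               tolerance = 1e-6)
  expect_equal(unname(f["budget_total"]), unname(f["budget_hb"]) +
                 unname(f["budget_la"]), tolerance = 1e-6)
})

test_that("raising the low-abundance budget never lowers the PC-FBA optimum", {
  m <- make_toy_gem()
  tab <- make_protein_tables(m)
  vals <- c(5, 20, 50, 100)
  opts <- vapply(vals, function(ub) {
    b <- budget_config(p_la_ub = ub, p_la_ub_fit = min(ub, 50))
    pc <- build_pc_model(m, tab$proteins,
                         derive_complexes(m, tab$proteins), budget = b)
    fba(pc, objective = "NAKATPASE")$objective_value
  }, numeric(1))
  expect_true(all(diff(opts) >= -1e-8))
})

test_that("protein and complex tables round-trip through TSV", {
  fx <- toy_fixture()
  dir <- withr::local_tempdir()
  ppath <- file.path(dir, "proteins.tsv")
  write_protein_table(fx$tables$proteins, ppath)
  rt <- read_protein_table(ppath)
  expect_identical(rt$gene, fx$tables$proteins$gene)
  expect_equal(rt$molar_mass, fx$tables$proteins$molar_mass,
               tolerance = 1e-9)
  expect_identical(rt$is_hemoglobin, fx$tables$proteins$is_hemoglobin)
  cpath <- file.path(dir, "complexes.tsv")
  write_complex_table(fx$tables$complexes, cpath)
  cur <- read_complex_table(cpath)
  expect_true("CPLX_NAKATPASE" %in% cur$complex_id)
})

test_that("construction errors name the offending gene or reaction", {
  m <- make_toy_gem()
  proteins <- make_protein_tables(m)$proteins
  expect_error(build_pc_model(m, proteins[proteins$gene != "PKM", ]),
               "PKM")
  cx <- derive_complexes(m, proteins)
  cx$catalysis <- cx$catalysis[cx$catalysis$reaction_id != "GLCt", ]
  expect_error(build_pc_model(m, proteins, cx), "GLCt")
})
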