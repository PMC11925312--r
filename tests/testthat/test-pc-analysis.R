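test_that("variability at fraction zero equals plain FVA on the context model", {
  ctx <- toy_context()$ctx
  res <- pc_fva(ctx, "NAKATPASE", fractions = 0,
                reactions = c("GLCt", "GLYC", "NAKATPASE"))
  plain <- fva(ctx, 0, reactions = c("GLCt", "GLYC", "NAKATPASE"))
  expect_equal(res$envelope$effective_min, plain$min, tolerance = 1e-8)
  expect_equal(res$envelope$effective_max, plain$max, tolerance = 1e-8)
})

test_that("per-fraction ranges nest and the envelope is their union", {
  ctx <- toy_context()$ctx
  res <- pc_fva(ctx, "NAKATPASE", fractions = c(0, 0.5, 0.9, 0.99),
                reactions = c("GLCt", "GLYC", "LACt", "NAKATPASE"))
  bf <- res$by_fraction
  for (r in unique(bf$reaction_id)) {
    sub <- bf[bf$reaction_id == r, ]
    sub <- sub[order(sub$fraction), ]
    expect_true(all(diff(sub$min) >= -1e-6), info = r)
    expect_true(all(diff(sub$max) <= 1e-6), info = r)
    env <- res$envelope[res$envelope$reaction_id == r, ]
    expect_equal(env$effective_min, min(sub$min), tolerance = 1e-9)
    expect_equal(env$effective_max, max(sub$max), tolerance = 1e-9)
  }
})

test_that("context-model ranges match an independent LP oracle", {
  ctx <- toy_context()$ctx
  reactions <- c("GLCt", "GLYC", "NAKATPASE")
  res <- pc_fva(ctx, "NAKATPASE", fractions = c(0, 0.9),
                reactions = reactions)
  lp <- model_lp_parts(ctx)
  opt <- highs_lp_oracle(as.numeric(lp$reactions == "NAKATPASE"),
                         lp$A, lp$b, lp$lb, lp$ub)$objective
  for (f in c(0, 0.9)) {
    A <- lp$A; b <- lp$b; lb <- lp$lb; ub <- lp$ub
    if (f > 0) {
      A <- rbind(cbind(A, 0),
                 c(as.numeric(lp$reactions == "NAKATPASE"), -1))
      b <- c(b, f * opt); lb <- c(lb, 0); ub <- c(ub, Inf)
    }
    for (r in reactions) {
      cvec <- c(as.numeric(lp$reactions == r), numeric(ncol(A) -
                                                         length(lp$reactions)))
      hi <- highs_lp_oracle(cvec, A, b, lb, ub, maximize = TRUE)
      row <- res$by_fraction[res$by_fraction$reaction_id == r &
                               res$by_fraction$fraction == f, ]
      expect_equal(row$max, hi$objective, tolerance = 1e-5,
                   info = paste(r, "fraction", f))
    }
  }
})

test_that("enzyme abundance ranges respect mass limits and an LP oracle", {
  ctx <- toy_context()$ctx
  rng <- enzyme_abundance_range(ctx, "GLCt")
  expect_lte(rng["min"], rng["max"])
  # oracle on the same quantity
  lp <- model_lp_parts(ctx)
  cvec <- as.numeric(lp$reactions %in% c("enz_fwd_GLCt", "enz_rev_GLCt"))
  hi <- highs_lp_oracle(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  expect_equal(unname(rng["max"]), hi$objective, tolerance = 1e-5)
  # no enzyme entity for spontaneous reactions
  expect_error(enzyme_abundance_range(ctx, "NAt"), "no enzyme entity")
  # mass bound: abundance cannot exceed the mass budget over the lightest
  # member complex
  budget_mass <- 100 + ctx$p_r_ub  # LA analysis budget + relaxation
  wmin <- min(ctx$complexes$molar_mass[ctx$complexes$complex_id %in%
                ctx$catalysis$complex_id[ctx$catalysis$reaction_id == "GLCt"]])
  r_max <- max(ctx$rates$r_fwd[ctx$rates$reaction_id == "GLCt"])
  expect_lte(rng["max"], r_max * budget_mass / wmin + 1e-6)
})

test_that("spearman_rho matches the rank-then-Pearson oracle, ties included", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(3:50, 1)
    x <- sample(1:8, n, replace = TRUE) + stats::runif(n, 0, 0.01)
    y <- if (trial %% 3 == 0) -x + stats::rnorm(n, 0, 0.5) else
      sample(1:5, n, replace = TRUE)
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12, info = paste("trial", trial))
  }
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_true(is.na(spearman_rho(c(1, NA), c(2, 3))))
})

test_that("classification thresholds and forced-independent rules apply", {
  samples <- paste0("s", 1:8)
  x <- 1:8
  flux <- cbind(dep = x, cor_r = c(1, 2, 3, 4, 5, 6, 8, 7) +
                  c(0, 3, -2, 1, 0, -1, 0, 2),
                indep = rep(2, 8), spont = x, blk = x)
  abund <- cbind(dep = x^2, cor_r = x, indep = x, spont = x, blk = x)
  rownames(flux) <- rownames(abund) <- samples
  gprs <- c(dep = "G1", cor_r = "G2", indep = "G3", spont = "", blk = "G4")
  cl <- classify_reactions(flux, abund, blocked = "blk", gprs = gprs)
  got <- setNames(cl$class, cl$reaction_id)
  expect_identical(got[["dep"]], "abundance-dependent")
  expect_identical(got[["spont"]], "abundance-independent")
  expect_identical(got[["blk"]], "abundance-independent")
  expect_identical(got[["indep"]], "abundance-independent")
  expect_identical(cl$flag[cl$reaction_id == "indep"], "undefined-rho")
  expect_identical(cl$flag[cl$reaction_id == "spont"], "spontaneous")
  expect_identical(cl$flag[cl$reaction_id == "blk"], "blocked")
  # the three classes partition the reactions
  expect_identical(sum(table(cl$class)), nrow(cl))
  # boundary values: rho exactly at the thresholds
  flux2 <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 4, 3))
  abund2 <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4))
  rownames(flux2) <- rownames(abund2) <- paste0("t", 1:4)
  cl2 <- classify_reactions(flux2, abund2,
                            gprs = c(r1 = "G", r2 = "G"),
                            dependent_threshold = 1,
                            correlated_threshold = 0.8)
  expect_identical(cl2$class, c("abundance-dependent",
                                "abundance-correlated"))
})

test_that("proteins sharing identical reaction sets are grouped", {
  fx <- toy_fixture()
  cl <- data.frame(reaction_id = c("GLYC", "NAKATPASE"),
                   rho = 1, class = "abundance-dependent",
                   category = NA, flag = "", stringsAsFactors = FALSE)
  class(cl) <- c("reaction_classification", "data.frame")
  groups <- protein_reaction_groups(cl, fx$model)
  # PKLR and PKM share {GLYC}; ATP1A1 and ATP1B1 share {NAKATPASE}
  expect_true("PKLR;PKM" %in% groups$genes)
  expect_true("ATP1A1;ATP1B1" %in% groups$genes)
})

test_that("metadata correlation finds planted identities and clusters duplicates", {
  set.seed(9)
  n <- 20
  vals <- cbind(rA = stats::runif(n), rB = stats::runif(n),
                rC = stats::runif(n))
  rownames(vals) <- paste0("s", 1:n)
  md <- data.frame(copy = vals[, "rB"],
                   copy_mono = exp(3 * vals[, "rB"]),
                   twin1 = vals[, "rA"] + 100,
                   twin2 = vals[, "rA"] + 100,
                   junk = rep(NA_real_, n),
                   row.names = rownames(vals))
  expect_warning(res <- correlate_metadata(md, vals), "junk")
  expect_equal(res$correlation["copy", "rB"], 1, tolerance = 1e-12)
  # rank invariance under strictly monotone transforms
  expect_equal(res$correlation["copy_mono", ],
               res$correlation["copy", ], tolerance = 1e-12)
  # identical rows end adjacent after clustering
  ord <- res$row_order
  pos <- match(c("twin1", "twin2"), rownames(res$correlation)[ord])
  expect_equal(abs(diff(pos)), 1)
})

test_that("the representative model envelopes every context it is built from", {
  fx <- toy_fixture()
  tc <- toy_context()
  p2 <- tc$p_data
  p2["SLC2A1"] <- p2["SLC2A1"] * 3
  fit2 <- fit_proteome(fx$pc, p2)
  ctx1 <- tc$ctx
  ctx2 <- build_context_model(fx$pc, fit2)
  reactions <- c("GLCt", "GLYC", "NAKATPASE", "LACt")
  env1 <- pc_fva(ctx1, "NAKATPASE", fractions = 0,
                 reactions = reactions)$envelope
  env2 <- pc_fva(ctx2, "NAKATPASE", fractions = 0,
                 reactions = reactions)$envelope
  rep1 <- build_representative_model(fx$pc, list(env1))
  idx <- match(reactions, rep1$reactions$id)
  expect_equal(rep1$reactions$lower_bound[idx], env1$effective_min,
               tolerance = 1e-12)
  expect_equal(rep1$reactions$upper_bound[idx], env1$effective_max,
               tolerance = 1e-12)
  rep12 <- build_representative_model(fx$pc, list(env1, env2))
  idx <- match(reactions, rep12$reactions$id)
  expect_equal(rep12$reactions$lower_bound[idx],
               pmin(env1$effective_min, env2$effective_min),
               tolerance = 1e-12)
  expect_equal(rep12$reactions$upper_bound[idx],
               pmax(env1$effective_max, env2$effective_max),
               tolerance = 1e-12)
  # every context range is contained in the representative bounds
  for (env in list(env1, env2)) {
    expect_true(all(env$effective_min >=
                      rep12$reactions$lower_bound[idx] - 1e-9))
    expect_true(all(env$effective_max <=
                      rep12$reactions$upper_bound[idx] + 1e-9))
  }
  expect_error(build_representative_model(fx$pc, list()), "no context")
})
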