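test_that("sample preparation drops incomplete donors and imputes hemoglobin", {
  fx <- toy_fixture()
  panel <- sample_donor_proteomes(fx$tables,
                                  synthetic_spec(n_donors = 5, seed = 11,
                                                 hb_missing_rate = 0))
  raw <- panel$raw_matrix
  hb <- panel$hb_table
  # drop one donor's day-42 column: all three of its samples must go
  raw2 <- raw[, colnames(raw) != "D002_42"]
  prep <- prepare_samples(raw2, hb)
  expect_identical(prep$dropped_donors, "D002")
  expect_identical(length(prep$samples), 3L * 4L)
  # missing hemoglobin concentration is imputed with the donor mean
  hb2 <- hb
  hb2$hb_concentration[1] <- NA
  prep2 <- prepare_samples(raw, hb2)
  expect_identical(prep2$n_imputed_hb, 1L)
  d1 <- prep2$samples[[1]]
  expect_equal(d1$hb_concentration, mean(hb$hb_concentration[-1]),
               tolerance = 1e-12)
  # unknown donor is an error
  raw3 <- raw
  colnames(raw3)[1] <- "GHOST_10"
  expect_error(prepare_samples(raw3, hb), "unknown donor")
})

test_that("retained sample count is three per retained donor", {
  fx <- toy_fixture()
  panel <- sample_donor_proteomes(fx$tables,
                                  synthetic_spec(n_donors = 8, seed = 2))
  prep <- prepare_samples(panel$raw_matrix, panel$hb_table)
  expect_identical(length(prep$samples),
                   3L * (8L - length(prep$dropped_donors)))
})

test_that("budget normalization fixes hemoglobin at 95% of protein mass", {
  fx <- toy_fixture()
  ctx <- toy_context()
  p <- ctx$p_data
  w <- setNames(fx$pc$proteins$molar_mass, fx$pc$proteins$gene)
  hb <- fx$pc$proteins$is_hemoglobin
  hb_mass <- sum(p[hb] * w[hb], na.rm = TRUE)
  la_mass <- sum(p[!hb] * w[!hb], na.rm = TRUE)
  expect_equal(hb_mass, 950, tolerance = 1e-9)
  expect_equal(la_mass, 50, tolerance = 1e-9)
  expect_equal(hb_mass / (hb_mass + la_mass), 0.95, tolerance = 1e-12)
})

test_that("normalization is invariant to the raw intensity scale", {
  fx <- toy_fixture()
  sm <- toy_context()$prep$samples[[1]]
  p1 <- normalize_to_budget(sm, fx$pc$proteins)
  sm2 <- sm
  sm2$p_data <- sm2$p_data * 7.3
  p2 <- normalize_to_budget(sm2, fx$pc$proteins)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a single measured non-hemoglobin protein carries the whole LA budget", {
  fx <- toy_fixture()
  proteins <- fx$pc$proteins
  raw <- setNames(rep(NA_real_, nrow(proteins)), proteins$accession)
  raw[proteins$accession[proteins$gene == "GYS1"]] <- 3
  raw[proteins$accession[proteins$is_hemoglobin]] <- c(100, 100)
  p <- normalize_to_budget(raw, proteins)
  w <- setNames(proteins$molar_mass, proteins$gene)
  expect_equal(unname(p["GYS1"] * w["GYS1"]), 50, tolerance = 1e-9)
  expect_true(all(is.na(p[setdiff(proteins$gene[!proteins$is_hemoglobin],
                                  "GYS1")])))
  # zero hemoglobin signal cannot be scaled
  raw[proteins$accession[proteins$is_hemoglobin]] <- 0
  expect_error(normalize_to_budget(raw, proteins), "hemoglobin")
})

test_that("a feasible target proteome is recovered exactly by the QP", {
  fx <- toy_fixture()
  ctx <- toy_context()
  fit <- ctx$fit
  expect_identical(fit$status, "optimal")
  expect_lt(fit$objective_value, 1e-10)
  meas <- !is.na(ctx$p_data)
  rel <- abs(fit$p_prime[meas] - ctx$p_data[meas]) /
    pmax(ctx$p_data[meas], 1e-9)
  expect_lt(max(rel), 1e-6)
})

test_that("missing proteins get zero weight; measured zeros get weight one", {
  fx <- toy_fixture()
  p <- toy_context()$p_data
  p["GYS1"] <- NA
  p["AQP1"] <- 0
  fit <- fit_proteome(fx$pc, p)
  expect_equal(unname(fit$weights["GYS1"]), 0)
  expect_equal(unname(fit$weights["AQP1"]), 1)
  expect_lt(abs(fit$p_prime[["AQP1"]]), 1e-6)
  # residuals of missing proteins are NA by convention
  expect_true(is.na(residuals(fit)[["GYS1"]]))
})

test_that("the model QP matches a dense KKT active-set oracle on a binding budget", {
  # five low-abundance proteins, no complexes, data oversubscribing the
  # LA budget so the budget constraint binds
  mets <- data.frame(id = "x_c", name = "", compartment = "c",
                     formula = "C", charge = 0L, stringsAsFactors = FALSE)
  rxns <- data.frame(id = "DM_x", name = "", lower_bound = 0,
                     upper_bound = 0, gpr = "", subsystem = "",
                     category = "Other", is_pseudo = TRUE,
                     objective_coefficient = 0, stringsAsFactors = FALSE)
  base <- metabolic_model("qp", mets, rxns, list(DM_x = c(x_c = -1)))
  genes <- paste0("P", 1:5)
  w <- c(0.02, 0.05, 0.03, 0.08, 0.04)
  proteins <- protein_table(gene = genes, molar_mass_da = w * 1e6,
                            is_hemoglobin = FALSE)
  budget <- budget_config(p_hb_lb = 0, p_la_ub = 100)
  pc <- build_pc_model(base, proteins,
                       list(complexes = data.frame(
                         complex_id = character(0),
                         molar_mass = numeric(0),
                         subunits = I(list())),
                         catalysis = data.frame(
                           complex_id = character(0),
                           reaction_id = character(0),
                           direction = character(0))),
                       rates = data.frame(
                         reaction_id = character(0),
                         complex_id = character(0), k_fwd = numeric(0),
                         k_rev = numeric(0), r_fwd = numeric(0),
                         r_rev = numeric(0)),
                       budget = budget)
  d <- c(400, 300, 250, 150, 500)     # mass 74 > 50: LA fitting budget binds
  p_data <- setNames(d, genes)
  fit <- fit_proteome(pc, p_data)
  expect_identical(fit$status, "optimal")
  # oracle: min sum c (p - d)^2 s.t. w'p <= 50, p >= 0
  oracle <- qp_kkt_oracle(
    a = d, W = diag(1 / d), G = rbind(w, -diag(5)), h = c(50, rep(0, 5)))
  expect_equal(unname(fit$p_prime), oracle$z, tolerance = 1e-6)
  expect_equal(fit$objective_value,
               sum((1 / d) * (fit$p_prime - d)^2), tolerance = 1e-10)
  expect_equal(sum(fit$p_prime * w), 50, tolerance = 1e-6)
})

test_that("QP objective is invariant to protein order and duplicated missing data", {
  fx <- toy_fixture()
  p <- toy_context()$p_data
  fit1 <- fit_proteome(fx$pc, p)
  fit2 <- fit_proteome(fx$pc, p[rev(names(p))])
  expect_equal(fit1$objective_value, fit2$objective_value,
               tolerance = 1e-10)
  p3 <- c(p, GHOST = NA_real_)  # unknown, unmeasured entries are ignored
  fit3 <- fit_proteome(fx$pc, p3)
  expect_equal(fit1$objective_value, fit3$objective_value,
               tolerance = 1e-10)
})

test_that("slack zero pins measured proteins and closes the relaxation pool", {
  fx <- toy_fixture()
  ctx0 <- build_context_model(fx$pc, toy_context()$fit, s = 0)
  expect_equal(ctx0$p_r_ub, 0)
  rx <- ctx0$reactions
  expect_equal(rx$upper_bound[rx$id == "budget_relax"], 0)
  fit <- toy_context()$fit
  for (g in names(fit$p_prime)) {
    i <- match(paste0("prot_", g), rx$id)
    if (is.na(fit$p_data[g])) {
      expect_equal(rx$lower_bound[i], 0)
      expect_equal(rx$upper_bound[i], 0)
    } else {
      expect_equal(rx$lower_bound[i], unname(fit$p_prime[g]))
      expect_equal(rx$upper_bound[i], unname(fit$p_prime[g]))
    }
  }
  expect_error(build_context_model(fx$pc, fit, s = -0.1), "slack")
})

test_that("the relaxation budget cap is the slack times the fitted proteome mass", {
  fx <- toy_fixture()
  fit <- toy_context()$fit
  ctx <- build_context_model(fx$pc, fit)        # default s = 0.03
  expect_equal(ctx$slack, 0.03)
  w <- setNames(fx$pc$proteins$molar_mass, fx$pc$proteins$gene)
  expect_equal(ctx$p_r_ub, 0.03 * sum(fit$p_prime[names(w)] * w),
               tolerance = 1e-9)
  # context feasible regions are nested in s
  opts <- vapply(c(0, 0.01, 0.03, 0.1), function(s) {
    fba(build_context_model(fx$pc, fit, s = s),
        objective = "NAKATPASE")$objective_value
  }, numeric(1))
  expect_true(all(diff(opts) >= -1e-8))
})

test_that("slack calibration returns the smallest plateau-reaching grid value", {
  fx <- toy_fixture()
  fit <- toy_context()$fit
  grid <- c(0, 0.01, 0.03, 0.1)
  cal <- calibrate_slack(fx$pc, list(fit), "NAKATPASE", s_grid = grid)
  # brute-force sweep oracle: recompute the objective at every grid value
  objs <- vapply(grid, function(s) {
    fba(build_context_model(fx$pc, fit, s = s),
        objective = "NAKATPASE")$objective_value
  }, numeric(1))
  ref <- objs[length(objs)]
  expected <- grid[which(objs >= 0.99 * ref)[1]]
  expect_equal(cal$s, expected)
  expect_true(all(diff(vapply(grid, function(s) {
    cal$table$objective[cal$table$s == s][1]
  }, numeric(1))) >= -1e-8))
})

test_that("an essential unmeasured enzyme forces a positive calibrated slack", {
  fx <- toy_fixture()
  p <- toy_context()$p_data
  p["ATP1A1"] <- NA   # pump alpha subunit never detected
  fit <- fit_proteome(fx$pc, p)
  grid <- c(0, 0.005, 0.02, 0.05)
  cal <- calibrate_slack(fx$pc, list(fit), "NAKATPASE", s_grid = grid)
  objs <- vapply(grid, function(s) {
    fba(build_context_model(fx$pc, fit, s = s),
        objective = "NAKATPASE")$objective_value
  }, numeric(1))
  expect_equal(objs[1], 0, tolerance = 1e-8)  # s = 0 pins it to zero
  expect_gt(cal$s, 0)
  expect_equal(cal$s, grid[which(objs >= 0.99 * objs[length(objs)])[1]])
})
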