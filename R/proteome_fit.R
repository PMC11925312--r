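# Proteome data preparation, weighted quadratic-programming fitting of
# measured proteomes onto a proteome-constrained model, slack-relaxed
# context-specific models, and slack calibration.

#' Prepare donor proteome samples
#'
#' Implements the total-protein-approach bookkeeping: per-sample relative
#' intensities are converted to copy numbers by scaling with the donor's
#' hemoglobin concentration at donation; donors lacking any of the storage
#' time points are dropped; missing hemoglobin concentrations are imputed
#' with the mean over the other donors.
#'
#' @param raw_matrix numeric matrix, rows = protein accessions (or gene
#'   symbols), columns = sample ids `"<donor>_<day>"`; `NA` marks a missing
#'   (undetected) value, which is distinct from a measured zero.
#' @param hb_table data.frame `donor_id`, `hb_concentration` (mass/volume at
#'   donation; `NA` allowed).
#' @param storage_days required storage days per donor.
#' @return list with `samples` (list of `proteome_sample` objects: `donor_id`,
#'   `storage_day`, `p_data`, `hb_concentration`), `dropped_donors`, and
#'   `n_imputed_hb`.
#' @export
prepare_samples <- function(raw_matrix, hb_table,
                            storage_days = c(10, 23, 42)) {
  cn <- colnames(raw_matrix)
  parts <- regmatches(cn, regexec("^(.+)_([0-9]+)$", cn))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) stop("sample id not of the form <donor>_<day>: ", cn[bad][1])
  donor <- vapply(parts, `[`, "", 2)
  day <- as.integer(vapply(parts, `[`, "", 3))
  unknown <- setdiff(donor, hb_table$donor_id)
  if (length(unknown)) {
    stop("sample with unknown donor: ", paste(unknown, collapse = ", "))
  }
  have <- split(day, donor)
  complete <- names(have)[vapply(have, function(d) {
    all(storage_days %in% d)
  }, logical(1))]
  dropped <- setdiff(unique(donor), complete)
  hb <- setNames(hb_table$hb_concentration, hb_table$donor_id)[complete]
  n_imputed <- sum(is.na(hb))
  if (n_imputed == length(hb)) stop("no donor has a hemoglobin concentration")
  hb[is.na(hb)] <- mean(hb, na.rm = TRUE)
  keep <- donor %in% complete & day %in% storage_days
  samples <- lapply(which(keep), function(k) {
    structure(list(donor_id = donor[k], storage_day = day[k],
                   p_data = raw_matrix[, k] * unname(hb[donor[k]]),
                   hb_concentration = unname(hb[donor[k]])),
              class = "proteome_sample")
  })
  ord <- order(vapply(samples, `[[`, "", "donor_id"),
               vapply(samples, `[[`, 0, "storage_day"))
  list(samples = samples[ord], dropped_donors = dropped,
       n_imputed_hb = n_imputed)
}

#' Scale a sample to the proteome budgets
#'
#' Rescales hemoglobin abundances so their total mass equals the fitting
#' hemoglobin budget (95% of protein content) and the remaining measured
#' proteins so their total mass equals the low-abundance fitting budget,
#' preserving within-group proportions. Proteins absent from the model's
#' protein table are ignored; missing values stay missing.
#'
#' @param sample a `proteome_sample` (or a named abundance vector keyed like
#'   the protein table's `accession` or `gene`).
#' @param proteins the model's [protein_table()].
#' @param budget a [budget_config()].
#' @return named vector over `proteins$gene` in nmol/gDW (`NA` = missing).
#' @export
normalize_to_budget <- function(sample, proteins, budget = budget_config()) {
  raw <- if (inherits(sample, "proteome_sample")) sample$p_data else sample
  key <- names(raw)
  idx <- match(key, proteins$accession)
  idx[is.na(idx)] <- match(key[is.na(idx)], proteins$gene)
  p <- setNames(rep(NA_real_, nrow(proteins)), proteins$gene)
  meas <- !is.na(idx)
  p[idx[meas]] <- raw[meas]
  w <- proteins$molar_mass
  hb <- proteins$is_hemoglobin
  hb_mass <- sum(p[hb] * w[hb], na.rm = TRUE)
  if (any(hb) && (all(is.na(p[hb])) || hb_mass <= 0)) {
    stop("zero total hemoglobin signal; cannot scale to hemoglobin budget")
  }
  if (any(hb)) p[hb] <- p[hb] * budget$p_hb_ub_fit / hb_mass
  la <- !hb
  la_mass <- sum(p[la] * w[la], na.rm = TRUE)
  if (la_mass > 0) p[la] <- p[la] * budget$p_la_ub_fit / la_mass
  p
}

#' Fit a measured proteome onto a proteome-constrained model
#'
#' Solves the convex QP `minimize sum_j c_j (p_j - p_j^data)^2` over the
#' model's full constraint set, with weights `c_j = 1/p_j^data` for positive
#' measurements, `c_j = 1` for measured zeros (penalizing expression of
#' unobserved proteins), and `c_j = 0` for missing values. During the fit
#' the budget upper bounds take their fitting values, matching the scaling
#' of [normalize_to_budget()] so an excellent fit is attainable.
#'
#' @param pc_model a `pc_model`.
#' @param p_data named vector over model genes (nmol/gDW, `NA` = missing),
#'   typically from [normalize_to_budget()].
#' @param ridge tiny diagonal regularization applied to variables outside
#'   the fitting objective (QP solver requires a positive-definite
#'   quadratic form); solver tolerance, not a model parameter.
#' @param fitting_budgets apply the fitting-mode budget upper bounds.
#' @return object of class `pc_fit`: `p_prime` (best-fit proteome, named by
#'   gene), `objective_value` (weighted squared error, ridge excluded),
#'   `status`, `fluxes` (all variable values), `p_data`, `weights`.
#' @export
fit_proteome <- function(pc_model, p_data, ridge = 1e-13,
                         fitting_budgets = TRUE) {
  stopifnot(inherits(pc_model, "pc_model"))
  model <- pc_model
  if (fitting_budgets) {
    model <- set_bounds(model, "budget_hb", upper = model$budget$p_hb_ub_fit)
    model <- set_bounds(model, "budget_la", upper = model$budget$p_la_ub_fit)
  }
  genes <- pc_model$proteins$gene
  p_data <- p_data[genes]
  names(p_data) <- genes
  weights <- ifelse(is.na(p_data), 0, ifelse(p_data > 0, 1 / p_data, 1))

  lp <- model_lp(model)
  n <- ncol(lp$A)
  rid <- lp$reactions
  pidx <- match(paste0("prot_", genes), rid)
  d <- rep(ridge, n)
  dv <- rep(0, n)
  meas <- weights > 0
  d[pidx[meas]] <- d[pidx[meas]] + weights[meas]
  dv[pidx[meas]] <- weights[meas] * p_data[meas]
  Dmat <- diag(2 * d)
  dvec <- 2 * dv

  # the QP solver needs linearly independent equality rows; stoichiometric
  # matrices carry conserved-moiety rank deficiencies, so keep a row basis
  qrA <- qr(t(lp$A))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  Aeq <- lp$A[keep, , drop = FALSE]
  beq <- lp$b[keep]
  finite_ub <- which(is.finite(lp$ub))
  Amat <- rbind(Aeq, diag(n)[seq_len(n), , drop = FALSE],
                -diag(n)[finite_ub, , drop = FALSE])
  bvec <- c(beq, lp$lb, -lp$ub[finite_ub])
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, t(Amat), bvec, meq = nrow(Aeq)),
    error = function(e) e)
  if (inherits(sol, "error")) {
    return(structure(list(p_prime = NULL, objective_value = NA_real_,
                          status = paste("solver error:",
                                         conditionMessage(sol)),
                          fluxes = NULL, p_data = p_data,
                          weights = weights),
                     class = "pc_fit"))
  }
  x <- setNames(sol$solution, rid)
  p_prime <- pmax(setNames(x[pidx], genes), 0)
  obj <- sum(weights[meas] * (p_prime[meas] - p_data[meas])^2)
  structure(list(p_prime = p_prime, objective_value = obj,
                 status = "optimal", fluxes = x, p_data = p_data,
                 weights = weights),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat("<pc_fit> status:", x$status, "\n")
  if (!is.null(x$p_prime)) {
    cat("  proteins:", length(x$p_prime),
        " measured:", sum(!is.na(x$p_data)),
        " weighted SSE:", format(x$objective_value, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
coef.pc_fit <- function(object, ...) object$p_prime

#' @export
residuals.pc_fit <- function(object, ...) {
  r <- object$p_prime - object$p_data
  r[is.na(object$p_data)] <- NA_real_
  r
}

#' @export
summary.pc_fit <- function(object, ...) {
  r <- residuals(object)
  out <- list(status = object$status,
              objective_value = object$objective_value,
              n_measured = sum(!is.na(object$p_data)),
              n_missing = sum(is.na(object$p_data)),
              max_abs_residual = if (all(is.na(r))) NA_real_ else
                max(abs(r), na.rm = TRUE))
  class(out) <- "summary.pc_fit"
  out
}

#' @export
print.summary.pc_fit <- function(x, ...) {
  cat("Proteome fit:", x$status, "\n",
      " measured proteins:", x$n_measured,
      " missing:", x$n_missing, "\n",
      " weighted SSE:", format(x$objective_value, digits = 6),
      " max |residual|:", format(x$max_abs_residual, digits = 6), "\n")
  invisible(x)
}

#' Build a context-specific model from a fitted proteome
#'
#' Installs the relaxation budget `P_R` (a pool of unspecified protein mass
#' absorbing measurement and workflow uncertainty) with upper bound
#' `P_R_ub = s * sum_j p'_j w_j`, and per-protein bounds: measured proteins
#' in `[(1 - s) p'_j, p'_j + s * P_R_ub / w_j]`, unmeasured proteins in
#' `[0, s * P_R_ub / w_j]`. With `s = 0` the fitted proteome is pinned
#' exactly. The analysis-mode budget bounds are restored.
#'
#' @param pc_model the `pc_model` the fit was computed on.
#' @param fit a `pc_fit`.
#' @param s slack term in `[0, 1]`; default from the model's budget config.
#' @return object of class `context_model` (inherits `pc_model`) with
#'   `slack` and `p_r_ub` recorded.
#' @export
build_context_model <- function(pc_model, fit, s = NULL) {
  stopifnot(inherits(pc_model, "pc_model"), inherits(fit, "pc_fit"))
  if (is.null(s)) s <- pc_model$budget$slack
  if (s < 0 || s > 1) stop("slack s must be in [0, 1]")
  if (is.null(fit$p_prime)) stop("cannot build context model: fit status is ",
                                 fit$status)
  w <- setNames(pc_model$proteins$molar_mass, pc_model$proteins$gene)
  p <- fit$p_prime[names(w)]
  p_r_ub <- s * sum(p * w)
  ctx <- pc_model
  ctx$reactions$upper_bound[match("budget_hb", ctx$reactions$id)] <-
    pc_model$budget$p_hb_ub
  ctx$reactions$upper_bound[match("budget_la", ctx$reactions$id)] <-
    pc_model$budget$p_la_ub
  measured <- !is.na(fit$p_data[names(w)])
  lb <- ifelse(measured, (1 - s) * p, 0)
  ub <- ifelse(measured, p + s * p_r_ub / w, s * p_r_ub / w)
  idx <- match(paste0("prot_", names(w)), ctx$reactions$id)
  ctx$reactions$lower_bound[idx] <- pmax(lb, 0)
  ctx$reactions$upper_bound[idx] <- pmax(ub, 0)
  ctx$reactions <- rbind(ctx$reactions, data.frame(
    id = "budget_relax", name = "relaxation proteome budget",
    lower_bound = 0, upper_bound = p_r_ub, gpr = "",
    subsystem = "Proteome constraints", category = "Other", is_pseudo = TRUE,
    objective_coefficient = 0, stringsAsFactors = FALSE))
  ctx$stoichiometry$budget_relax <- c(budget_total_p = -1)
  ctx$slack <- s
  ctx$p_r_ub <- p_r_ub
  class(ctx) <- c("context_model", class(pc_model))
  ctx
}

#' Calibrate the relaxation slack term
#'
#' For each slack value on an increasing grid, builds context models for the
#' supplied (typically mean/median) fits and solves the lexicographic
#' problem: maximize flux through the objective reaction, then minimize the
#' utilized relaxation budget at that optimum. Returns the smallest grid
#' value at which every calibration model attains at least
#' `plateau` (99%) of its objective at the largest slack.
#'
#' @param pc_model a `pc_model`.
#' @param fits list of `pc_fit` objects.
#' @param objective_reaction reaction id to maximize.
#' @param s_grid increasing slack values (at least 2).
#' @param plateau fraction of the largest-slack objective that counts as
#'   converged.
#' @return list `s` (chosen slack), `table` (data.frame: `s`, `fit`,
#'   `objective`, `relax_used`).
#' @export
calibrate_slack <- function(pc_model, fits, objective_reaction,
                            s_grid = c(0, 0.01, 0.02, 0.03, 0.05, 0.1),
                            plateau = 0.99) {
  stopifnot(length(s_grid) >= 2, !is.unsorted(s_grid))
  rows <- list()
  for (s in s_grid) {
    for (f in seq_along(fits)) {
      ctx <- build_context_model(pc_model, fits[[f]], s = s)
      lp <- model_lp(ctx)
      cvec <- objective_vector(ctx, objective_reaction)
      sol <- solve_lp(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
      if (sol$status != "optimal") {
        rows[[length(rows) + 1L]] <- data.frame(
          s = s, fit = f, objective = NA_real_, relax_used = NA_real_)
        next
      }
      # lexicographic step: fix the optimum (to tolerance), minimize P_R
      A2 <- rbind(cbind(lp$A, 0), c(cvec, -1))
      b2 <- c(lp$b, sol$objective - 1e-9 * max(1, abs(sol$objective)))
      relax <- rep(0, ncol(A2))
      relax[match("budget_relax", lp$reactions)] <- 1
      sol2 <- solve_lp(relax, A2, b2, c(lp$lb, 0), c(lp$ub, Inf),
                       maximize = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        s = s, fit = f, objective = sol$objective,
        relax_used = if (sol2$status == "optimal") sol2$objective else
          NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  smax <- max(s_grid)
  ref <- tab$objective[tab$s == smax]
  if (all(is.na(ref)) || all(ref[!is.na(ref)] == 0)) {
    warning("objective is zero (or unsolved) at every slack value; ",
            "returning the largest grid value")
    return(list(s = smax, table = tab))
  }
  for (s in s_grid) {
    obj <- tab$objective[tab$s == s]
    if (!anyNA(obj) && all(obj >= plateau * ref)) {
      return(list(s = s, table = tab))
    }
  }
  list(s = smax, table = tab)
}
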