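# Linear programming on metabolic models: flux balance analysis (FBA), flux
# variability analysis (FVA), and blocked-reaction detection.  The LP core is
# a compiled bounded-variable primal simplex (src/simplex.cpp) with row
# equilibration for the wide coefficient ranges that proteome-constrained
# models produce (stoichiometric coefficients ~1 next to rate constants
# ~1e5).

#' Solve a linear program
#'
#' `maximize c'x` subject to `A x = b`, `lb <= x <= ub`. Upper bounds may be
#' `Inf`; lower bounds must be finite.
#'
#' @param obj objective coefficients.
#' @param A constraint matrix (dense or `Matrix` sparse).
#' @param b right-hand side.
#' @param lb,ub variable bounds.
#' @param maximize direction; `FALSE` minimizes.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x`, and `objective`.
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == nrow(A))
  if (any(!is.finite(lb))) stop("lower bounds must be finite (use a sentinel)")
  # row equilibration: scale each row (and rhs) by its largest coefficient
  scale <- apply(abs(A), 1, max)
  scale[scale < .Machine$double.eps] <- 1
  As <- A / scale
  bs <- b / scale
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)
  res <- .simplex_solve(As, bs, cc, as.numeric(lb), as.numeric(ub), tol = tol)
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  x <- if (status == "optimal") as.numeric(res$x) else NULL
  objective <- if (status == "optimal") sum(obj * x)
               else if (status == "unbounded") (if (maximize) Inf else -Inf)
               else NA_real_
  list(status = status, x = x, objective = objective)
}

# Internal: LP data (A, b, lb, ub) for a model.  Bounds pass through
# unchanged: the +-1000 mmol/gDW/hr convention acts as an ordinary large
# finite bound, and genuinely infinite upper bounds (slack sinks, default
# protein caps) are handled natively by the simplex.
model_lp <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(A = S, b = rep(0, nrow(S)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       reactions = model$reactions$id)
}

objective_vector <- function(model, objective = NULL) {
  n <- nrow(model$reactions)
  if (is.null(objective)) {
    cvec <- model$reactions$objective_coefficient
    if (all(cvec == 0)) stop("model has no objective; supply `objective`")
  } else if (is.character(objective)) {
    cvec <- as.numeric(model$reactions$id %in% objective)
    if (sum(cvec) != length(objective)) stop("unknown objective reaction")
  } else {
    cvec <- rep(0, n)
    idx <- match(names(objective), model$reactions$id)
    if (anyNA(idx)) stop("unknown objective reaction")
    cvec[idx] <- unname(objective)
  }
  cvec
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear objective over the steady-state flux
#' polytope `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id (or named coefficient vector); default: the
#'   model's stored objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution`: list with `status`, `objective_value`, and the
#'   named flux vector `fluxes`. Infeasibility/unboundedness is surfaced in
#'   `status`, never silently zeroed.
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- model_lp(model)
  cvec <- objective_vector(model, objective)
  res <- solve_lp(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = sense == "max")
  fluxes <- if (is.null(res$x)) NULL else setNames(res$x, lp$reactions)
  structure(list(status = res$status, objective_value = res$objective,
                 fluxes = fluxes, sense = sense),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 8), "\n")
  invisible(x)
}

# Internal engine shared by fva() and pc_fva(): per-reaction min/max with the
# objective constrained to >= fraction * optimum.
fva_engine <- function(model, fraction_of_optimum, reactions, objective = NULL,
                       tol = 1e-9) {
  lp <- model_lp(model)
  n <- ncol(lp$A)
  if (is.null(reactions)) reactions <- lp$reactions
  idx <- match(reactions, lp$reactions)
  if (anyNA(idx)) stop("unknown reaction: ", reactions[is.na(idx)][1])
  A <- lp$A; b <- lp$b; lb <- lp$lb; ub <- lp$ub
  if (fraction_of_optimum > 0) {
    cvec <- objective_vector(model, objective)
    opt <- solve_lp(cvec, A, b, lb, ub, maximize = TRUE)
    if (opt$status != "optimal") {
      stop("base objective problem is ", opt$status,
           "; cannot apply fraction_of_optimum")
    }
    # c'v - s = f*opt with s >= 0
    A <- rbind(cbind(A, 0), c(cvec, -1))
    b <- c(b, fraction_of_optimum * opt$objective)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  mins <- maxs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    cvec <- rep(0, ncol(A)); cvec[idx[k]] <- 1
    lo <- solve_lp(cvec, A, b, lb, ub, maximize = FALSE, tol = tol)
    hi <- solve_lp(cvec, A, b, lb, ub, maximize = TRUE, tol = tol)
    mins[k] <- if (lo$status == "optimal") lo$objective else
      if (lo$status == "unbounded") -Inf else NA_real_
    maxs[k] <- if (hi$status == "optimal") hi$objective else
      if (hi$status == "unbounded") Inf else NA_real_
  }
  data.frame(reaction_id = reactions, min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum steady-state flux with the
#' model objective constrained to at least `fraction_of_optimum` times its
#' optimum (fraction 0 imposes no objective constraint).
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum number in `[0, 1]`.
#' @param reactions subset of reaction ids (default: all).
#' @param objective objective override passed to [fba()].
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, fraction_of_optimum = 0, reactions = NULL,
                objective = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  fva_engine(model, fraction_of_optimum, reactions, objective)
}

#' Find blocked reactions
#'
#' Reactions whose unconstrained (fraction-0) FVA range lies within
#' `tolerance` of zero: they cannot carry steady-state flux under any
#' admissible exchange pattern, whatever the objective.
#'
#' @param model a `metabolic_model`.
#' @param tolerance flux tolerance in mmol/gDW/hr.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked <- function(model, tolerance = 1e-6) {
  rng <- fva(model, fraction_of_optimum = 0)
  rng$reaction_id[abs(rng$min) <= tolerance & abs(rng$max) <= tolerance]
}
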