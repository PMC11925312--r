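# Independent oracles, kept deliberately separate from the package's solver
# paths: a brute-force vertex enumerator for small LPs, a pure-R simplex via
# boot::simplex, and an active-set-enumeration KKT solver for small QPs.

# maximize c'x s.t. A x = b, lb <= x <= ub by enumerating basic solutions:
# fix n - rank(A) variables at a bound, solve for the rest, keep feasible.
lp_vertex_oracle <- function(obj, A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  qrA <- qr(A)
  m <- qrA$rank
  best <- -Inf
  nf <- n - m
  if (nf < 0) stop("over-determined oracle problem")
  free_sets <- if (nf == 0) list(integer(0)) else
    utils::combn(n, nf, simplify = FALSE)
  for (fx in free_sets) {
    patterns <- if (nf == 0) list(numeric(0)) else {
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), nf))
      lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
    }
    for (pat in patterns) {
      xfix <- ifelse(pat, ub[fx], lb[fx])
      if (any(!is.finite(xfix))) next
      rest <- setdiff(seq_len(n), fx)
      Ar <- A[, rest, drop = FALSE]
      rhs <- b - if (length(fx)) A[, fx, drop = FALSE] %*% xfix else 0
      sol <- tryCatch(qr.solve(Ar, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Ar %*% sol - rhs)) > tol) next
      x <- numeric(n)
      x[fx] <- xfix
      x[rest] <- sol
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (val > best) best <- val
    }
  }
  best
}

# maximize c'x s.t. A x = b, lb <= x <= ub through boot::simplex
# (shift x = lb + y so y >= 0; upper bounds become A1 rows; rows are
# equilibrated so the wide coefficient ranges of proteome-constrained
# models do not destabilize the pure-R tableau)
boot_lp_oracle <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(all(is.finite(lb)))
  scale <- apply(abs(A), 1, max)
  scale[scale < .Machine$double.eps] <- 1
  A <- A / scale
  b <- b / scale
  span <- ub - lb
  fin <- which(is.finite(span))
  b3 <- as.vector(b - A %*% lb)
  sgn <- ifelse(b3 < 0, -1, 1)
  res <- boot::simplex(
    a = if (maximize) obj else -obj,
    A1 = diag(n)[fin, , drop = FALSE], b1 = span[fin],
    A3 = A * sgn, b3 = b3 * sgn, maxi = TRUE, n.iter = 1000)
  if (res$solved != 1) return(list(status = res$solved, objective = NA_real_))
  val <- unname(res$value + sum((if (maximize) obj else -obj) * lb))
  list(status = 1, objective = if (maximize) val else -val,
       x = as.numeric(res$soln) + lb)
}

# maximize c'x s.t. A x = b, lb <= x <= ub through scipy's HiGHS solver in
# a python subprocess: an entirely independent implementation, used for the
# larger proteome-constrained LPs where the pure-R tableau oracle is
# numerically fragile.
highs_lp_oracle <- function(obj, A, b, lb, ub, maximize = TRUE) {
  prob <- list(c = as.numeric(if (maximize) -obj else obj),
               A = as.matrix(A), b = as.numeric(b),
               lb = as.numeric(lb),
               ub = ifelse(is.infinite(ub), 1e30, as.numeric(ub)))
  inp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, out)), add = TRUE)
  jsonlite::write_json(prob, inp, digits = NA, matrix = "rowmajor")
  script <- sprintf("
import json, numpy as np
from scipy.optimize import linprog
with open('%s') as fh:
    p = json.load(fh)
A = np.array(p['A'], dtype=float)
res = linprog(np.array(p['c'], dtype=float), A_eq=A,
              b_eq=np.array(p['b'], dtype=float),
              bounds=list(zip(p['lb'], p['ub'])), method='highs')
json.dump({'status': int(res.status),
           'fun': None if res.fun is None else float(res.fun)},
          open('%s', 'w'))
", inp, out)
  status <- system2("python", "-", input = script, stdout = FALSE,
                    stderr = FALSE)
  if (status != 0 || !file.exists(out)) {
    stop("HiGHS oracle subprocess failed")
  }
  res <- jsonlite::read_json(out)
  if (res$status != 0) return(list(status = res$status,
                                   objective = NA_real_))
  list(status = 0,
       objective = if (maximize) -res$fun else res$fun)
}

# minimize (z - a)' W (z - a) s.t. Aeq z = beq, G z <= h, by enumerating
# active sets of the inequalities and solving each KKT system.
qp_kkt_oracle <- function(a, W, Aeq = NULL, beq = NULL, G = NULL, h = NULL,
                          tol = 1e-8) {
  n <- length(a)
  W <- as.matrix(W)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric(0) }
  if (is.null(G)) { G <- matrix(0, 0, n); h <- numeric(0) }
  mI <- nrow(G)
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^mI - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(mI) - 1)) > 0)
    C <- rbind(Aeq, G[act, , drop = FALSE])
    d <- c(beq, h[act])
    K <- rbind(cbind(2 * W, t(C)),
               cbind(C, matrix(0, nrow(C), nrow(C))))
    rhs <- c(2 * W %*% a, d)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    z <- sol[seq_len(n)]
    lam <- sol[-seq_len(n)]
    mu <- if (length(act)) lam[nrow(Aeq) + seq_along(act)] else numeric(0)
    if (length(beq) && max(abs(Aeq %*% z - beq)) > tol) next
    if (mI && any(G %*% z > h + tol)) next
    if (any(mu < -tol)) next           # KKT dual feasibility
    val <- as.numeric(t(z - a) %*% W %*% (z - a))
    if (val < best_val - 1e-12) { best_val <- val; best <- unname(z) }
  }
  list(z = best, value = best_val)
}

# brute-force Spearman: explicit average ranks then the Pearson formula
spearman_oracle <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}
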