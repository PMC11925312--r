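# Proteome-constrained flux variability analysis, enzyme abundance ranges,
# Spearman-based classification of reactions by abundance dependence,
# metadata correlation, and the representative model.

#' Proteome-constrained flux variability analysis
#'
#' Per-reaction flux ranges at a set of objective fractions: for each
#' fraction f the objective reaction is constrained to at least f times its
#' maximum, and each reaction's flux is minimized and maximized. The
#' effective envelope is the union over fractions (which, by nesting of the
#' constrained polytopes, equals the fraction-0 range; per-fraction ranges
#' are still reported so tighter operating regimes can be examined).
#'
#' @param context_model a `context_model` (or any `metabolic_model`).
#' @param objective_reaction reaction id used for the fraction constraint.
#' @param fractions objective fractions in `[0, 1]`.
#' @param reactions subset of reaction ids (default: the base model's
#'   non-pseudo reactions when available, otherwise all).
#' @return object of class `pc_fva`: list with `envelope` (data.frame
#'   `reaction_id`, `effective_min`, `effective_max`), `by_fraction`
#'   (data.frame `reaction_id`, `fraction`, `min`, `max`), and
#'   `objective_value`.
#' @export
pc_fva <- function(context_model, objective_reaction,
                   fractions = c(0, 0.5, 0.9, 0.99), reactions = NULL) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  if (is.null(reactions)) {
    reactions <- if (!is.null(context_model$base_reactions)) {
      intersect(context_model$base_reactions,
                context_model$reactions$id[!context_model$reactions$is_pseudo])
    } else context_model$reactions$id
  }
  opt <- fba(context_model, objective = objective_reaction)
  if (opt$status != "optimal") {
    stop("objective problem is ", opt$status, "; cannot run variability")
  }
  per <- list()
  for (f in sort(fractions)) {
    rng <- tryCatch(
      fva_engine(context_model, f, reactions,
                 objective = objective_reaction),
      error = function(e) {
        warning("fraction ", f, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(rng)) next
    rng$fraction <- f
    per[[as.character(f)]] <- rng
  }
  by_fraction <- do.call(rbind, per)
  rownames(by_fraction) <- NULL
  env <- stats::aggregate(cbind(min, max) ~ reaction_id, by_fraction,
                          function(x) x)
  envelope <- data.frame(
    reaction_id = env$reaction_id,
    effective_min = apply(as.matrix(env$min), 1, min),
    effective_max = apply(as.matrix(env$max), 1, max),
    stringsAsFactors = FALSE)
  envelope <- envelope[match(reactions, envelope$reaction_id), ]
  rownames(envelope) <- NULL
  structure(list(envelope = envelope, by_fraction = by_fraction,
                 objective_value = opt$objective_value,
                 objective_reaction = objective_reaction),
            class = "pc_fva")
}

#' @export
print.pc_fva <- function(x, ...) {
  cat("<pc_fva> objective", x$objective_reaction, "=",
      format(x$objective_value, digits = 8), "over",
      nrow(x$envelope), "reactions at fractions",
      paste(unique(x$by_fraction$fraction), collapse = "/"), "\n")
  invisible(x)
}

#' Enzyme abundance range for a reaction
#'
#' Minimum and maximum of the total enzyme-entity abundance
#' (`e_fwd + e_rev`, nmol/gDW) of a reaction, subject to the model's
#' constraints (optionally with the objective held at a fraction of its
#' optimum).
#'
#' @param context_model a `context_model` or `pc_model`.
#' @param reaction reaction id; must carry a gene association.
#' @param objective_reaction,fraction optional objective-fraction
#'   constraint.
#' @return named numeric `c(min, max)`.
#' @export
enzyme_abundance_range <- function(context_model, reaction,
                                   objective_reaction = NULL, fraction = 0) {
  vars <- paste0(c("enz_fwd_", "enz_rev_"), reaction)
  vars <- vars[vars %in% context_model$reactions$id]
  if (!length(vars)) {
    stop("no enzyme entity for reaction ", sQuote(reaction),
         " (spontaneous or unknown)")
  }
  lp <- model_lp(context_model)
  A <- lp$A; b <- lp$b; lb <- lp$lb; ub <- lp$ub
  if (fraction > 0) {
    if (is.null(objective_reaction)) {
      stop("objective_reaction required when fraction > 0")
    }
    cvec <- objective_vector(context_model, objective_reaction)
    opt <- solve_lp(cvec, A, b, lb, ub, maximize = TRUE)
    if (opt$status != "optimal") stop("objective problem is ", opt$status)
    A <- rbind(cbind(A, 0), c(cvec, -1))
    b <- c(b, fraction * opt$objective)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  cvec <- rep(0, ncol(A))
  cvec[match(vars, lp$reactions)] <- 1
  lo <- solve_lp(cvec, A, b, lb, ub, maximize = FALSE)
  hi <- solve_lp(cvec, A, b, lb, ub, maximize = TRUE)
  c(min = if (lo$status == "optimal") lo$objective else NA_real_,
    max = if (hi$status == "optimal") hi$objective else
      if (hi$status == "unbounded") Inf else NA_real_)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values, after dropping pairs with
#' a missing member. Returns `NA` (undefined) when fewer than two complete
#' pairs remain or either vector is constant.
#'
#' @param x,y equal-length numeric vectors.
#' @return rho in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Classify reactions by enzyme-abundance dependence
#'
#' For each reaction, the Spearman correlation between its maximum
#' attainable flux and its total enzyme abundance across samples determines
#' the class: abundance-dependent (`rho >= 0.8`), abundance-correlated
#' (`0.5 <= rho < 0.8`), abundance-independent otherwise. Spontaneous
#' reactions (no gene association) and blocked reactions are always
#' abundance-independent; an undefined correlation (constant flux or
#' abundance) is abundance-independent and flagged.
#'
#' @param flux_maxima samples x reactions matrix of maximum fluxes.
#' @param abundances samples x reactions matrix of enzyme abundances
#'   (aligned columns and rows).
#' @param blocked character vector of blocked reaction ids.
#' @param gprs named character vector of GPR strings per reaction (or a
#'   `metabolic_model`).
#' @param categories optional named character vector of metabolic
#'   categories per reaction.
#' @param dependent_threshold,correlated_threshold class boundaries on rho.
#' @return data.frame of class `reaction_classification`: `reaction_id`,
#'   `rho`, `class`, `category`, `flag`.
#' @export
classify_reactions <- function(flux_maxima, abundances, blocked = character(0),
                               gprs = NULL, categories = NULL,
                               dependent_threshold = 0.8,
                               correlated_threshold = 0.5) {
  stopifnot(identical(dim(flux_maxima), dim(abundances)))
  rids <- colnames(flux_maxima)
  if (!identical(rids, colnames(abundances))) {
    stop("flux and abundance matrices have different reaction columns")
  }
  if (inherits(gprs, "metabolic_model")) {
    gprs <- setNames(gprs$reactions$gpr, gprs$reactions$id)
  }
  rho <- vapply(rids, function(r) {
    spearman_rho(abundances[, r], flux_maxima[, r])
  }, numeric(1))
  spontaneous <- if (is.null(gprs)) rep(FALSE, length(rids)) else
    !nzchar(gprs[rids]) | is.na(gprs[rids])
  forced <- spontaneous | rids %in% blocked
  cls <- ifelse(forced, "abundance-independent",
         ifelse(!is.na(rho) & rho >= dependent_threshold,
                "abundance-dependent",
         ifelse(!is.na(rho) & rho >= correlated_threshold,
                "abundance-correlated", "abundance-independent")))
  flag <- ifelse(rids %in% blocked, "blocked",
          ifelse(spontaneous, "spontaneous",
          ifelse(is.na(rho), "undefined-rho", "")))
  out <- data.frame(reaction_id = rids, rho = unname(rho), class = cls,
                    category = if (is.null(categories)) NA_character_ else
                      unname(categories[rids]),
                    flag = flag, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("reaction_classification", "data.frame")
  out
}

#' Group proteins by their associated reaction sets
#'
#' Within a classification, proteins acting on identical sets of reactions
#' of a given class are reported as one group.
#'
#' @param classification a `reaction_classification`.
#' @param model the `metabolic_model` (source of GPRs).
#' @param class which class to summarize.
#' @return data.frame `genes` (`;`-joined group), `n_reactions`.
#' @export
protein_reaction_groups <- function(classification, model,
                                    class = "abundance-dependent") {
  sel <- classification$reaction_id[classification$class == class]
  gpr <- setNames(model$reactions$gpr, model$reactions$id)
  gene_rxns <- list()
  for (r in sel) {
    for (g in gpr_genes(gpr[[r]])) {
      gene_rxns[[g]] <- c(gene_rxns[[g]], r)
    }
  }
  if (!length(gene_rxns)) {
    return(data.frame(genes = character(0), n_reactions = integer(0)))
  }
  key <- vapply(gene_rxns, function(r) paste(sort(r), collapse = ";"),
                character(1))
  groups <- split(names(gene_rxns), key)
  out <- data.frame(
    genes = vapply(groups, function(g) paste(sort(g), collapse = ";"), ""),
    n_reactions = vapply(names(groups), function(k) {
      length(strsplit(k, ";", fixed = TRUE)[[1]])
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_reactions, out$genes), , drop = FALSE]
}

#' Correlate sample metadata with per-reaction values
#'
#' Spearman correlation between every numeric metadata column and every
#' reaction column (e.g. maximum fluxes), with rows and columns ordered by
#' agglomerative hierarchical clustering (Euclidean distance on the
#' correlation vectors).
#'
#' @param metadata data.frame of numeric metadata, rownames = sample ids.
#' @param values samples x reactions numeric matrix, rownames = sample ids.
#' @param linkage hierarchical clustering linkage method.
#' @return list: `correlation` (metadata x reactions), `row_order`,
#'   `col_order`, `dropped_columns`.
#' @export
correlate_metadata <- function(metadata, values, linkage = "average") {
  shared <- intersect(rownames(metadata), rownames(values))
  if (length(shared) < 2) stop("fewer than 2 shared samples")
  md <- as.data.frame(metadata)[shared, , drop = FALSE]
  vals <- values[shared, , drop = FALSE]
  keep <- vapply(md, function(col) is.numeric(col) && !all(is.na(col)),
                 logical(1))
  dropped <- names(md)[!keep]
  if (length(dropped)) {
    warning("dropping non-numeric or all-missing metadata column(s): ",
            paste(dropped, collapse = ", "))
  }
  md <- md[, keep, drop = FALSE]
  cors <- matrix(NA_real_, ncol(md), ncol(vals),
                 dimnames = list(names(md), colnames(vals)))
  for (i in seq_len(ncol(md))) {
    for (j in seq_len(ncol(vals))) {
      cors[i, j] <- spearman_rho(md[[i]], vals[, j])
    }
  }
  cl <- function(m) {
    if (nrow(m) < 2) return(seq_len(nrow(m)))
    m[is.na(m)] <- 0
    stats::hclust(stats::dist(m), method = linkage)$order
  }
  list(correlation = cors, row_order = cl(cors), col_order = cl(t(cors)),
       dropped_columns = dropped)
}

#' Build the representative model
#'
#' Per reaction, bounds are set to the envelope over all context-specific
#' models: lower bound = min over contexts of the effective minima, upper
#' bound = max over contexts of the effective maxima. Per protein, dilution
#' bounds are set likewise from enzyme/protein abundance ranges when given.
#'
#' @param pc_model the base `pc_model` to re-bound.
#' @param envelopes list of envelope data.frames
#'   (`reaction_id`, `effective_min`, `effective_max`), one per context.
#' @param abundance_ranges optional list of data.frames
#'   (`gene`, `min`, `max`), one per context, applied to protein dilution
#'   bounds.
#' @return a `pc_model` with representative bounds.
#' @export
build_representative_model <- function(pc_model, envelopes,
                                       abundance_ranges = NULL) {
  if (!length(envelopes)) stop("no context envelopes supplied")
  all_env <- do.call(rbind, envelopes)
  lo <- tapply(all_env$effective_min, all_env$reaction_id, min)
  hi <- tapply(all_env$effective_max, all_env$reaction_id, max)
  rep_model <- pc_model
  idx <- match(names(lo), rep_model$reactions$id)
  ok <- !is.na(idx)
  rep_model$reactions$lower_bound[idx[ok]] <- as.numeric(lo)[ok]
  rep_model$reactions$upper_bound[idx[ok]] <- as.numeric(hi)[ok]
  if (!is.null(abundance_ranges) && length(abundance_ranges)) {
    ar <- do.call(rbind, abundance_ranges)
    lo <- tapply(ar$min, ar$gene, min)
    hi <- tapply(ar$max, ar$gene, max)
    idx <- match(paste0("prot_", names(lo)), rep_model$reactions$id)
    ok <- !is.na(idx)
    rep_model$reactions$lower_bound[idx[ok]] <- as.numeric(lo)[ok]
    rep_model$reactions$upper_bound[idx[ok]] <- as.numeric(hi)[ok]
  }
  rep_model$id <- paste0(pc_model$id, "_representative")
  rep_model
}

#' Run the context-specific classification pipeline
#'
#' End-to-end driver: normalizes each prepared sample to the proteome
#' budgets, fits the best-fit proteome by QP, builds the slack-relaxed
#' context model, computes each reaction's maximum flux (the effective
#' maximum over objective fractions) and enzyme abundance, and classifies
#' reactions by abundance dependence across samples.
#'
#' @param pc_model a `pc_model`.
#' @param samples list of `proteome_sample` objects from
#'   [prepare_samples()].
#' @param objective_reaction objective for the variability analysis.
#' @param s slack; default from the budget config.
#' @param reactions reactions to classify (default: enzymatic + spontaneous
#'   non-pseudo base reactions).
#' @param envelopes also compute flux minima and return per-sample
#'   envelopes (doubles the LP count; the classification itself only needs
#'   maxima).
#' @param verbose print one progress line per sample.
#' @return list: `classification`, `flux_maxima`, `abundances` (samples x
#'   reactions), `fits`, `blocked`, `envelopes` (per-sample fraction-0
#'   ranges as envelope data.frames; `NULL` unless requested).
#' @export
classify_pipeline <- function(pc_model, samples, objective_reaction,
                              s = NULL, reactions = NULL, envelopes = FALSE,
                              verbose = FALSE) {
  stopifnot(inherits(pc_model, "pc_model"))
  base_rx <- pc_model$reactions[pc_model$reactions$id %in%
                                  pc_model$base_reactions, , drop = FALSE]
  if (is.null(reactions)) {
    reactions <- base_rx$id[!base_rx$is_pseudo]
  }
  blocked <- find_blocked(pc_model)
  enz <- intersect(reactions, pc_model$enzymatic_reactions)
  nsamp <- length(samples)
  ids <- vapply(samples, function(sm) {
    paste0(sm$donor_id, "_", sm$storage_day)
  }, character(1))
  flux_max <- matrix(NA_real_, nsamp, length(reactions),
                     dimnames = list(ids, reactions))
  abund <- matrix(NA_real_, nsamp, length(reactions),
                  dimnames = list(ids, reactions))
  fits <- vector("list", nsamp)
  env_list <- if (envelopes) vector("list", nsamp) else NULL
  for (k in seq_len(nsamp)) {
    p_data <- normalize_to_budget(samples[[k]], pc_model$proteins,
                                  pc_model$budget)
    fit <- fit_proteome(pc_model, p_data)
    fits[[k]] <- fit
    if (fit$status != "optimal") next
    ctx <- build_context_model(pc_model, fit, s = s)
    lp <- model_lp(ctx)
    n <- ncol(lp$A)
    opt_one <- function(cols, maximize) {
      cvec <- rep(0, n)
      cvec[cols] <- 1
      sol <- solve_lp(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = maximize)
      if (sol$status == "optimal") sol$objective else NA_real_
    }
    ridx <- match(reactions, lp$reactions)
    mins <- rep(NA_real_, length(reactions))
    for (j in seq_along(reactions)) {
      flux_max[k, j] <- opt_one(ridx[j], TRUE)
      if (envelopes) mins[j] <- opt_one(ridx[j], FALSE)
    }
    for (r in enz) {
      ecols <- match(paste0(c("enz_fwd_", "enz_rev_"), r), lp$reactions)
      abund[k, r] <- opt_one(ecols[!is.na(ecols)], TRUE)
    }
    if (envelopes) {
      env_list[[k]] <- data.frame(reaction_id = reactions,
                                  effective_min = mins,
                                  effective_max = unname(flux_max[k, ]),
                                  stringsAsFactors = FALSE)
    }
    if (verbose) {
      message("sample ", ids[k], ": fit SSE ",
              format(fit$objective_value, digits = 4))
    }
  }
  categories <- setNames(base_rx$category, base_rx$id)
  classification <- classify_reactions(
    flux_max, abund, blocked = blocked, gprs = pc_model,
    categories = categories)
  list(classification = classification, flux_maxima = flux_max,
       abundances = abund, fits = fits, blocked = blocked,
       envelopes = env_list)
}
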