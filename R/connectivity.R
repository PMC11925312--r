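# Network connectivity statistics: metabolite and gene degrees, currency
# metabolite / substrate-product motif pruning, and rank-distribution
# comparison against a reference line.

#' Metabolite connectivity
#'
#' Degree of each metabolite: the number of distinct non-pseudo reactions in
#' which it participates with nonzero coefficient. Pseudo-reactions (system
#' boundaries, pooling) are removed first. With `merge_compartments = TRUE`
#' the degree of a base id counts reactions in which any compartment
#' instance participates.
#'
#' @param model a `metabolic_model`.
#' @param merge_compartments collapse compartment instances of a metabolite.
#' @return data.frame `entity_id`, `degree`, `rank`, sorted by decreasing
#'   degree, ties broken lexicographically by id.
#' @export
metabolite_connectivity <- function(model, merge_compartments = FALSE) {
  rxns <- model$reactions$id[!model$reactions$is_pseudo]
  comps <- unique(model$metabolites$compartment)
  ids <- if (merge_compartments) {
    unique(base_met_id(model$metabolites$id, comps))
  } else model$metabolites$id
  degree <- setNames(integer(length(ids)), ids)
  for (r in rxns) {
    st <- model$stoichiometry[[r]]
    st <- st[st != 0]
    if (!length(st)) next
    touched <- if (merge_compartments) {
      unique(base_met_id(names(st), comps))
    } else names(st)
    degree[touched] <- degree[touched] + 1L
  }
  rank_records(degree)
}

#' Gene connectivity
#'
#' Degree of each gene: the number of non-pseudo reactions whose GPR rule
#' references it. Genes present in the model but absent from every GPR have
#' degree zero.
#'
#' @param model a `metabolic_model`.
#' @return data.frame `entity_id`, `degree`, `rank`, sorted by decreasing
#'   degree.
#' @export
gene_connectivity <- function(model) {
  degree <- setNames(integer(nrow(model$genes)), model$genes$symbol)
  active <- !model$reactions$is_pseudo
  for (k in which(active)) {
    g <- gpr_genes(model$reactions$gpr[k])
    g <- intersect(g, names(degree))
    degree[g] <- degree[g] + 1L
  }
  rank_records(degree)
}

rank_records <- function(degree) {
  ord <- order(-degree, names(degree))
  data.frame(entity_id = names(degree)[ord],
             degree = as.integer(unname(degree)[ord]),
             rank = seq_along(degree), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pruning specification for connectivity analysis
#'
#' Defines currency species to delete, substrate-product motifs whose
#' members are removed from reactions containing the full pair on opposite
#' sides, and whether to drop transport reactions. Defaults cover water,
#' protons, common small/co-transport ions, and the ATP-hydrolysis and
#' redox-pair coupling motifs.
#'
#' @param remove_species base metabolite ids deleted from all reactions.
#' @param remove_motifs list of length-2 character vectors
#'   `c(substrate, product)` of base ids.
#' @param remove_transport drop reactions whose merged-compartment
#'   stoichiometry cancels to all zeros (plus reactions annotated as
#'   Transport).
#' @return object of class `prune_spec`.
#' @export
prune_spec <- function(remove_species = character(0),
                       remove_motifs = list(),
                       remove_transport = FALSE) {
  stopifnot(all(vapply(remove_motifs, length, 0L) == 2L))
  structure(list(remove_species = remove_species,
                 remove_motifs = remove_motifs,
                 remove_transport = remove_transport),
            class = "prune_spec")
}

#' Default pruning specification
#'
#' @param remove_transport see [prune_spec()].
#' @return a `prune_spec` with the standard currency species and motifs.
#' @export
default_prune_spec <- function(remove_transport = FALSE) {
  prune_spec(
    remove_species = c("h2o", "h", "na1", "k", "cl", "ca2", "mg2", "fe2",
                       "fe3", "pi"),
    remove_motifs = list(c("atp", "adp"), c("atp", "amp"),
                         c("nad", "nadh"), c("nadp", "nadph"),
                         c("gsh", "gssg")),
    remove_transport = remove_transport)
}

#' Prune a metabolic network for connectivity analysis
#'
#' Deletes listed currency species from every reaction; for each motif pair,
#' removes both members from any reaction containing the full pair on
#' opposite sides (partial matches leave the reaction untouched); optionally
#' drops transport reactions. Pruning is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param spec a [prune_spec()].
#' @return the pruned `metabolic_model`.
#' @export
prune_network <- function(model, spec = default_prune_spec()) {
  stopifnot(inherits(spec, "prune_spec"))
  comps <- unique(model$metabolites$compartment)
  st_list <- model$stoichiometry
  for (r in names(st_list)) {
    st <- st_list[[r]]
    if (!length(st)) next
    base <- base_met_id(names(st), comps)
    keep <- !(base %in% spec$remove_species)
    st <- st[keep]; base <- base[keep]
    for (motif in spec$remove_motifs) {
      a_sub <- base == motif[1] & st < 0; a_prod <- base == motif[1] & st > 0
      b_sub <- base == motif[2] & st < 0; b_prod <- base == motif[2] & st > 0
      if ((any(a_sub) && any(b_prod)) || (any(a_prod) && any(b_sub))) {
        drop <- base %in% motif
        st <- st[!drop]; base <- base[!drop]
      }
    }
    st_list[[r]] <- st
  }
  model$stoichiometry <- st_list
  if (spec$remove_transport) {
    is_transport <- vapply(model$reactions$id, function(r) {
      st <- st_list[[r]]
      if (!length(st)) return(FALSE)
      merged <- tapply(st, base_met_id(names(st), comps), sum)
      all(abs(merged) < 1e-12)
    }, logical(1))
    is_transport <- is_transport |
      model$reactions$category == "Transport" |
      grepl("transport", model$reactions$subsystem, ignore.case = TRUE)
    keep <- !is_transport | model$reactions$is_pseudo
    model$reactions <- model$reactions[keep, , drop = FALSE]
    model$stoichiometry <- model$stoichiometry[model$reactions$id]
  }
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  model
}

#' Compare ranked connectivity distributions to their reference lines
#'
#' For each distribution, draws the straight line in (rank, log10 degree)
#' space from (1, log10 max) to (N, log10 min) and counts points strictly
#' above and strictly below it. Connectivity distributions are heavy-tailed,
#' so curvature relative to this line distinguishes hub-dominated from
#' evenly connected networks.
#'
#' @param dist_a,dist_b numeric degree vectors (or data.frames from
#'   [metabolite_connectivity()]).
#' @param tol vertical tolerance for "on the line".
#' @return list with one element per distribution: `n_above`, `n_below`,
#'   `n_on`, `n`.
#' @export
reference_line_comparison <- function(dist_a, dist_b = NULL, tol = 1e-9) {
  one <- function(d) {
    if (is.data.frame(d)) d <- d$degree
    d <- sort(as.numeric(d[d > 0]), decreasing = TRUE)
    n <- length(d)
    if (n == 0) stop("empty connectivity distribution")
    y <- log10(d)
    if (n == 1 || abs(y[1] - y[n]) < tol) {
      return(list(n_above = 0L, n_below = 0L, n_on = n, n = n))
    }
    line <- y[1] + (seq_len(n) - 1) / (n - 1) * (y[n] - y[1])
    resid <- y - line
    list(n_above = sum(resid > tol), n_below = sum(resid < -tol),
         n_on = sum(abs(resid) <= tol), n = n)
  }
  out <- list(a = one(dist_a))
  if (!is.null(dist_b)) out$b <- one(dist_b)
  out
}
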