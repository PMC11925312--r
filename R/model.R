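#' @useDynLib pcgem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

# Default sentinel for "unbounded" fluxes (mmol/gDW/hr), the usual COBRA
# convention.  Bounds at or beyond the sentinel are treated as infinite when
# constructing LPs.
PCGEM_BIG_BOUND <- 1000

#' Metabolic categories used to group reactions
#'
#' The eight broad categories used to group metabolic subsystems: five
#' KEGG-style metabolism groups, a reactive-species group, transport, and a
#' catch-all.
#' @export
metabolic_categories <- function() {
  c("Amino acid metabolism", "Carbohydrate metabolism", "Lipid metabolism",
    "Metabolism of cofactors and vitamins", "Nucleotide metabolism",
    "Reactive species", "Transport", "Other")
}

#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` is the basic container for constraint-based analysis:
#' metabolites (with elemental formula and charge), reactions (with flux
#' bounds, gene-protein-reaction rules, subsystem and category annotations,
#' and a pseudo-reaction flag for exchanges/demands/sinks/pooling), genes,
#' and linear objective coefficients.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`. Metabolite ids follow the `<base_id>_<compartment>`
#'   convention.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (boolean gene expression as a string, `""` for
#'   spontaneous), `subsystem`, `category`, `is_pseudo`,
#'   `objective_coefficient`.
#' @param stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = substrate).
#' @param genes data.frame with columns `symbol`, `accession`.
#' @param name human-readable model name.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = NULL, name = id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  need_met <- c("id", "name", "compartment", "formula", "charge")
  for (col in setdiff(need_met, names(metabolites))) {
    metabolites[[col]] <- if (col == "charge") 0L else ""
  }
  defaults <- list(name = "", lower_bound = -PCGEM_BIG_BOUND,
                   upper_bound = PCGEM_BIG_BOUND, gpr = "", subsystem = "",
                   category = "Other", is_pseudo = FALSE,
                   objective_coefficient = 0)
  for (col in names(defaults)) {
    if (is.null(reactions[[col]])) reactions[[col]] <- defaults[[col]]
  }
  if (is.null(genes)) {
    syms <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
    genes <- data.frame(symbol = syms, accession = rep("", length(syms)),
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$accession)) genes$accession <- ""
  model <- structure(list(id = id, name = name, metabolites = metabolites,
                          reactions = reactions,
                          stoichiometry = stoichiometry[reactions$id],
                          genes = genes),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, stoichiometry referencing existing
#' metabolites, and that every gene in a GPR exists in the gene table.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; stops with a descriptive error on violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  if (anyDuplicated(model$genes$symbol)) {
    stop("duplicate gene symbols: ",
         paste(unique(model$genes$symbol[duplicated(model$genes$symbol)]),
               collapse = ", "))
  }
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound for: ",
                        paste(bad, collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns$id)) {
    stop("stoichiometry list does not match reaction ids")
  }
  unknown <- setdiff(unique(unlist(lapply(model$stoichiometry, names))),
                     mets$id)
  if (length(unknown)) stop("stoichiometry references unknown metabolites: ",
                            paste(unknown, collapse = ", "))
  gpr_syms <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  missing_genes <- setdiff(gpr_syms, model$genes$symbol)
  if (length(missing_genes)) stop("GPR references unknown genes: ",
                                  paste(missing_genes, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_pseudo), " pseudo)",
      "  genes: ", nrow(x$genes), "\n", sep = "")
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  if (length(obj)) cat("  objective: ", paste(obj, collapse = " + "), "\n",
                       sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  rx <- object$reactions
  out <- list(id = object$id,
              n_metabolites = nrow(object$metabolites),
              n_reactions = nrow(rx),
              n_pseudo = sum(rx$is_pseudo),
              n_genes = nrow(object$genes),
              n_enzymatic = sum(!rx$is_pseudo & nzchar(rx$gpr)),
              n_spontaneous = sum(!rx$is_pseudo & !nzchar(rx$gpr)))
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Model", x$id, ":", x$n_metabolites, "metabolites,", x$n_reactions,
      "reactions (", x$n_pseudo, "pseudo,", x$n_enzymatic, "enzymatic,",
      x$n_spontaneous, "spontaneous ),", x$n_genes, "genes\n")
  invisible(x)
}

#' Base (compartment-free) metabolite identifier
#'
#' Strips the trailing `_<compartment>` tag from a metabolite id.
#' @param ids character vector of metabolite ids.
#' @param compartments known compartment tags; when supplied only these are
#'   stripped, otherwise the final underscore-delimited token is.
#' @return character vector of base ids.
#' @export
base_met_id <- function(ids, compartments = NULL) {
  if (is.null(compartments)) return(sub("_[^_]+$", "", ids))
  pat <- paste0("_(", paste(compartments, collapse = "|"), ")$")
  sub(pat, "", ids)
}

#' Stoichiometric matrix of a model
#'
#' Builds the sparse stoichiometric matrix S with one row per metabolite and
#' one column per reaction, entry (i, j) the signed coefficient of metabolite
#' i in reaction j. With `merge_compartments = TRUE` rows sharing a base
#' metabolite id are collapsed by summation (so pure transport reactions
#' cancel to zero columns).
#'
#' @param model a `metabolic_model`.
#' @param merge_compartments collapse rows over compartments by summation.
#' @param drop_pseudo drop pseudo-reaction columns first.
#' @return a `Matrix::sparseMatrix` with dimnames (metabolite ids or base
#'   ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model, merge_compartments = FALSE,
                                  drop_pseudo = FALSE) {
  rxns <- model$reactions
  if (drop_pseudo) rxns <- rxns[!rxns$is_pseudo, , drop = FALSE]
  met_ids <- model$metabolites$id
  rids <- rxns$id
  if (merge_compartments) {
    rows <- unique(base_met_id(met_ids, unique(model$metabolites$compartment)))
    rowkey <- setNames(base_met_id(met_ids,
                                   unique(model$metabolites$compartment)),
                       met_ids)
  } else {
    rows <- met_ids
    rowkey <- setNames(met_ids, met_ids)
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    st <- model$stoichiometry[[rids[k]]]
    if (!length(st)) next
    i <- c(i, match(rowkey[names(st)], rows))
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(rows), length(rids)),
                       dimnames = list(rows, rids))
}

#' Set the model objective
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction receiving objective coefficient 1 (all others
#'   reset to 0), or a named numeric vector of coefficients.
#' @return the modified model.
#' @export
set_objective <- function(model, reaction_id) {
  model$reactions$objective_coefficient <- 0
  if (is.character(reaction_id)) {
    idx <- match(reaction_id, model$reactions$id)
    if (anyNA(idx)) stop("unknown reaction: ",
                         paste(reaction_id[is.na(idx)], collapse = ", "))
    model$reactions$objective_coefficient[idx] <- 1
  } else {
    idx <- match(names(reaction_id), model$reactions$id)
    if (anyNA(idx)) stop("unknown reaction in objective")
    model$reactions$objective_coefficient[idx] <- unname(reaction_id)
  }
  model
}

#' Set flux bounds for one reaction
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  idx <- match(reaction_id, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction: ", reaction_id[is.na(idx)][1])
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  model
}
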