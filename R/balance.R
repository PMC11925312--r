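# Elemental formula parsing and mass/charge balance reporting.  Generic
# R-groups (acyl-chain placeholders and the like) are carried as an inert
# pseudo-element so that lipid-pooling reactions can be excluded from the
# balance summary in the same way boundary pseudo-reactions are.

PCGEM_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Se", "Br", "Mo", "I", "W")

#' Parse an elemental formula
#'
#' Accepts standard Hill-notation formulas (e.g. `"C6H12O6"`). Tokens that
#' are not chemical elements (e.g. `"R"`, `"X"`) are kept as opaque
#' pseudo-elements, flagged via the `"has_rgroup"` attribute.
#'
#' @param formula formula string; `""`/`NA` returns an empty count vector
#'   with attribute `"missing" = TRUE`.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    return(structure(setNames(numeric(0), character(0)), missing = TRUE))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("unparseable formula: ", sQuote(formula))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  cnt[is.na(cnt) | sub("^[A-Z][a-z]?", "", toks) == ""] <- 1
  counts <- tapply(cnt, sym, sum)
  out <- setNames(as.numeric(counts), names(counts))
  attr(out, "has_rgroup") <- any(!names(out) %in% PCGEM_ELEMENTS)
  out
}

# Internal: per-reaction elemental and charge residuals.
reaction_residuals <- function(model, reaction_id) {
  st <- model$stoichiometry[[reaction_id]]
  mets <- model$metabolites
  idx <- match(names(st), mets$id)
  parsed <- lapply(mets$formula[idx], parse_formula)
  if (any(vapply(parsed, function(p) isTRUE(attr(p, "missing")), logical(1)))) {
    return(list(checkable = FALSE))
  }
  has_r <- any(vapply(parsed, function(p) isTRUE(attr(p, "has_rgroup")),
                      logical(1)))
  elements <- unique(unlist(lapply(parsed, names)))
  resid <- setNames(numeric(length(elements)), elements)
  for (k in seq_along(st)) {
    p <- parsed[[k]]
    resid[names(p)] <- resid[names(p)] + st[[k]] * as.numeric(p)
  }
  charge <- sum(st * mets$charge[idx])
  list(checkable = TRUE, has_rgroup = has_r, residuals = resid,
       charge_residual = charge)
}

#' Mass and charge balance report
#'
#' Checks every non-pseudo reaction for elemental and charge balance.
#' Pseudo-reactions (exchanges, demands, sinks, pooling) are excluded from
#' the summary, as are reactions involving generic R-group species (lipid
#' pooling); reactions with a missing metabolite formula are marked
#' uncheckable rather than failed.
#'
#' @param model a `metabolic_model`.
#' @param tolerance residual magnitude treated as zero.
#' @return list with `report` (data.frame: `reaction_id`, `checkable`,
#'   `excluded`, `mass_ok`, `charge_ok`, `residuals` as text,
#'   `charge_residual`) and `summary` (percent mass/charge balanced among
#'   checkable, non-excluded reactions).
#' @export
balance_report <- function(model, tolerance = 1e-6) {
  rxns <- model$reactions
  ids <- rxns$id
  n <- length(ids)
  checkable <- excluded <- mass_ok <- charge_ok <- rep(NA, n)
  resid_txt <- rep("", n)
  charge_res <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (rxns$is_pseudo[k]) { excluded[k] <- TRUE; next }
    rr <- reaction_residuals(model, ids[k])
    if (!rr$checkable) { checkable[k] <- FALSE; excluded[k] <- FALSE; next }
    checkable[k] <- TRUE
    excluded[k] <- rr$has_rgroup
    bad <- rr$residuals[abs(rr$residuals) > tolerance]
    mass_ok[k] <- length(bad) == 0L
    charge_ok[k] <- abs(rr$charge_residual) <= tolerance
    charge_res[k] <- rr$charge_residual
    if (length(bad)) {
      resid_txt[k] <- paste(sprintf("%s:%+g", names(bad), bad), collapse = ";")
    }
  }
  report <- data.frame(reaction_id = ids, checkable = checkable,
                       excluded = excluded, mass_ok = mass_ok,
                       charge_ok = charge_ok, residuals = resid_txt,
                       charge_residual = charge_res,
                       stringsAsFactors = FALSE)
  use <- which(checkable %in% TRUE & excluded %in% FALSE)
  summ <- list(
    n_checked = length(use),
    n_uncheckable = sum(checkable %in% FALSE),
    n_excluded = sum(excluded %in% TRUE),
    pct_mass_balanced = if (length(use)) 100 * mean(mass_ok[use]) else NA_real_,
    pct_charge_balanced = if (length(use)) 100 * mean(charge_ok[use]) else NA_real_)
  list(report = report, summary = summ)
}
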