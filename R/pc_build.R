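# Construction of proteome-constrained models: proteins, catalytic
# complexes, per-reaction "enzyme" entities with forward/reverse capacity,
# molar-mass-scaled effective rate constants, and the partitioned proteome
# budget (total / hemoglobin / low-abundance).
#
# All proteomic constraints are realized as pseudo-metabolite balances with
# pseudo-reactions, so a proteome-constrained model remains an ordinary
# stoichiometric model: the same LP machinery (and the SBML writer) applies
# unchanged. Identifier prefixes: prot_, cplx_, enz_fwd_/enz_rev_, budget_,
# and sink_* for the slack drains that turn inequalities into balances.

# average (natural-isotope) amino-acid residue masses, g/mol
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Protein molar mass from amino-acid sequence
#'
#' Sums average-isotope residue masses and adds one water, i.e. the mass of
#' the free (unmodified) polypeptide.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @return molar mass in mg/nmol (1 g/mol = 1e-6 mg/nmol).
#' @export
protein_molar_mass <- function(sequence) {
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("empty protein sequence")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(AA_RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown amino acid ", sQuote(aa[bad[1]]), " at position ", bad[1])
  }
  (sum(AA_RESIDUE_MASS[aa]) + WATER_MASS) * 1e-6
}

#' Hemoglobin gene symbols used by default
#'
#' The default membership of the hemoglobin index set: adult, fetal, and
#' embryonic globin chains. User-overridable wherever it is consumed.
#' @export
default_hb_genes <- function() {
  c("HBA1", "HBA2", "HBB", "HBD", "HBG1", "HBG2", "HBE1", "HBZ")
}

#' Construct a protein table
#'
#' @param gene gene symbols (unique).
#' @param accession UniProtKB-style accessions.
#' @param sequence amino-acid sequences (`NA` allowed when `molar_mass_da`
#'   given).
#' @param molar_mass_da molar masses in Da (g/mol); computed from `sequence`
#'   when `NA`.
#' @param is_hemoglobin logical membership in the hemoglobin set; default
#'   matches [default_hb_genes()].
#' @param p_ub per-protein abundance upper bound, nmol/gDW (default
#'   unbounded below the proteome budget).
#' @return data.frame of class `protein_table` with `molar_mass` in mg/nmol.
#' @export
protein_table <- function(gene, accession = gene, sequence = NA_character_,
                          molar_mass_da = NA_real_, is_hemoglobin = NULL,
                          p_ub = Inf) {
  n <- length(gene)
  if (anyDuplicated(gene)) stop("duplicate gene symbols in protein table")
  sequence <- rep_len(sequence, n)
  molar_mass_da <- rep_len(molar_mass_da, n)
  if (is.null(is_hemoglobin)) is_hemoglobin <- gene %in% default_hb_genes()
  mass <- molar_mass_da * 1e-6
  for (k in which(is.na(mass))) mass[k] <- protein_molar_mass(sequence[k])
  if (any(mass <= 0, na.rm = TRUE)) stop("nonpositive protein molar mass")
  out <- data.frame(gene = gene, accession = rep_len(accession, n),
                    sequence = sequence, molar_mass = mass,
                    is_hemoglobin = rep_len(is_hemoglobin, n),
                    p_ub = rep_len(p_ub, n), stringsAsFactors = FALSE)
  class(out) <- c("protein_table", "data.frame")
  out
}

#' Derive catalytic complexes from GPR rules
#'
#' Each OR-branch of a reaction's GPR yields one candidate complex;
#' AND-conjuncts become subunits with default copy number 1. Identical
#' subunit compositions arising from different reactions share one complex.
#' Curated complex records override the derived ones for the reactions they
#' list.
#'
#' @param model a `metabolic_model`.
#' @param proteins a [protein_table()]; every GPR gene must appear.
#' @param curated optional curated records: data.frame with columns
#'   `complex_id`, `subunits` (text `"gene:copies;gene:copies"`),
#'   `reaction_ids` (text, `;`-separated), `direction`
#'   (`"fwd"`, `"rev"`, or `"both"`).
#' @return list with `complexes` (data.frame `complex_id`, `molar_mass`, and
#'   list-column `subunits` of named copy numbers) and `catalysis`
#'   (data.frame `complex_id`, `reaction_id`, `direction`).
#' @export
derive_complexes <- function(model, proteins, curated = NULL) {
  stopifnot(inherits(proteins, "protein_table"))
  wmap <- setNames(proteins$molar_mass, proteins$gene)
  curated_rxns <- character(0)
  cur_list <- list()
  if (!is.null(curated) && nrow(curated)) {
    for (k in seq_len(nrow(curated))) {
      subs <- parse_subunits(curated$subunits[k])
      rids <- strsplit(curated$reaction_ids[k], ";", fixed = TRUE)[[1]]
      dirn <- if (is.null(curated$direction)) "both" else curated$direction[k]
      cur_list[[curated$complex_id[k]]] <- list(subunits = subs,
                                                reactions = rids,
                                                direction = dirn)
      curated_rxns <- c(curated_rxns, rids)
    }
  }
  comp <- list()       # composition key -> complex id
  subunits <- list()
  catal <- list()
  add_complex <- function(id, subs, rxn, dirn) {
    subunits[[id]] <<- subs
    catal[[length(catal) + 1L]] <<- data.frame(
      complex_id = id, reaction_id = rxn, direction = dirn,
      stringsAsFactors = FALSE)
  }
  for (cid in names(cur_list)) {
    cu <- cur_list[[cid]]
    for (r in cu$reactions) add_complex(cid, cu$subunits, r, cu$direction)
  }
  enz <- model$reactions[!model$reactions$is_pseudo &
                           nzchar(model$reactions$gpr), , drop = FALSE]
  for (k in seq_len(nrow(enz))) {
    rid <- enz$id[k]
    if (rid %in% curated_rxns) next
    alts <- gpr_alternatives(parse_gpr(enz$gpr[k]))
    for (genes in alts) {
      key <- paste(genes, collapse = "&")
      if (is.null(comp[[key]])) {
        comp[[key]] <- paste0("CPLX_", paste(genes, collapse = "_"))
      }
      add_complex(comp[[key]], setNames(rep(1L, length(genes)), genes),
                  rid, "both")
    }
  }
  if (!length(catal)) {
    return(list(
      complexes = data.frame(complex_id = character(0),
                             molar_mass = numeric(0),
                             subunits = I(list())),
      catalysis = data.frame(complex_id = character(0),
                             reaction_id = character(0),
                             direction = character(0),
                             stringsAsFactors = FALSE)))
  }
  catal <- unique(do.call(rbind, catal))
  ids <- unique(catal$complex_id)
  missing <- setdiff(unique(unlist(lapply(subunits, names))), names(wmap))
  if (length(missing)) {
    stop("complex subunit without protein record: ",
         paste(missing, collapse = ", "))
  }
  mass <- vapply(ids, function(id) {
    s <- subunits[[id]]
    sum(wmap[names(s)] * as.numeric(s))
  }, numeric(1))
  complexes <- data.frame(complex_id = ids, molar_mass = unname(mass),
                          stringsAsFactors = FALSE)
  complexes$subunits <- unname(subunits[ids])
  list(complexes = complexes, catalysis = catal)
}

parse_subunits <- function(txt) {
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
           vapply(parts, `[`, "", 1))
}

#' Proteome budget configuration
#'
#' Budgets in mg protein per g dry weight. The total proteome may not exceed
#' `p_total_ub`; it is partitioned into a hemoglobin budget (lower-bounded,
#' hemoglobin dominates the red-cell proteome) and a low-abundance budget.
#' During proteome fitting, tighter budgets matching the data normalization
#' (hemoglobin scaled to 95% of protein content) apply.
#'
#' @param p_total_ub total proteome cap, mg/gDW (100% of dry weight).
#' @param p_hb_lb,p_hb_ub hemoglobin budget bounds.
#' @param p_la_lb,p_la_ub low-abundance budget bounds.
#' @param p_hb_ub_fit,p_la_ub_fit budget upper bounds during QP fitting.
#' @param k_avg average effective rate constant, 1/hr (65 s^-1).
#' @param slack slack term for context-specific relaxation.
#' @param mass_exponent exponent of the molar-mass scaling of complex rate
#'   constants (solvent-accessible surface area scales as mass^(3/4)).
#' @param enzyme_flux_scale unit conversion in the capacity coupling
#'   `v <= k * e`: fluxes are mmol/gDW/hr while enzyme abundances are
#'   nmol/gDW, so the dimensionally consistent factor is 1e-6 mmol/nmol.
#' @return object of class `budget_config`.
#' @export
budget_config <- function(p_total_ub = 1000, p_hb_lb = 900, p_hb_ub = 1000,
                          p_la_lb = 0, p_la_ub = 100, p_hb_ub_fit = 950,
                          p_la_ub_fit = 50, k_avg = 2.34e5, slack = 0.03,
                          mass_exponent = 0.75, enzyme_flux_scale = 1e-6) {
  stopifnot(p_hb_lb >= 0, p_hb_lb <= p_hb_ub, p_la_lb >= 0,
            p_la_lb <= p_la_ub, p_total_ub > 0, k_avg > 0, slack >= 0,
            p_hb_ub_fit + p_la_ub_fit <= p_total_ub)
  structure(list(p_total_ub = p_total_ub, p_hb_lb = p_hb_lb,
                 p_hb_ub = p_hb_ub, p_la_lb = p_la_lb, p_la_ub = p_la_ub,
                 p_hb_ub_fit = p_hb_ub_fit, p_la_ub_fit = p_la_ub_fit,
                 k_avg = k_avg, slack = slack,
                 mass_exponent = mass_exponent,
                 enzyme_flux_scale = enzyme_flux_scale),
            class = "budget_config")
}

#' Estimate effective rate constants
#'
#' Enzyme-level forward and reverse rate constants are fixed at `k_avg`.
#' Complex-level constants scale with complex molar mass relative to the
#' mean complex mass, `k_l = k_avg * (M_l / mean(M))^mass_exponent`
#' (surface-area scaling); reverse constants are zeroed for complexes whose
#' reaction is irreversible (`v_lb >= 0`). The ratios `r = k_l / k_avg`
#' weight each complex's contribution to its reaction's enzyme entity.
#'
#' @param complexes,catalysis output of [derive_complexes()].
#' @param model the base `metabolic_model` (for reaction reversibility).
#' @param budget a [budget_config()] (supplies `k_avg`, `mass_exponent`).
#' @return data.frame `reaction_id`, `complex_id`, `k_fwd`, `k_rev`,
#'   `r_fwd`, `r_rev` (1/hr; ratios dimensionless).
#' @export
estimate_rate_constants <- function(complexes, catalysis, model,
                                    budget = budget_config()) {
  if (!is.data.frame(complexes) && !is.null(complexes$complexes)) {
    if (missing(catalysis) || is.null(catalysis)) {
      catalysis <- complexes$catalysis
    }
    complexes <- complexes$complexes
  }
  if (any(complexes$molar_mass <= 0)) stop("nonpositive complex molar mass")
  mbar <- mean(complexes$molar_mass)
  kl <- budget$k_avg * (complexes$molar_mass / mbar)^budget$mass_exponent
  kmap <- setNames(kl, complexes$complex_id)
  lb <- setNames(model$reactions$lower_bound, model$reactions$id)
  out <- catalysis
  out$k_fwd <- ifelse(out$direction == "rev", 0,
                      unname(kmap[out$complex_id]))
  irrev <- lb[out$reaction_id] >= 0
  out$k_rev <- ifelse(irrev | out$direction == "fwd", 0,
                      unname(kmap[out$complex_id]))
  out$r_fwd <- out$k_fwd / budget$k_avg
  out$r_rev <- out$k_rev / budget$k_avg
  rownames(out) <- NULL
  out
}

#' Build a proteome-constrained model
#'
#' Augments a metabolic model with protein dilution, complex formation, and
#' enzyme formation pseudo-reactions, a partitioned proteome budget, and
#' flux-capacity coupling: each enzymatic reaction's flux is limited to
#' `k_avg` times its forward (reverse) enzyme abundance, and enzyme
#' abundance equals the rate-ratio-weighted sum of member complex
#' abundances. Enzyme capacity caps flux but never forces it (slack sinks
#' absorb unused protein, complex, and capacity).
#'
#' @param model the base `metabolic_model`.
#' @param proteins a [protein_table()] covering every GPR gene.
#' @param complexes optional output of [derive_complexes()]; derived from
#'   the GPRs when `NULL`.
#' @param rates optional output of [estimate_rate_constants()].
#' @param budget a [budget_config()].
#' @return object of class `pc_model` (inherits `metabolic_model`) with
#'   components `proteins`, `complexes`, `catalysis`, `rates`, `budget`,
#'   `enzymatic_reactions`, and `base_reactions`.
#' @export
build_pc_model <- function(model, proteins, complexes = NULL, rates = NULL,
                           budget = budget_config()) {
  stopifnot(inherits(proteins, "protein_table"))
  gpr_syms <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  nomass <- setdiff(gpr_syms, proteins$gene)
  if (length(nomass)) {
    stop("GPR gene(s) without protein record: ",
         paste(nomass, collapse = ", "))
  }
  if (is.null(complexes)) complexes <- derive_complexes(model, proteins)
  cx <- complexes$complexes
  catal <- complexes$catalysis
  unknown <- setdiff(unlist(lapply(cx$subunits, names)), proteins$gene)
  if (length(unknown)) {
    stop("complex references absent protein: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(rates)) {
    rates <- estimate_rate_constants(cx, catal, model, budget)
  }
  enz_ids <- model$reactions$id[!model$reactions$is_pseudo &
                                  nzchar(model$reactions$gpr)]
  nocplx <- setdiff(enz_ids, catal$reaction_id)
  if (length(nocplx)) {
    stop("enzymatic reaction without complex: ",
         paste(nocplx, collapse = ", "))
  }

  mets <- model$metabolites
  rxns <- model$reactions
  stoich <- model$stoichiometry
  add_met <- function(id, name) {
    mets <<- rbind(mets, data.frame(id = id, name = name, compartment = "p",
                                    formula = "", charge = 0L,
                                    stringsAsFactors = FALSE))
  }
  add_rxn <- function(id, st, lb = 0, ub = Inf, name = id) {
    rxns <<- rbind(rxns, data.frame(
      id = id, name = name, lower_bound = lb, upper_bound = ub, gpr = "",
      subsystem = "Proteome constraints", category = "Other",
      is_pseudo = TRUE, objective_coefficient = 0, stringsAsFactors = FALSE))
    stoich[[id]] <<- st
  }

  add_met("budget_total_p", "total proteome budget pool")
  add_met("budget_hb_p", "hemoglobin proteome budget pool")
  add_met("budget_la_p", "low-abundance proteome budget pool")
  add_rxn("budget_total", c(budget_total_p = 1), 0, budget$p_total_ub)
  add_rxn("budget_hb", c(budget_total_p = -1, budget_hb_p = 1),
          budget$p_hb_lb, budget$p_hb_ub)
  add_rxn("budget_la", c(budget_total_p = -1, budget_la_p = 1),
          budget$p_la_lb, budget$p_la_ub)

  for (k in seq_len(nrow(proteins))) {
    g <- proteins$gene[k]
    pool <- if (proteins$is_hemoglobin[k]) "budget_hb_p" else "budget_la_p"
    psp <- paste0("prot_", g, "_p")
    add_met(psp, paste("protein", g))
    st <- setNames(c(-proteins$molar_mass[k], 1), c(pool, psp))
    add_rxn(paste0("prot_", g), st, 0, proteins$p_ub[k])
    add_rxn(paste0("sink_prot_", g), setNames(-1, psp))
  }

  kcap <- budget$k_avg * budget$enzyme_flux_scale
  rev_channel <- setNames(logical(length(enz_ids)), enz_ids)
  for (rid in enz_ids) {
    rr <- rates[rates$reaction_id == rid, , drop = FALSE]
    rev_channel[rid] <- rxns$lower_bound[match(rid, rxns$id)] < 0 &&
      any(rr$k_rev > 0)
    add_met(paste0("enzpool_", rid, "_p"), paste("enzyme pool", rid))
    add_met(paste0("capf_", rid, "_p"), paste("forward capacity", rid))
    add_rxn(paste0("enz_fwd_", rid),
            setNames(c(-1, kcap),
                     paste0(c("enzpool_", "capf_"), rid, "_p")))
    add_rxn(paste0("sink_capf_", rid),
            setNames(-1, paste0("capf_", rid, "_p")))
    reversible <- rxns$lower_bound[match(rid, rxns$id)] < 0
    if (reversible) {
      add_met(paste0("capr_", rid, "_p"), paste("reverse capacity", rid))
      add_rxn(paste0("sink_capr_", rid),
              setNames(-1, paste0("capr_", rid, "_p")))
      if (rev_channel[rid]) {
        add_rxn(paste0("enz_rev_", rid),
                setNames(c(-1, kcap),
                         paste0(c("enzpool_", "capr_"), rid, "_p")))
      }
    }
    st <- stoich[[rid]]
    st[paste0("capf_", rid, "_p")] <- -1
    if (reversible) st[paste0("capr_", rid, "_p")] <- 1
    stoich[[rid]] <- st
  }

  for (k in seq_len(nrow(cx))) {
    cid <- cx$complex_id[k]
    subs <- cx$subunits[[k]]
    st <- setNames(-as.numeric(subs), paste0("prot_", names(subs), "_p"))
    rr <- rates[rates$complex_id == cid, , drop = FALSE]
    for (j in seq_len(nrow(rr))) {
      rid <- rr$reaction_id[j]
      if (!rid %in% enz_ids) next
      r_contrib <- max(rr$r_fwd[j], rr$r_rev[j])
      if (r_contrib > 0) {
        pool <- paste0("enzpool_", rid, "_p")
        st[pool] <- if (is.na(st[pool])) r_contrib else st[pool] + r_contrib
      }
    }
    add_rxn(paste0("cplx_", cid), st)
  }

  pc <- metabolic_model(id = paste0(model$id, "_pc"), metabolites = mets,
                        reactions = rxns, stoichiometry = stoich,
                        genes = model$genes,
                        name = paste(model$name, "(proteome-constrained)"))
  pc$proteins <- proteins
  pc$complexes <- cx
  pc$catalysis <- catal
  pc$rates <- rates
  pc$budget <- budget
  pc$enzymatic_reactions <- enz_ids
  pc$rev_channel <- rev_channel
  pc$base_reactions <- model$reactions$id
  class(pc) <- c("pc_model", class(pc))
  pc
}

#' @export
print.pc_model <- function(x, ...) {
  NextMethod()
  cat("  proteins: ", nrow(x$proteins),
      " (", sum(x$proteins$is_hemoglobin), " hemoglobin)",
      "  complexes: ", nrow(x$complexes),
      "  enzyme entities: ", length(x$enzymatic_reactions),
      "  nonzero rate constants: ",
      sum(x$rates$k_fwd > 0) + sum(x$rates$k_rev > 0), "\n", sep = "")
  invisible(x)
}

#' Read a protein table from TSV
#'
#' Columns: `gene`, `accession`, and `sequence` or `molar_mass_da`;
#' optionally `is_hemoglobin`, `p_ub`.
#' @param path TSV file.
#' @return a [protein_table()].
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  protein_table(
    gene = df$gene,
    accession = if (is.null(df$accession)) df$gene else df$accession,
    sequence = if (is.null(df$sequence)) NA_character_ else df$sequence,
    molar_mass_da = if (is.null(df$molar_mass_da)) NA_real_ else
      df$molar_mass_da,
    is_hemoglobin = if (is.null(df$is_hemoglobin)) NULL else
      as.logical(df$is_hemoglobin),
    p_ub = if (is.null(df$p_ub)) Inf else df$p_ub)
}

#' Write a protein table to TSV
#' @param proteins a [protein_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path) {
  out <- as.data.frame(proteins)
  out$molar_mass_da <- out$molar_mass * 1e6
  out$molar_mass <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curated complex table from TSV
#'
#' Columns: `complex_id`, `subunits` (`"gene:copies;..."`), `reaction_ids`
#' (`;`-separated), `direction`.
#' @param path TSV file.
#' @return data.frame in the curated format accepted by
#'   [derive_complexes()].
#' @export
read_complex_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a curated complex table to TSV
#' @param complexes list as from [derive_complexes()] or a curated
#'   data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_complex_table <- function(complexes, path) {
  if (is.list(complexes) && !is.data.frame(complexes)) {
    cx <- complexes$complexes
    catal <- complexes$catalysis
    df <- data.frame(
      complex_id = cx$complex_id,
      subunits = vapply(cx$subunits, function(s) {
        paste(sprintf("%s:%d", names(s), as.integer(s)), collapse = ";")
      }, character(1)),
      reaction_ids = vapply(cx$complex_id, function(id) {
        paste(catal$reaction_id[catal$complex_id == id], collapse = ";")
      }, character(1)),
      direction = vapply(cx$complex_id, function(id) {
        paste(unique(catal$direction[catal$complex_id == id]),
              collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE)
  } else df <- complexes
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
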