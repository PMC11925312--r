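# Synthetic study generator: a deterministic red-cell-like toy GEM, matching
# protein/complex tables, and donor proteome panels over three storage time
# points with a hemoglobin-dominated mass distribution, log-normal
# low-abundance proteins, missing-at-random detection, storage drift,
# planted abundance-limiting enzymes, and metadata columns with planted
# monotone links to enzyme abundances.

#' Specification for synthetic donor proteome panels
#'
#' Defaults reflect the study conditions the generator emulates: three
#' storage time points (days 10, 23, 42) per donor, hemoglobin carrying 95%
#' of protein mass, log-normally distributed low-abundance proteins,
#' missing-at-random detection, and a planted glucose-transport enzyme
#' whose abundance limits its reaction.
#'
#' @param n_donors number of donors.
#' @param storage_days storage time points (days).
#' @param hb_mass_fraction hemoglobin share of total protein mass.
#' @param lognormal_sigma donor-level log-sd of low-abundance proteins.
#' @param missing_rate probability a non-planted low-abundance measurement
#'   is missing (`[0, 1)`).
#' @param storage_drift named per-protein multiplicative trend per day of
#'   storage (unnamed scalar recycles to all non-hemoglobin proteins).
#' @param planted_limiting character vector of gene symbols whose abundance
#'   is made the binding constraint of their reaction (never masked
#'   missing).
#' @param planted_scale median abundance (nmol/gDW scale after budget
#'   normalization) of planted limiting enzymes.
#' @param metadata_links list: metadata column name -> list(gene, effect)
#'   with `effect` the sign of the planted monotone relationship.
#' @param metadata_noise sd of Gaussian noise added to metadata columns (0
#'   gives exact monotone links).
#' @param hb_missing_rate fraction of donors with missing hemoglobin
#'   concentration (exercises imputation).
#' @param seed integer seed; every draw derives from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_donors = 50, storage_days = c(10, 23, 42),
                           hb_mass_fraction = 0.95, lognormal_sigma = 0.5,
                           missing_rate = 0.1, storage_drift = 0.995,
                           planted_limiting = "SLC2A1",
                           planted_scale = 10,
                           metadata_links = list(
                             osmotic_hemolysis = list(gene = "SLC2A1",
                                                      effect = -1),
                             storage_hemolysis = list(gene = "GYS1",
                                                      effect = 1)),
                           metadata_noise = 0.05,
                           hb_missing_rate = 0.04, seed = 1L) {
  if (missing_rate >= 1 || missing_rate < 0) {
    stop("missing_rate must be in [0, 1)")
  }
  stopifnot(hb_mass_fraction > 0, hb_mass_fraction < 1, n_donors >= 1)
  structure(list(n_donors = n_donors, storage_days = storage_days,
                 hb_mass_fraction = hb_mass_fraction,
                 lognormal_sigma = lognormal_sigma,
                 missing_rate = missing_rate, storage_drift = storage_drift,
                 planted_limiting = planted_limiting,
                 planted_scale = planted_scale,
                 metadata_links = metadata_links,
                 metadata_noise = metadata_noise,
                 hb_missing_rate = hb_missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Deterministic red-cell-like toy metabolic model
#'
#' A small, fully mass- and charge-balanced network: glucose uptake feeding
#' a lumped glycolysis (isozyme pair PKLR/PKM) that powers a sodium/potassium
#' ATPase pump (heterodimeric complex; the default objective), lactate and
#' proton export, spontaneous cation leaks closing the pump cycle, a
#' glycogen-storage branch point, and a fatty-acid-synthesis branch whose
#' malonyl-CoA precursor has no producer (a planted blocked branch).
#'
#' @param seed accepted for interface uniformity; the model is fully
#'   deterministic and identical for every seed.
#' @return a `metabolic_model` with attributes `planted_blocked`,
#'   `planted_spontaneous`, and `objective_reaction`.
#' @export
make_toy_gem <- function(seed = 1L) {
  mets <- utils::read.csv(text = "id,name,compartment,formula,charge
glc__D_e,D-glucose,e,C6H12O6,0
glc__D_c,D-glucose,c,C6H12O6,0
lac__L_c,L-lactate,c,C3H5O3,-1
lac__L_e,L-lactate,e,C3H5O3,-1
atp_c,ATP,c,C10H12N5O13P3,-4
adp_c,ADP,c,C10H12N5O10P2,-3
pi_c,phosphate,c,HPO4,-2
h_c,proton,c,H,1
h_e,proton,e,H,1
h2o_c,water,c,H2O,0
h2o_e,water,e,H2O,0
na1_c,sodium,c,Na,1
na1_e,sodium,e,Na,1
k_c,potassium,c,K,1
k_e,potassium,e,K,1
gstore_c,glycan storage unit,c,C6H10O5,0
malcoa_c,malonyl-CoA,c,C24H33N7O19P3S,-5
faprec_c,acyl precursor,c,C24H35N7O20P3S,-5
facyl_c,acyl product,c,C24H36N7O20P3S,-4
", stringsAsFactors = FALSE)
  rx <- function(id, name, st, lb, ub, gpr, subsystem, category,
                 pseudo = FALSE, obj = 0) {
    list(id = id, name = name, st = st, lb = lb, ub = ub, gpr = gpr,
         subsystem = subsystem, category = category, pseudo = pseudo,
         obj = obj)
  }
  defs <- list(
    rx("EX_glc__D_e", "glucose exchange", c(glc__D_e = -1), -10, 1000, "",
       "Exchange", "Other", pseudo = TRUE),
    rx("EX_lac__L_e", "lactate exchange", c(lac__L_e = -1), 0, 1000, "",
       "Exchange", "Other", pseudo = TRUE),
    rx("EX_h_e", "proton exchange", c(h_e = -1), -1000, 1000, "",
       "Exchange", "Other", pseudo = TRUE),
    rx("EX_h2o_e", "water exchange", c(h2o_e = -1), -1000, 1000, "",
       "Exchange", "Other", pseudo = TRUE),
    rx("GLCt", "glucose transport", c(glc__D_e = -1, glc__D_c = 1),
       -1000, 1000, "SLC2A1", "Transport reactions", "Transport"),
    rx("GLYC", "glycolysis (lumped)",
       c(glc__D_c = -1, adp_c = -2, pi_c = -2, lac__L_c = 2, atp_c = 2,
         h2o_c = 2),
       0, 1000, "PKLR or PKM", "Glycolysis", "Carbohydrate metabolism"),
    rx("NAKATPASE", "sodium/potassium pump",
       c(atp_c = -1, h2o_c = -1, na1_c = -3, k_e = -2, adp_c = 1, pi_c = 1,
         h_c = 1, na1_e = 3, k_c = 2),
       0, 1000, "ATP1A1 and ATP1B1", "Transport reactions", "Transport"),
    rx("LACt", "lactate/proton symport",
       c(lac__L_c = -1, h_c = -1, lac__L_e = 1, h_e = 1),
       -1000, 1000, "SLC16A1", "Transport reactions", "Transport"),
    rx("NAt", "sodium leak (passive)", c(na1_e = -1, na1_c = 1),
       0, 1000, "", "Transport reactions", "Transport"),
    rx("KLEAK", "potassium leak (passive)", c(k_c = -1, k_e = 1),
       0, 1000, "", "Transport reactions", "Transport"),
    rx("H2Ot", "water transport", c(h2o_c = -1, h2o_e = 1),
       -1000, 1000, "AQP1", "Transport reactions", "Transport"),
    rx("GSS", "glycan storage synthesis",
       c(glc__D_c = -1, gstore_c = 1, h2o_c = 1),
       0, 1000, "GYS1", "Glycan metabolism", "Carbohydrate metabolism"),
    rx("DM_gstore_c", "glycan storage demand", c(gstore_c = -1), 0, 1000,
       "", "Demand", "Other", pseudo = TRUE),
    rx("DM_glc__D_c", "intracellular glucose demand", c(glc__D_c = -1),
       0, 1000, "", "Demand", "Other", pseudo = TRUE),
    rx("FAS1", "acyl precursor synthesis",
       c(malcoa_c = -1, h2o_c = -1, faprec_c = 1),
       0, 1000, "FASN", "Fatty acid synthesis", "Lipid metabolism"),
    rx("FAS2", "acyl precursor processing",
       c(faprec_c = -1, h_c = -1, facyl_c = 1),
       0, 1000, "OLAH", "Fatty acid synthesis", "Lipid metabolism"),
    rx("DM_facyl_c", "acyl product demand", c(facyl_c = -1), 0, 1000,
       "", "Demand", "Other", pseudo = TRUE))
  reactions <- do.call(rbind, lapply(defs, function(d) {
    data.frame(id = d$id, name = d$name, lower_bound = d$lb,
               upper_bound = d$ub, gpr = d$gpr, subsystem = d$subsystem,
               category = d$category, is_pseudo = d$pseudo,
               objective_coefficient = d$obj, stringsAsFactors = FALSE)
  }))
  stoich <- setNames(lapply(defs, `[[`, "st"), reactions$id)
  genes <- data.frame(
    symbol = c("SLC2A1", "PKLR", "PKM", "ATP1A1", "ATP1B1", "SLC16A1",
               "AQP1", "GYS1", "FASN", "OLAH"),
    accession = c("P11166", "P30613", "P14618", "P05023", "P05026",
                  "P53985", "P29972", "P13807", "P49327", "Q9GV12"),
    stringsAsFactors = FALSE)
  model <- metabolic_model("toy_rbc", mets, reactions, stoich, genes,
                           name = "toy red-cell network")
  model <- set_objective(model, "NAKATPASE")
  attr(model, "planted_blocked") <- c("FAS1", "FAS2", "DM_facyl_c")
  attr(model, "planted_spontaneous") <- c("NAt", "KLEAK")
  attr(model, "objective_reaction") <- "NAKATPASE"
  model
}

#' Protein and complex tables for the toy model
#'
#' One protein per model gene plus the two hemoglobin chains (not part of
#' any reaction), with realistic molar masses; a curated heterotetrameric
#' pump complex (two copies each of the alpha and beta subunits) overrides
#' the GPR-derived one, and the glycolysis isozyme pair yields two
#' single-subunit complexes.
#'
#' @param model the toy model from [make_toy_gem()].
#' @param seed accepted for interface uniformity; tables are deterministic.
#' @return list `proteins` (a [protein_table()]), `complexes` (as from
#'   [derive_complexes()]), `curated` (the curated records used).
#' @export
make_protein_tables <- function(model, seed = 1L) {
  masses <- c(SLC2A1 = 54084, PKLR = 61830, PKM = 57937, ATP1A1 = 112896,
              ATP1B1 = 35061, SLC16A1 = 53944, AQP1 = 28526, GYS1 = 83786,
              FASN = 273427, OLAH = 29916, HBA1 = 15258, HBB = 15998)
  acc <- c(setNames(model$genes$accession, model$genes$symbol),
           HBA1 = "P69905", HBB = "P68871")
  proteins <- protein_table(
    gene = names(masses), accession = unname(acc[names(masses)]),
    molar_mass_da = unname(masses),
    is_hemoglobin = names(masses) %in% c("HBA1", "HBB"))
  curated <- data.frame(
    complex_id = "CPLX_NAKATPASE",
    subunits = "ATP1A1:2;ATP1B1:2",
    reaction_ids = "NAKATPASE",
    direction = "fwd",
    stringsAsFactors = FALSE)
  complexes <- derive_complexes(model, proteins, curated = curated)
  list(proteins = proteins, complexes = complexes, curated = curated)
}

#' Sample synthetic donor proteome panels
#'
#' Draws per-donor, per-storage-day raw abundance matrices with hemoglobin
#' at the target mass fraction, log-normal low-abundance proteins with
#' per-day multiplicative storage drift, missing-at-random masking (never
#' for planted limiting enzymes), per-donor hemoglobin concentrations
#' (some missing), metadata columns monotonically linked to planted enzyme
#' abundances, and the planted ground truth.
#'
#' @param tables output of [make_protein_tables()].
#' @param spec a [synthetic_spec()].
#' @return list: `raw_matrix` (accessions x samples, `NA` = missing),
#'   `hb_table`, `metadata` (rownames = sample ids), `truth` (class
#'   `planted_truth`).
#' @export
sample_donor_proteomes <- function(tables, spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  proteins <- tables$proteins
  set.seed(spec$seed)
  donors <- sprintf("D%03d", seq_len(spec$n_donors))
  days <- sort(spec$storage_days)
  sample_ids <- as.vector(t(outer(donors, days, paste, sep = "_")))
  genes <- proteins$gene
  w <- setNames(proteins$molar_mass, genes)
  hb <- proteins$is_hemoglobin
  la_genes <- genes[!hb]
  hb_genes <- genes[hb]
  planted <- intersect(spec$planted_limiting, genes)

  # baseline abundance scale (nmol/gDW-like): low-abundance proteins share
  # the non-hemoglobin budget roughly equally; planted enzymes sit at the
  # much lower scale where capacity, not the network, limits flux
  base <- setNames(50 / (length(la_genes) * w[la_genes]), la_genes)
  base[planted] <- spec$planted_scale
  drift <- spec$storage_drift
  if (is.null(names(drift))) {
    drift <- setNames(rep(drift, length(la_genes)), la_genes)
  } else {
    miss <- setdiff(la_genes, names(drift))
    drift <- c(drift, setNames(rep(1, length(miss)), miss))[la_genes]
  }

  raw <- matrix(NA_real_, length(genes), length(sample_ids),
                dimnames = list(unname(proteins$accession[match(
                  genes, proteins$gene)]), sample_ids))
  rownames(raw) <- proteins$accession[match(genes, proteins$gene)]
  truth_abund <- matrix(NA_real_, length(planted), length(sample_ids),
                        dimnames = list(planted, sample_ids))
  for (d in seq_along(donors)) {
    donor_level <- base[la_genes] *
      exp(stats::rnorm(length(la_genes), 0, spec$lognormal_sigma))
    for (t in seq_along(days)) {
      sid <- paste0(donors[d], "_", days[t])
      la <- donor_level * drift[la_genes]^(days[t] - days[1]) *
        exp(stats::rnorm(length(la_genes), 0, 0.05))
      la_mass <- sum(la * w[la_genes])
      hb_total_mass <- la_mass * spec$hb_mass_fraction /
        (1 - spec$hb_mass_fraction)
      split <- 0.5 + stats::runif(1, -0.02, 0.02)
      hb_ab <- hb_total_mass * c(split, 1 - split) / w[hb_genes]
      col <- setNames(numeric(length(genes)), genes)
      col[la_genes] <- la
      col[hb_genes] <- hb_ab
      mask <- stats::runif(length(la_genes)) < spec$missing_rate
      maskable <- setdiff(la_genes[mask], planted)
      col[maskable] <- NA_real_
      raw[, sid] <- unname(col)
      truth_abund[, sid] <- la[planted]
    }
  }

  hb_conc <- stats::rnorm(length(donors), 13.5, 1.2)
  hb_missing <- stats::runif(length(donors)) < spec$hb_missing_rate
  if (all(hb_missing)) hb_missing[1] <- FALSE
  hb_conc[hb_missing] <- NA_real_
  hb_table <- data.frame(donor_id = donors, hb_concentration = hb_conc,
                         stringsAsFactors = FALSE)

  metadata <- data.frame(row.names = sample_ids)
  truth_links <- list()
  for (col in names(spec$metadata_links)) {
    link <- spec$metadata_links[[col]]
    g <- link$gene
    if (!g %in% genes) stop("metadata link references unknown gene ", g)
    acc <- proteins$accession[match(g, proteins$gene)]
    x <- raw[acc, ]
    if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    metadata[[col]] <- link$effect * log(x) +
      stats::rnorm(length(x), 0, spec$metadata_noise)
    truth_links[[col]] <- list(gene = g, sign = sign(link$effect))
  }
  metadata$storage_day <- as.numeric(sub("^.*_", "", sample_ids))

  truth <- structure(list(dependent_genes = planted,
                          planted_abundance = truth_abund,
                          metadata_links = truth_links),
                     class = "planted_truth")
  list(raw_matrix = raw, hb_table = hb_table, metadata = metadata,
       truth = truth)
}

#' Write a full synthetic study bundle to disk
#'
#' Emits the file dialects consumed by the other modules: toy model SBML,
#' protein and complex TSVs, abundance CSV, hemoglobin CSV, metadata CSV,
#' and the planted-truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synthetic_spec()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_toy_gem(spec$seed)
  tables <- make_protein_tables(model, spec$seed)
  panel <- sample_donor_proteomes(tables, spec)
  paths <- c(
    model = file.path(dir, "model.xml"),
    proteins = file.path(dir, "proteins.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    abundance = file.path(dir, "abundance.csv"),
    hb = file.path(dir, "hemoglobin.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json"))
  write_sbml(model, paths["model"])
  write_protein_table(tables$proteins, paths["proteins"])
  write_complex_table(tables$complexes, paths["complexes"])
  utils::write.csv(panel$raw_matrix, paths["abundance"], na = "NA")
  utils::write.csv(panel$hb_table, paths["hb"], row.names = FALSE, na = "NA")
  utils::write.csv(panel$metadata, paths["metadata"], na = "NA")
  jsonlite::write_json(
    list(dependent_genes = panel$truth$dependent_genes,
         metadata_links = lapply(panel$truth$metadata_links, function(l) {
           list(gene = l$gene, sign = l$sign)
         })),
    paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
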