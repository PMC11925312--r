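# Flat-table model dialect: three TSV files (reactions, metabolites, genes)
# mirroring the column layout used by version-controlled GEM repositories.
# Stoichiometry is serialized per reaction as "met:coef;met:coef".

#' Write a model as flat TSV tables
#'
#' Writes `<prefix>_reactions.tsv`, `<prefix>_metabolites.tsv`,
#' `<prefix>_genes.tsv`.
#'
#' @param model a `metabolic_model`.
#' @param prefix path prefix for the three files.
#' @return character vector of the three paths, invisibly.
#' @export
write_model_tables <- function(model, prefix) {
  rx <- model$reactions
  rx$stoichiometry <- vapply(model$stoichiometry[rx$id], function(st) {
    paste(sprintf("%s:%.15g", names(st), st), collapse = ";")
  }, character(1))
  paths <- paste0(prefix, "_", c("reactions", "metabolites", "genes"), ".tsv")
  utils::write.table(rx, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$metabolites, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$genes, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a model from flat TSV tables
#'
#' @param prefix path prefix as used by [write_model_tables()].
#' @param id model id.
#' @return a `metabolic_model`.
#' @export
read_model_tables <- function(prefix, id = basename(prefix)) {
  paths <- paste0(prefix, "_", c("reactions", "metabolites", "genes"), ".tsv")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing table file(s): ",
                            paste(missing, collapse = ", "))
  rx <- utils::read.delim(paths[1], stringsAsFactors = FALSE, na.strings = NULL)
  mets <- utils::read.delim(paths[2], stringsAsFactors = FALSE,
                            na.strings = NULL)
  genes <- utils::read.delim(paths[3], stringsAsFactors = FALSE,
                             na.strings = NULL)
  stoich <- lapply(rx$stoichiometry, function(s) {
    if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
             vapply(parts, `[`, "", 1))
  })
  rx$stoichiometry <- NULL
  metabolic_model(id = id, metabolites = mets, reactions = rx,
                  stoichiometry = setNames(stoich, rx$id), genes = genes)
}

#' Read a metabolic model (SBML or flat tables)
#'
#' Dispatches on the source: an `.xml`/`.sbml` file goes to [read_sbml()],
#' anything else is treated as a flat-table prefix for [read_model_tables()].
#'
#' @param source file path or table prefix.
#' @return a `metabolic_model`.
#' @export
read_model <- function(source) {
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE)) {
    return(read_sbml(source))
  }
  read_model_tables(source)
}

#' Write a metabolic model (SBML or flat tables)
#'
#' @param model a `metabolic_model`.
#' @param target `.xml`/`.sbml` path or flat-table prefix.
#' @return the target, invisibly.
#' @export
write_model <- function(model, target) {
  if (grepl("\\.(xml|sbml)$", target, ignore.case = TRUE)) {
    return(write_sbml(model, target))
  }
  write_model_tables(model, target)
  invisible(target)
}
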