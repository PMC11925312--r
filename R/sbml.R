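# SBML I/O: Level 3 Version 2 core with the fbc version-2 extension
# (flux-bound parameters, gene-product associations, chemical formula and
# charge).  Identifiers carry the conventional M_/R_/G_ prefixes on disk and
# are stripped in memory.  Subsystem, category, and pseudo-reaction flags
# travel in reaction notes using COBRA-style key/value lines.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version2/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape_id <- function(id) gsub("[^A-Za-z0-9_]", "__", id)

#' Write a model to SBML
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "2", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sbml_escape_id(model$id),
                               name = model$name, "fbc:strict" = "true")
  comps <- unique(model$metabolites$compartment)
  cl <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(cl, "compartment", id = cp, constant = "true")
  }
  sl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (k in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[k, ]
    sp <- xml2::xml_add_child(
      sl, "species", id = paste0("M_", sbml_escape_id(mt$id)), name = mt$name,
      compartment = mt$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = as.character(as.integer(mt$charge)))
    if (nzchar(mt$formula) && !is.na(mt$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
    }
  }
  # one shared parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- function(v) {
    s <- gsub("-", "m", gsub("\\.", "p", format(v, scientific = TRUE,
                                                digits = 12)))
    paste0("B_", gsub("\\+", "", s))
  }
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(pl, "parameter", id = bid(v),
                        value = format_sbml_num(v), constant = "true")
  }
  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (k in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[k, ]
    rnode <- xml2::xml_add_child(
      rl, "reaction", id = paste0("R_", sbml_escape_id(rx$id)), name = rx$name,
      reversible = tolower(rx$lower_bound < 0),
      "fbc:lowerFluxBound" = bid(rx$lower_bound),
      "fbc:upperFluxBound" = bid(rx$upper_bound))
    notes <- xml2::xml_add_child(rnode, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rx$subsystem))
    xml2::xml_add_child(body, "p", paste0("CATEGORY: ", rx$category))
    xml2::xml_add_child(body, "p", paste0("PSEUDO: ",
                                          tolower(isTRUE(rx$is_pseudo))))
    st <- model$stoichiometry[[rx$id]]
    st <- st[order(names(st))]  # canonical order keeps round-trips stable
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      ln <- xml2::xml_add_child(rnode, "listOfReactants")
      for (j in seq_along(subs)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_",
                                             sbml_escape_id(names(subs)[j])),
                            stoichiometry = format_sbml_num(-subs[[j]]),
                            constant = "true")
      }
    }
    if (length(prods)) {
      ln <- xml2::xml_add_child(rnode, "listOfProducts")
      for (j in seq_along(prods)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = paste0("M_",
                                             sbml_escape_id(names(prods)[j])),
                            stoichiometry = format_sbml_num(prods[[j]]),
                            constant = "true")
      }
    }
    tree <- parse_gpr(rx$gpr)
    if (!is.null(tree)) {
      ga <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      add_gpa_node(ga, tree)
    }
  }
  gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
  for (k in seq_len(nrow(model$genes))) {
    g <- model$genes[k, ]
    xml2::xml_add_child(gl, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_escape_id(g$symbol)),
                        "fbc:label" = g$symbol, "fbc:name" = g$accession)
  }
  ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  on <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
  oidx <- which(model$reactions$objective_coefficient != 0)
  for (k in oidx) {
    xml2::xml_add_child(
      fl, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_escape_id(model$reactions$id[k])),
      "fbc:coefficient" = format_sbml_num(
        model$reactions$objective_coefficient[k]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

format_sbml_num <- function(v) {
  if (is.infinite(v)) return(if (v > 0) "INF" else "-INF")
  format(v, scientific = FALSE, digits = 15, trim = TRUE)
}

add_gpa_node <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_",
                                                   sbml_escape_id(tree)))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (a in tree$args) add_gpa_node(node, a)
  invisible(NULL)
}

#' Read a model from SBML
#'
#' Parses the SBML Level 3 + fbc dialect written by [write_sbml()] (and the
#' compatible subset produced by COBRA-style exporters): species with
#' formula/charge, flux-bound parameters, gene-product associations, and an
#' active linear objective. Element and reaction ordering follows document
#' order.
#'
#' @param path SBML file path.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in ", path, ": ", conditionMessage(e))
  })
  ns <- c(d1 = SBML_CORE_NS, fbc = SBML_FBC_NS)
  real_ns <- xml2::xml_ns(doc)
  # tolerate other SBML level/version URIs in the default namespace
  ns["d1"] <- unname(real_ns[names(real_ns) == "d1"][1])
  fbcs <- real_ns[grepl("fbc", real_ns)]
  if (length(fbcs)) ns["fbc"] <- unname(fbcs[1])
  mnode <- xml2::xml_find_first(doc, "./d1:model", ns)
  if (inherits(mnode, "xml_missing")) {
    stop("malformed SBML in ", path, ": no <model> element")
  }
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  fattr <- function(node, name) xml2::xml_attr(node, name, ns = ns)

  spn <- xml2::xml_find_all(mnode, ".//d1:listOfSpecies/d1:species", ns)
  charge <- suppressWarnings(as.integer(vapply(spn, fattr, "",
                                               name = "fbc:charge")))
  charge[is.na(charge)] <- 0L
  formula <- vapply(spn, fattr, "", name = "fbc:chemicalFormula")
  formula[is.na(formula)] <- ""
  metabolites <- data.frame(
    id = strip(xml2::xml_attr(spn, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(spn, "name")), "",
                  xml2::xml_attr(spn, "name")),
    compartment = xml2::xml_attr(spn, "compartment"),
    formula = formula, charge = charge, stringsAsFactors = FALSE)

  pn <- xml2::xml_find_all(mnode, ".//d1:listOfParameters/d1:parameter", ns)
  pvals <- setNames(parse_sbml_num(xml2::xml_attr(pn, "value")),
                    xml2::xml_attr(pn, "id"))

  rn <- xml2::xml_find_all(mnode, ".//d1:listOfReactions/d1:reaction", ns)
  n <- length(rn)
  stoich <- vector("list", n)
  lbv <- ubv <- numeric(n)
  gprs <- subsys <- categ <- character(n)
  pseudo <- logical(n)
  rids <- strip(xml2::xml_attr(rn, "id"), "R_")
  for (k in seq_len(n)) {
    node <- rn[[k]]
    lbv[k] <- bound_value(node, "fbc:lowerFluxBound", pvals, ns, -Inf)
    ubv[k] <- bound_value(node, "fbc:upperFluxBound", pvals, ns, Inf)
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(
        node, paste0("./d1:", tag, "/d1:speciesReference"), ns)
      if (length(refs)) {
        co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        co[is.na(co)] <- 1
        st <- c(st, setNames(side * co,
                             strip(xml2::xml_attr(refs, "species"), "M_")))
      }
    }
    stoich[[k]] <- tapply_sum(st)
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gprs[k] <- if (inherits(ga, "xml_missing")) "" else
      deparse_gpr(read_gpa_node(xml2::xml_child(ga), ns))
    notes <- xml2::xml_text(xml2::xml_find_all(
      node, "./d1:notes//*[local-name()='p']", ns))
    subsys[k] <- note_field(notes, "SUBSYSTEM")
    cat_val <- note_field(notes, "CATEGORY")
    categ[k] <- if (nzchar(cat_val)) cat_val else "Other"
    pseudo[k] <- identical(note_field(notes, "PSEUDO"), "true") ||
      grepl("^(EX|DM|SK)_", rids[k])
  }
  reactions <- data.frame(
    id = rids,
    name = ifelse(is.na(xml2::xml_attr(rn, "name")), "",
                  xml2::xml_attr(rn, "name")),
    lower_bound = lbv, upper_bound = ubv, gpr = gprs, subsystem = subsys,
    category = categ, is_pseudo = pseudo, objective_coefficient = 0,
    stringsAsFactors = FALSE)

  gp <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  if (length(gp)) {
    label <- vapply(gp, fattr, "", name = "fbc:label")
    accession <- vapply(gp, fattr, "", name = "fbc:name")
    accession[is.na(accession)] <- ""
    genes <- data.frame(symbol = label, accession = accession,
                        stringsAsFactors = FALSE)
  } else genes <- NULL

  fo <- xml2::xml_find_all(
    mnode, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  obj <- setNames(as.numeric(vapply(fo, fattr, "", name = "fbc:coefficient")),
                  strip(vapply(fo, fattr, "", name = "fbc:reaction"), "R_"))
  obj[is.na(obj)] <- 1
  reactions$objective_coefficient <-
    ifelse(reactions$id %in% names(obj), obj[reactions$id], 0)

  mid <- xml2::xml_attr(mnode, "id")
  mname <- xml2::xml_attr(mnode, "name")
  metabolic_model(id = if (is.na(mid)) "model" else mid,
                  metabolites = metabolites, reactions = reactions,
                  stoichiometry = setNames(stoich, rids), genes = genes,
                  name = if (is.na(mname)) "" else mname)
}

parse_sbml_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("INF", "inf", "Infinity")] <- Inf
  out[x %in% c("-INF", "-inf", "-Infinity")] <- -Inf
  out
}

bound_value <- function(node, attr, pvals, ns, default) {
  ref <- xml2::xml_attr(node, attr, ns = ns)
  if (is.na(ref)) return(default)
  if (!ref %in% names(pvals)) {
    stop("malformed SBML: flux bound references unknown parameter ",
         sQuote(ref))
  }
  unname(pvals[ref])
}

read_gpa_node <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(sub("^G_", "", xml2::xml_attr(node, "fbc:geneProduct", ns = ns)))
  }
  if (nm %in% c("and", "or")) {
    return(list(op = nm,
                args = lapply(xml2::xml_children(node), read_gpa_node,
                              ns = ns)))
  }
  stop("malformed SBML: unexpected element ", sQuote(nm),
       " in geneProductAssociation")
}

note_field <- function(notes, key) {
  hit <- grep(paste0("^", key, ":"), notes, value = TRUE)
  if (!length(hit)) return("")
  trimws(sub(paste0("^", key, ":"), "", hit[1]))
}

tapply_sum <- function(x) {
  if (!length(x)) return(x)
  out <- tapply(x, names(x), sum)
  setNames(as.numeric(out), names(out))
}
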