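# Minimal SBML Level 3 core importer (with optional fbc package support for
# flux bounds, objectives and gene-product associations).  Import only; the
# tabular dialect is the package's native format.

#' Read a metabolic network from an SBML Level 3 file
#'
#' Supports SBML Level 3 core: `listOfCompartments`, `listOfSpecies`,
#' `listOfReactions` with `listOfReactants`/`listOfProducts` stoichiometry.
#' When the `fbc` package is present, per-reaction flux bounds
#' (`fbc:lowerFluxBound`/`fbc:upperFluxBound` resolved through
#' `listOfParameters`), the active objective, and
#' `fbc:geneProductAssociation` rules are imported.  Without `fbc`
#' annotations, bounds default to `[-1000, 1000]` for reversible and
#' `[0, 1000]` for irreversible reactions.
#'
#' @param path Path to an SBML file.
#' @return A `metabolic_network`.
#' @export
read_network_sbml <- function(path) {
  if (!file.exists(path)) .parse_error("missing file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  param_val <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) .parse_error("SBML file contains no species")
  met_id <- xml2::xml_attr(sp, "id")
  met_name <- xml2::xml_attr(sp, "name")
  met_name[is.na(met_name)] <- met_id[is.na(met_name)]
  mets <- data.frame(id = met_id, name = met_name,
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  mets$is_water <- grepl("^(M_)?h2o(_.*)?$", met_id, ignore.case = TRUE)
  mets$is_proton <- grepl("^(M_)?h(_.*)?$", met_id, ignore.case = TRUE)

  gene_products <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*")
  gp_label <- stats::setNames(
    xml2::xml_attr(gene_products, "label"),
    xml2::xml_attr(gene_products, "id"))

  # active objective
  obj_coef <- list()
  fobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  for (fo in fobj)
    obj_coef[[xml2::xml_attr(fo, "reaction")]] <-
      as.numeric(xml2::xml_attr(fo, "coefficient"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) .parse_error("SBML file contains no reactions")
  n <- length(rx)
  rxn_id <- xml2::xml_attr(rx, "id")
  rxn_name <- xml2::xml_attr(rx, "name")
  rxn_name[is.na(rxn_name)] <- rxn_id[is.na(rxn_name)]
  lb <- ub <- numeric(n)
  gpr <- character(n)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rxn_id))
  for (j in seq_len(n)) {
    r <- rx[[j]]
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(param_val)) param_val[[lbp]] else
      if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(param_val)) param_val[[ubp]] else 1000
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(r, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% mets$id)
          .validation_error("reaction ", rxn_id[j],
                            " references undeclared species ", sid)
        S[sid, j] <- S[sid, j] + sign * st
      }
    }
    gpa <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(gpa, "xml_missing")) "" else .sbml_gpa_to_rule(gpa, gp_label)
  }
  rxns <- data.frame(id = rxn_id, name = rxn_name, lower_bound = lb,
                     upper_bound = ub,
                     objective_coeff = vapply(rxn_id, function(id)
                       obj_coef[[id]] %||% 0, numeric(1)),
                     gpr = gpr, stringsAsFactors = FALSE)
  metabolic_network(mets, rxns, S)
}

# Render an fbc geneProductAssociation subtree as a boolean rule string.
.sbml_gpa_to_rule <- function(node, gp_label) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- gp_label[[ref]]
    return(if (is.null(lbl) || is.na(lbl)) ref else lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .sbml_gpa_to_rule, character(1), gp_label = gp_label)
  parts <- parts[nzchar(parts)]
  if (name == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (name == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  paste(parts, collapse = " ")
}
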