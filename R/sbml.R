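# SBML Level 3 export of the model variants: two compartments, species,
# parameters, and mass-action kinetic laws in MathML.

mathml_times <- function(symbols) {
  ci <- paste0("<ci> ", symbols, " </ci>", collapse = " ")
  if (length(symbols) == 1) ci else paste0("<apply> <times/> ", ci, " </apply>")
}

#' Export a model as SBML Level 3
#'
#' Writes an SBML L3V2 document with `nucleus` and `cytosol` compartments,
#' one species per model species, one (global) parameter per free rate
#' constant, and one reaction per mass-action reaction with its kinetic law.
#' Rates pinned to 1 by the nondimensionalization are exported as parameters
#' with value 1.
#'
#' @param model a `reaction_network`.
#' @param path output file.
#' @param params optional named values for the parameters (default 1).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path, params = NULL) {
  stopifnot(inherits(model, "reaction_network"))
  val <- function(sym) {
    if (sym == "one") 1
    else if (!is.null(params) && sym %in% names(params)) unname(unlist(params)[sym])
    else 1
  }
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = model$name)
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$species$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true",
                        spatialDimensions = "3", size = "1")
  }
  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(spl, "species",
                        id = model$species$name[i],
                        compartment = model$species$compartment[i],
                        initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  prl <- xml2::xml_add_child(mdl, "listOfParameters")
  rate_syms <- unique(vapply(model$reactions, function(r) r$rate, character(1)))
  for (sym in rate_syms) {
    xml2::xml_add_child(prl, "parameter", id = sym,
                        value = format(val(sym)), constant = "true")
  }
  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    rx <- xml2::xml_add_child(rxl, "reaction",
                              id = sprintf("r%02d_%s", j, r$rate),
                              reversible = "false")
    if (length(r$reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in unique(r$reactants)) {
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = format(sum(r$reactants == s)),
                            constant = "true")
      }
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in unique(r$products)) {
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = format(sum(r$products == s)),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- paste0(
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\"> ",
      mathml_times(c(r$rate, r$reactants)), " </math>")
    xml2::xml_add_child(kl, xml2::read_xml(math))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
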