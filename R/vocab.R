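#' Controlled vocabulary of physical-entity classes
#'
#' The closed set of entity classes recognized by the model, mirroring the
#' PathoML `PhysicalEntity` hierarchy at the granularity used throughout the
#' package: cells, cellular components, proteins, and tissue-scale entities.
#' `"Other"` is an escape hatch for entities outside the named hierarchy; such
#' nodes carry a free-text `subtype`.
#'
#' @return Character vector of admissible `entity_class` values.
#' @export
entity_classes <- function() {
  c("PhysicalEntity",
    "Cell", "NeoplasticCell",
    "Cellular_Component", "NeoplasticCellularComponent",
    "Protein",
    "Tumor", "Stroma", "Parenchyma", "Substance",
    "Tissue", "Anatomical_Structure",
    "Other")
}

# Kind predicates used by invariants.
is_cell_class <- function(x) x %in% c("Cell", "NeoplasticCell")
is_component_class <- function(x) {
  x %in% c("Cellular_Component", "NeoplasticCellularComponent")
}
is_protein_class <- function(x) x == "Protein"

phenotype_pathoml_classes <- function() {
  c("Cytopathological_Phenotype", "Histopathological_Phenotype",
    "Immunophenotype", "Quantitative_Indicators")
}

phenotype_kinds <- function() {
  c("single_cell", "multi_cell", "quantitative_indicator")
}
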