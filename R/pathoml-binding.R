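# IRI binding between the in-memory model and the PathoML vocabulary.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDF_TYPE <- paste0(RDF_NS, "type")

#' PathoML IRI binding
#'
#' Maps model types and entity classes to ontology class IRIs, edge kinds to
#' object properties, and scalar fields to data properties. Both the schema
#' namespace and the per-document individual namespace are configurable; the
#' maps are total over everything the model can serialize.
#'
#' @param schema_ns Namespace of the PathoML schema terms.
#' @param doc_ns Namespace under which a document's individuals are minted.
#' @return A list with `schema_ns`, `doc_ns`, `class_map`, `objprop_map`,
#'   `dataprop_map`.
#' @export
pathoml_binding <- function(schema_ns = "http://www.pathoml.org/pathoml#",
                            doc_ns = "http://example.org/pathograph/doc#") {
  pml <- function(x) paste0(schema_ns, x)
  class_map <- c(
    stats::setNames(vapply(entity_classes(), pml, ""), entity_classes()),
    EntityGraph = pml("EntityGraph"),
    EntityAttribute = pml("EntityAttribute"),
    Quantification = pml("Quantification"),
    Cytopathological_Phenotype = pml("Cytopathological_Phenotype"),
    Histopathological_Phenotype = pml("Histopathological_Phenotype"),
    Immunophenotype = pml("Immunophenotype"),
    Quantitative_Indicators = pml("Quantitative_Indicators"),
    Relationship = pml("Relationship"),
    DiagnosisProcess = pml("DiagnosisProcess"),
    DiagnosisStage = pml("DiagnosisStage"),
    Final_Diagnosis = pml("Final_Diagnosis"),
    Differential_Diagnosis = pml("Differential_Diagnosis"),
    Xref = pml("Xref"),
    HE_Slide = pml("HE_Slide"),
    IHC_Slide = pml("IHC_Slide"),
    Pathology_Report = pml("Pathology_Report"),
    PathoDocument = pml("PathoDocument")
  )
  objprop_map <- c(
    hasComponent = pml("hasComponent"),
    express = pml("express"),
    hasAttribute = pml("hasAttribute"),
    quantification = pml("quantification"),
    present_Entity = pml("present_Entity"),
    has_Relationship = pml("has_Relationship"),
    subject = pml("subject"),
    object = pml("object"),
    has_quantity = pml("has_quantity"),
    diagnosisOrder = pml("diagnosisOrder"),
    nextStep = pml("nextStep"),
    stepProcess = pml("stepProcess"),
    examinesPhenotype = pml("examinesPhenotype"),
    hasSupportEvidence = pml("hasSupportEvidence"),
    hasContradictEvidence = pml("hasContradictEvidence"),
    has_Phenotype = pml("has_Phenotype"),
    has_Process = pml("has_Process"),
    has_EntityGraph = pml("has_EntityGraph"),
    hasRoot = pml("hasRoot"),
    hasXref = pml("hasXref")
  )
  dataprop_map <- c(
    displayName = pml("displayName"),
    segmentation = pml("segmentation"),
    boundingBox = pml("boundingBox"),
    otherSubtype = pml("otherSubtype"),
    featureName = pml("featureName"),
    paramName = pml("paramName"),
    hasValue = pml("hasValue"),
    unit = pml("unit"),
    phenotypeKind = pml("phenotypeKind"),
    predicateLabel = pml("predicateLabel"),
    relationCategory = pml("relationCategory"),
    indicatorName = pml("indicatorName"),
    hasFormula = pml("hasFormula"),
    diagnosisLabel = pml("diagnosisLabel"),
    diagnosisItem = pml("diagnosisItem"),
    stageIndex = pml("stageIndex"),
    xrefVocabulary = pml("xrefVocabulary"),
    xrefCode = pml("xrefCode"),
    slideHeight = pml("slideHeight"),
    slideWidth = pml("slideWidth"),
    magnification = pml("magnification"),
    antigen = pml("antigen"),
    provenance = pml("provenance")
  )
  list(schema_ns = schema_ns, doc_ns = doc_ns, class_map = class_map,
       objprop_map = objprop_map, dataprop_map = dataprop_map)
}

# Empty triple table. o_type: "iri" or "literal"; dt: datatype IRI or NA
# (plain string).
empty_triples <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_type = character(), dt = character(), stringsAsFactors = FALSE)
}

triple <- function(s, p, o, o_type = "iri", dt = NA_character_) {
  data.frame(s = s, p = p, o = o, o_type = o_type, dt = dt,
             stringsAsFactors = FALSE)
}

lit <- function(s, p, text) triple(s, p, as.character(text), "literal")
lit_dbl <- function(s, p, x) triple(s, p, pg_format_double(x), "literal",
                                    paste0(XSD_NS, "double"))
lit_int <- function(s, p, x) triple(s, p, sprintf("%d", as.integer(x)),
                                    "literal", paste0(XSD_NS, "integer"))

# Canonical triple-set key used for set comparison and deduplication.
triple_key <- function(tr) {
  paste(tr$s, tr$p, tr$o_type, tr$o, ifelse(is.na(tr$dt), "", tr$dt),
        sep = "\r")
}

# Set equality of two triple tables.
same_triples <- function(a, b) {
  setequal(triple_key(a), triple_key(b))
}
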