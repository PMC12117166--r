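#' Create a pathological entity node
#'
#' An entity node stands for a microscopically observable biological structure
#' (a cell, a cellular component, a protein, a tumor region, ...). The class is
#' drawn from the closed hierarchy in [entity_classes()]. Entities may carry a
#' segmentation outline (polygon, pixel units) and an axis-aligned bounding box.
#'
#' @param id Document-unique identifier (opaque string).
#' @param entity_class One of [entity_classes()].
#' @param display_name Human-readable name; defaults to `id`.
#' @param outline Optional `n x 2` numeric matrix of polygon vertices
#'   (pixel coordinates, image convention: y grows downward).
#' @param bbox Optional numeric vector `c(xmin, ymin, xmax, ymax)`; computed
#'   from the outline when an outline is present and `bbox` is `NULL`.
#' @param subtype Free-text subtype, required when `entity_class == "Other"`.
#' @param xrefs List of `c(vocabulary, code)` character pairs.
#' @return An object of class `pg_entity`.
#' @export
entity_node <- function(id, entity_class, display_name = id, outline = NULL,
                        bbox = NULL, subtype = NULL, xrefs = list()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!entity_class %in% entity_classes()) {
    pg_stop("pg_vocab_error",
            sprintf("unknown entity class '%s'", entity_class))
  }
  if (identical(entity_class, "Other") && is.null(subtype)) {
    pg_stop("pg_vocab_error", "'Other' entities require a free-text subtype")
  }
  if (!is.null(outline)) {
    outline <- as.matrix(outline)
    storage.mode(outline) <- "double"
    if (is.null(bbox)) {
      bbox <- c(min(outline[, 1]), min(outline[, 2]),
                max(outline[, 1]), max(outline[, 2]))
    }
  }
  structure(list(id = id, entity_class = entity_class,
                 display_name = display_name, outline = outline, bbox = bbox,
                 subtype = subtype, xrefs = xrefs),
            class = "pg_entity")
}

#' Create a pathological feature node
#'
#' A feature names a characteristic of an entity that changes with disease
#' (e.g. "staining extent", "nuclear shape"). It is owned by exactly one entity
#' of the same graph and may be quantified by parameters.
#'
#' @param id Document-unique identifier.
#' @param feature_name Controlled or free text.
#' @param owner_id Id of the owning entity node.
#' @return An object of class `pg_feature`.
#' @export
feature_node <- function(id, feature_name, owner_id) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  structure(list(id = id, feature_name = feature_name,
                 owner_id = owner_id, xrefs = list()),
            class = "pg_feature")
}

#' Create a quantitative parameter
#'
#' A measurable quantity attached to a feature (e.g. an area in px^2, a
#' roundness, a staining completeness fraction).
#'
#' @param id Document-unique identifier.
#' @param param_name Parameter name.
#' @param value Finite numeric value.
#' @param unit Unit text; empty for dimensionless quantities.
#' @param feature_id Id of the quantified feature node.
#' @return An object of class `pg_param`.
#' @export
quant_param <- function(id, param_name, value, unit = "", feature_id) {
  stopifnot(is.character(id), length(id) == 1)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    pg_stop("pg_value_error",
            sprintf("parameter '%s' must have a finite numeric value", id))
  }
  structure(list(id = id, param_name = param_name, value = as.numeric(value),
                 unit = unit, feature_id = feature_id, xrefs = list()),
            class = "pg_param")
}

#' Create a spatial or behavioral relationship edge
#'
#' Relationships capture spatial arrangement patterns ("back-to-back
#' arrangement", "envelops") and dynamic behaviors ("invades") among the
#' entities of a multi-cell phenotype. `subjects` initiate or anchor the
#' relation; `objects` are its targets.
#'
#' @param id Document-unique identifier.
#' @param predicate Relation label.
#' @param category `"spatial"` or `"behavioral"`.
#' @param subjects,objects Non-empty, disjoint character vectors of entity ids.
#' @return An object of class `pg_relationship`.
#' @export
relationship_edge <- function(id, predicate, category = c("spatial", "behavioral"),
                              subjects, objects) {
  category <- match.arg(category)
  stopifnot(length(subjects) >= 1, length(objects) >= 1)
  structure(list(id = id, predicate = predicate, category = category,
                 subjects = as.character(subjects),
                 objects = as.character(objects)),
            class = "pg_relationship")
}

#' Create a phenotype
#'
#' Phenotypes come in three graph-theoretic kinds: `single_cell` (one cell and
#' its alterations), `multi_cell` (several entities plus their spatial and
#' behavioral relationships), and `quantitative_indicator` (a numeric phenotype;
#' see [quant_indicator()] for the indicator object itself). The PathoML class
#' records the slide modality the phenotype was observed in.
#'
#' @param id Document-unique identifier.
#' @param kind One of [phenotype_kinds()].
#' @param pathoml_class One of [phenotype_pathoml_classes()].
#' @param label Phenotype label used for display and for reasoning atoms
#'   (e.g. "glandular pattern").
#' @param entities Character vector of entity ids constituting the phenotype.
#' @param relationships List of [relationship_edge()] objects (multi-cell only).
#' @param entity_graphs Named list mapping entity ids to their expanded
#'   [build_entity_graph()] representations; normally filled by
#'   [expand_phenotype()].
#' @param xrefs List of `c(vocabulary, code)` pairs.
#' @return An object of class `pg_phenotype`.
#' @export
phenotype <- function(id, kind, pathoml_class, label = id,
                      entities = character(), relationships = list(),
                      entity_graphs = list(), xrefs = list()) {
  if (!kind %in% phenotype_kinds()) {
    pg_stop("pg_vocab_error", sprintf("unknown phenotype kind '%s'", kind))
  }
  if (!pathoml_class %in% phenotype_pathoml_classes()) {
    pg_stop("pg_vocab_error",
            sprintf("unknown phenotype class '%s'", pathoml_class))
  }
  structure(list(id = id, kind = kind, pathoml_class = pathoml_class,
                 label = label, entities = as.character(entities),
                 relationships = relationships,
                 entity_graphs = entity_graphs, xrefs = xrefs),
            class = "pg_phenotype")
}

#' Create a quantitative phenotypic indicator
#'
#' A numeric phenotype (e.g. "% tumor cells with intracytoplasmic mucin")
#' computed from quantitative parameters by a stated formula. The formula is
#' stored as content MathML text; when it is evaluable over the parameters,
#' validation checks that it reproduces `value`.
#'
#' @param id Document-unique identifier.
#' @param name Indicator name.
#' @param params List of [quant_param()] objects used in the calculation.
#' @param value Finite numeric result.
#' @param formula Content-MathML string (may be empty).
#' @param xrefs List of `c(vocabulary, code)` pairs.
#' @return An object of class `pg_indicator`.
#' @export
quant_indicator <- function(id, name, params = list(), value, formula = "",
                            xrefs = list()) {
  if (!is.numeric(value) || !is.finite(value)) {
    pg_stop("pg_value_error", sprintf("indicator '%s' value must be finite", id))
  }
  structure(list(id = id, name = name, params = params,
                 value = as.numeric(value), formula = formula, xrefs = xrefs),
            class = "pg_indicator")
}

#' Create a diagnostic possibility
#'
#' One candidate outcome considered at a diagnostic stage, either
#' `"established"` or `"excluded"`, with supporting and contradicting phenotype
#' evidence. A phenotype id may not appear in both evidence lists.
#'
#' @param id Document-unique identifier.
#' @param label The diagnostic possibility (e.g. "large B-cell lymphoma").
#' @param status `"established"` or `"excluded"`.
#' @param support,contradict Character vectors of phenotype/indicator ids.
#' @return An object of class `pg_diagnosis`.
#' @export
diagnosis <- function(id, label, status = c("established", "excluded"),
                      support = character(), contradict = character()) {
  status <- match.arg(status)
  structure(list(id = id, label = label, status = status,
                 support = as.character(support),
                 contradict = as.character(contradict), xrefs = list()),
            class = "pg_diagnosis")
}

#' Create a diagnostic stage
#'
#' One step of a staged diagnostic process: the possibilities the pathologist
#' weighs at this stage and the phenotypes examined.
#'
#' @param id Document-unique identifier.
#' @param index Positive integer position in the process.
#' @param possibilities Non-empty list of [diagnosis()] objects.
#' @param phenotypes Character vector of phenotype/indicator ids examined.
#' @return An object of class `pg_stage`.
#' @export
diagnosis_stage <- function(id, index, possibilities, phenotypes = character()) {
  stopifnot(length(possibilities) >= 1)
  index <- as.integer(index)
  if (is.na(index) || index < 1) {
    pg_stop("pg_value_error", "stage index must be a positive integer")
  }
  structure(list(id = id, index = index, possibilities = possibilities,
                 phenotypes = as.character(phenotypes)),
            class = "pg_stage")
}

#' Assemble and validate a staged diagnostic process
#'
#' Stages are held in list order; the order encodes the successor chain that
#' serialization emits as explicit next-step pairs. Stage indices must be
#' strictly increasing, and the terminal stage may establish at most one
#' outcome. Establishing outcomes at non-terminal stages is permitted (a stage
#' may confirm an intermediate diagnosis that later stages refine), but more
#' than one established outcome at a non-terminal stage draws a warning.
#'
#' @param stages Ordered, non-empty list of [diagnosis_stage()] objects.
#' @param id Process identifier.
#' @param item The diagnostic item the process resolves (e.g. "histologic type").
#' @return An object of class `pg_process`.
#' @export
build_diagnosis_process <- function(stages, id = "Process-1",
                                    item = "histologic type") {
  if (length(stages) < 1) {
    pg_stop("pg_value_error", "a diagnostic process requires at least one stage")
  }
  idx <- vapply(stages, function(s) s$index, 1L)
  if (anyDuplicated(idx)) {
    pg_stop("pg_value_error",
            sprintf("duplicate stage indices: %s",
                    paste(idx[duplicated(idx)], collapse = ", ")))
  }
  if (any(diff(idx) <= 0)) {
    pg_stop("pg_value_error", "stage indices must be strictly increasing")
  }
  for (s in stages[-length(stages)]) {
    n_est <- sum(vapply(s$possibilities,
                        function(d) d$status == "established", TRUE))
    if (n_est > 1) {
      warning(sprintf("stage '%s' establishes %d outcomes", s$id, n_est))
    }
  }
  proc <- structure(list(id = id, stages = stages, item = item, xrefs = list()),
                    class = "pg_process")
  v <- validate_process(proc)
  if (nrow(v) > 0) {
    pg_stop("pg_validation_error",
            paste(v$message, collapse = "; "))
  }
  proc
}

#' Create a pathology document
#'
#' The unit of PathoML serialization: a container binding entity graphs,
#' phenotypes, quantitative indicators and diagnostic processes to slide or
#' report metadata.
#'
#' @param entity_graphs List of [build_entity_graph()] results.
#' @param phenotypes List of [phenotype()] objects.
#' @param indicators List of [quant_indicator()] objects.
#' @param processes List of [build_diagnosis_process()] results.
#' @param slide_meta Optional list with fields `modality` (`"HE"`, `"IHC"` or
#'   `"report"`), `height`, `width`, `magnification`, and for IHC slides
#'   `antigen`.
#' @param provenance Free-text provenance note.
#' @param id Document identifier (the subject of document-level metadata).
#' @return An object of class `pg_document`.
#' @export
patho_document <- function(entity_graphs = list(), phenotypes = list(),
                           indicators = list(), processes = list(),
                           slide_meta = NULL, provenance = "",
                           id = "document") {
  named_by_id <- function(xs) {
    if (length(xs) == 0) return(list())
    stats::setNames(xs, vapply(xs, function(x) x$id, ""))
  }
  structure(list(id = id,
                 entity_graphs = named_by_id(entity_graphs),
                 phenotypes = named_by_id(phenotypes),
                 indicators = named_by_id(indicators),
                 processes = named_by_id(processes),
                 slide_meta = slide_meta, provenance = provenance),
            class = "pg_document")
}

# All entity nodes of a document, keyed by id (roots + components).
document_entities <- function(doc) {
  out <- list()
  for (g in doc$entity_graphs) {
    out[[g$root$id]] <- g$root
    for (e in g$components) out[[e$id]] <- e
  }
  out
}

# Ids usable as diagnostic evidence: phenotypes and indicators.
document_phenotype_ids <- function(doc) {
  c(names(doc$phenotypes), names(doc$indicators))
}

#' @export
print.pg_document <- function(x, ...) {
  cat("<pathology document>", x$id, "\n")
  cat("  entity graphs:", length(x$entity_graphs),
      " phenotypes:", length(x$phenotypes),
      " indicators:", length(x$indicators),
      " processes:", length(x$processes), "\n")
  if (!is.null(x$slide_meta)) {
    cat("  slide:", x$slide_meta$modality %||% "?",
        if (!is.null(x$slide_meta$antigen)) paste0("(", x$slide_meta$antigen, ")")
        else "", "\n")
  }
  invisible(x)
}

#' @export
print.pg_entity_graph <- function(x, ...) {
  cat("<entity graph> root:", x$root$id, sprintf("(%s)", x$root$entity_class),
      "\n  components:", length(x$components),
      " features:", length(x$features),
      " params:", length(x$params),
      "\n  part-whole edges:", nrow(x$part_whole),
      " express edges:", nrow(x$express_links), "\n")
  invisible(x)
}

#' @export
print.pg_process <- function(x, ...) {
  cat("<diagnosis process>", x$id, "item:", x$item, "\n")
  for (s in x$stages) {
    labs <- vapply(s$possibilities,
                   function(d) sprintf("%s [%s]", d$label, d$status), "")
    cat(sprintf("  stage %d (%s): %s\n", s$index, s$id,
                paste(labs, collapse = "; ")))
  }
  invisible(x)
}
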