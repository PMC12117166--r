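# Structural validation. Violations are returned as records, never raised;
# builders that promise errors call these and translate.

validate_entity_node <- function(e, where = e$id) {
  v <- pg_no_violations()
  if (!is.null(e$outline)) {
    if (nrow(e$outline) < 3) {
      v <- rbind_violations(v, pg_violation("EntityNode", where, "outline",
        sprintf("entity '%s': outline has fewer than 3 vertices", e$id)))
    } else {
      a <- tryCatch(polygon_area(e$outline), error = function(err) NA_real_)
      if (is.na(a) || a <= 0) {
        v <- rbind_violations(v, pg_violation("EntityNode", where, "outline",
          sprintf("entity '%s': outline degenerate or self-intersecting", e$id)))
      }
    }
    if (!is.null(e$bbox) && nrow(e$outline) >= 1) {
      inside <- all(e$outline[, 1] >= e$bbox[1] - 1e-9,
                    e$outline[, 2] >= e$bbox[2] - 1e-9,
                    e$outline[, 1] <= e$bbox[3] + 1e-9,
                    e$outline[, 2] <= e$bbox[4] + 1e-9)
      if (!inside) {
        v <- rbind_violations(v, pg_violation("EntityNode", where, "bbox",
          sprintf("entity '%s': bounding box does not contain the outline", e$id)))
      }
    }
  }
  v
}

validate_entity_graph <- function(g) {
  v <- pg_no_violations()
  ent_ids <- c(g$root$id, names(g$components))
  feat_ids <- names(g$features)
  par_ids <- names(g$params)

  if (g$root$id %in% names(g$components)) {
    v <- rbind_violations(v, pg_violation("EntityGraph", g$id, "root",
      sprintf("root '%s' also listed among components", g$root$id)))
  }
  dup <- unique(c(ent_ids, feat_ids, par_ids)[duplicated(c(ent_ids, feat_ids, par_ids))])
  if (length(dup) > 0) {
    v <- rbind_violations(v, pg_violation("EntityGraph", g$id, "unique_ids",
      sprintf("duplicate ids within graph: %s", paste(dup, collapse = ", "))))
  }

  for (e in c(list(g$root), g$components)) {
    v <- rbind_violations(v, validate_entity_node(e))
  }

  check_refs <- function(pairs, from_ok, to_ok, rel) {
    bad_from <- setdiff(pairs$from, from_ok)
    bad_to <- setdiff(pairs$to, to_ok)
    out <- pg_no_violations()
    for (b in bad_from) out <- rbind_violations(out,
      pg_violation("EntityGraph", g$id, "resolution",
        sprintf("%s: unresolved source id '%s'", rel, b)))
    for (b in bad_to) out <- rbind_violations(out,
      pg_violation("EntityGraph", g$id, "resolution",
        sprintf("%s: unresolved target id '%s'", rel, b)))
    out
  }
  v <- rbind_violations(v,
    check_refs(g$part_whole, ent_ids, setdiff(ent_ids, g$root$id), "part_whole"),
    check_refs(g$feature_links, ent_ids, feat_ids, "feature_links"),
    check_refs(g$quant_links, feat_ids, par_ids, "quant_links"),
    check_refs(g$express_links, ent_ids, ent_ids, "express_links"))

  for (f in g$features) {
    if (!f$owner_id %in% ent_ids) {
      v <- rbind_violations(v, pg_violation("FeatureNode", f$id, "resolution",
        sprintf("feature '%s': owner '%s' not in graph", f$id, f$owner_id)))
    }
  }
  for (q in g$params) {
    if (!q$feature_id %in% feat_ids) {
      v <- rbind_violations(v, pg_violation("QuantParam", q$id, "resolution",
        sprintf("parameter '%s': feature '%s' not in graph", q$id, q$feature_id)))
    }
  }

  cyc <- find_cycle(g$part_whole)
  if (!is.null(cyc)) {
    v <- rbind_violations(v, pg_violation("EntityGraph", g$id, "part_whole_acyclic",
      sprintf("part-whole cycle: %s", paste(cyc, collapse = " -> "))))
  }

  # Express typing: cellular component -> protein.
  if (nrow(g$express_links) > 0 &&
      nrow(v[v$clause == "resolution", , drop = FALSE]) == 0) {
    lookup <- c(stats::setNames(list(g$root), g$root$id), g$components)
    for (i in seq_len(nrow(g$express_links))) {
      fr <- lookup[[g$express_links$from[i]]]
      to <- lookup[[g$express_links$to[i]]]
      if (!is_component_class(fr$entity_class) || !is_protein_class(to$entity_class)) {
        v <- rbind_violations(v, pg_violation("EntityGraph", g$id, "express_typing",
          sprintf("express edge %s -> %s must pair a cellular component with a protein",
                  fr$id, to$id)))
      }
    }
  }

  # Connectivity: components hang off the root through part-whole or express.
  if (is.null(cyc) && length(g$components) > 0) {
    seen <- reachable_from(g$root$id, g$part_whole, g$express_links)
    stranded <- setdiff(names(g$components), seen)
    if (length(stranded) > 0) {
      v <- rbind_violations(v, pg_violation("EntityGraph", g$id, "connectivity",
        sprintf("components unreachable from root: %s",
                paste(stranded, collapse = ", "))))
    }
  }
  v
}

validate_phenotype <- function(p, entity_lookup = NULL) {
  v <- pg_no_violations()
  if (p$kind == "single_cell") {
    if (length(p$entities) != 1) {
      v <- rbind_violations(v, pg_violation("Phenotype", p$id, "single_cell_cardinality",
        sprintf("single-cell phenotype '%s' must reference exactly one cell, has %d",
                p$id, length(p$entities))))
    } else if (!is.null(entity_lookup)) {
      e <- entity_lookup[[p$entities[1]]]
      if (!is.null(e) && !is_cell_class(e$entity_class)) {
        v <- rbind_violations(v, pg_violation("Phenotype", p$id, "single_cell_class",
          sprintf("single-cell phenotype '%s' references non-cell entity '%s' (%s)",
                  p$id, e$id, e$entity_class)))
      }
    }
  }
  if (p$kind == "multi_cell") {
    if (length(p$entities) < 2 && length(p$relationships) < 1) {
      v <- rbind_violations(v, pg_violation("Phenotype", p$id, "multi_cell_cardinality",
        sprintf("multi-cell phenotype '%s' needs >=2 entities or >=1 relationship", p$id)))
    }
  }
  for (r in p$relationships) {
    if (length(intersect(r$subjects, r$objects)) > 0) {
      v <- rbind_violations(v, pg_violation("RelationshipEdge", r$id, "subject_object_disjoint",
        sprintf("relationship '%s': subjects and objects overlap", r$id)))
    }
    bad <- setdiff(c(r$subjects, r$objects), p$entities)
    if (length(bad) > 0) {
      v <- rbind_violations(v, pg_violation("RelationshipEdge", r$id, "resolution",
        sprintf("relationship '%s': endpoints not among phenotype entities: %s",
                r$id, paste(bad, collapse = ", "))))
    }
  }
  if (!is.null(entity_lookup)) {
    bad <- p$entities[!vapply(p$entities,
                              function(eid) !is.null(entity_lookup[[eid]]), TRUE)]
    if (length(bad) > 0) {
      v <- rbind_violations(v, pg_violation("Phenotype", p$id, "resolution",
        sprintf("phenotype '%s': unresolved entities: %s",
                p$id, paste(bad, collapse = ", "))))
    }
  }
  v
}

validate_indicator <- function(qi) {
  v <- pg_no_violations()
  if (nzchar(qi$formula)) {
    vals <- stats::setNames(vapply(qi$params, function(q) q$value, 0),
                            vapply(qi$params, function(q) q$param_name, ""))
    got <- tryCatch(eval_mathml(qi$formula, vals), error = function(e) NULL)
    if (!is.null(got) && is.finite(got)) {
      denom <- max(abs(qi$value), 1)
      if (abs(got - qi$value) / denom > 1e-9) {
        v <- rbind_violations(v, pg_violation("QuantIndicator", qi$id, "formula_value",
          sprintf("indicator '%s': formula evaluates to %.12g, stored value %.12g",
                  qi$id, got, qi$value)))
      }
    }
  }
  v
}

validate_process <- function(proc, visible_phenotypes = NULL) {
  v <- pg_no_violations()
  if (length(proc$stages) < 1) {
    return(pg_violation("DiagnosisProcess", proc$id, "stages",
                        sprintf("process '%s' has no stages", proc$id)))
  }
  idx <- vapply(proc$stages, function(s) s$index, 1L)
  if (any(diff(idx) <= 0)) {
    v <- rbind_violations(v, pg_violation("DiagnosisProcess", proc$id, "stage_order",
      sprintf("process '%s': stage indices not strictly increasing", proc$id)))
  }
  terminal <- proc$stages[[length(proc$stages)]]
  n_est <- sum(vapply(terminal$possibilities,
                      function(d) d$status == "established", TRUE))
  if (n_est > 1) {
    v <- rbind_violations(v, pg_violation("DiagnosisStage", terminal$id,
      "terminal_established",
      sprintf("terminal stage '%s' establishes %d outcomes (at most one allowed)",
              terminal$id, n_est)))
  }
  for (s in proc$stages) {
    for (d in s$possibilities) {
      both <- intersect(d$support, d$contradict)
      if (length(both) > 0) {
        v <- rbind_violations(v, pg_violation("Diagnosis", d$id, "evidence_disjoint",
          sprintf("diagnosis '%s': evidence both supports and contradicts: %s",
                  d$id, paste(both, collapse = ", "))))
      }
      if (!is.null(visible_phenotypes)) {
        bad <- setdiff(c(d$support, d$contradict), visible_phenotypes)
        if (length(bad) > 0) {
          v <- rbind_violations(v, pg_violation("Diagnosis", d$id, "resolution",
            sprintf("diagnosis '%s': evidence ids not in document: %s",
                    d$id, paste(bad, collapse = ", "))))
        }
      }
    }
    if (!is.null(visible_phenotypes)) {
      bad <- setdiff(s$phenotypes, visible_phenotypes)
      if (length(bad) > 0) {
        v <- rbind_violations(v, pg_violation("DiagnosisStage", s$id, "resolution",
          sprintf("stage '%s': phenotype ids not in document: %s",
                  s$id, paste(bad, collapse = ", "))))
      }
    }
  }
  v
}

#' Validate a pathology document
#'
#' Checks every structural invariant of every contained object — entity-graph
#' relation typing and acyclicity, phenotype cardinalities, indicator
#' formula/value agreement, diagnostic-process stage ordering and evidence
#' resolution, and document-wide id uniqueness. Violations are returned as
#' records, not raised; an empty result means the document is clean.
#'
#' @param doc A [patho_document()].
#' @return A data frame with columns `type`, `id`, `clause`, `message`;
#'   zero rows iff the document is valid.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "pg_document"))
  v <- pg_no_violations()

  ids <- character()
  for (g in doc$entity_graphs) {
    ids <- c(ids, g$id, g$root$id, names(g$components), names(g$features),
             names(g$params))
  }
  ids <- c(ids, names(doc$phenotypes), names(doc$indicators))
  for (p in doc$phenotypes) ids <- c(ids, vapply(p$relationships,
                                                 function(r) r$id, ""))
  for (pr in doc$processes) {
    ids <- c(ids, pr$id)
    for (s in pr$stages) {
      ids <- c(ids, s$id, vapply(s$possibilities, function(d) d$id, ""))
    }
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    v <- rbind_violations(v, pg_violation("PathoDocument", doc$id, "unique_ids",
      sprintf("duplicate ids document-wide: %s", paste(dup, collapse = ", "))))
  }

  for (g in doc$entity_graphs) v <- rbind_violations(v, validate_entity_graph(g))
  lookup <- document_entities(doc)
  for (p in doc$phenotypes) {
    v <- rbind_violations(v, validate_phenotype(p, entity_lookup = lookup))
  }
  for (qi in doc$indicators) v <- rbind_violations(v, validate_indicator(qi))
  visible <- document_phenotype_ids(doc)
  for (pr in doc$processes) {
    v <- rbind_violations(v, validate_process(pr, visible_phenotypes = visible))
  }

  if (!is.null(doc$slide_meta)) {
    m <- doc$slide_meta
    if (!is.null(m$modality) && !m$modality %in% c("HE", "IHC", "report")) {
      v <- rbind_violations(v, pg_violation("PathoDocument", doc$id, "slide_meta",
        sprintf("unknown modality '%s'", m$modality)))
    }
  }
  v
}
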