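# Serialization: model -> triples -> Turtle / RDF-XML.

outline_to_text <- function(outline) {
  paste(paste0(pg_format_double(outline[, 1]), ",",
               pg_format_double(outline[, 2])), collapse = " ")
}

text_to_outline <- function(txt) {
  pts <- strsplit(trimws(txt), "\\s+")[[1]]
  do.call(rbind, lapply(strsplit(pts, ","), as.numeric))
}

bbox_to_text <- function(bbox) paste(pg_format_double(bbox), collapse = ",")
text_to_bbox <- function(txt) as.numeric(strsplit(txt, ",")[[1]])

# paste0() treats zero-length vectors as ""; IRI minting must not.
mint <- function(ns, ids) {
  if (length(ids) == 0) return(character(0))
  paste0(ns, ids)
}

# Triple collector: chunked append of parallel character vectors, flattened
# once at the end. Keeps serialization linear in document size.
tc_new <- function() {
  e <- new.env(parent = emptyenv())
  e$chunks <- list()
  e
}
tc_add <- function(tc, s, p, o, o_type = "iri", dt = NA_character_) {
  if (length(s) == 0 || length(p) == 0 || length(o) == 0) {
    return(invisible(NULL))
  }
  n <- max(length(s), length(p), length(o))
  tc$chunks[[length(tc$chunks) + 1]] <-
    list(s = rep_len(as.character(s), n), p = rep_len(as.character(p), n),
         o = rep_len(as.character(o), n),
         o_type = rep_len(o_type, n), dt = rep_len(dt, n))
  invisible(NULL)
}
tc_lit <- function(tc, s, p, text) tc_add(tc, s, p, as.character(text), "literal")
tc_dbl <- function(tc, s, p, x) {
  tc_add(tc, s, p, pg_format_double(x), "literal", paste0(XSD_NS, "double"))
}
tc_int <- function(tc, s, p, x) {
  tc_add(tc, s, p, sprintf("%d", as.integer(x)), "literal",
         paste0(XSD_NS, "integer"))
}
tc_table <- function(tc) {
  if (length(tc$chunks) == 0) return(empty_triples())
  g <- function(f) unlist(lapply(tc$chunks, `[[`, f), use.names = FALSE)
  data.frame(s = g("s"), p = g("p"), o = g("o"), o_type = g("o_type"),
             dt = g("dt"), stringsAsFactors = FALSE)
}

# Xref individuals are shared document-wide (same vocab+code, same IRI).
emit_xrefs <- function(tc, owner_iri, xrefs, b) {
  for (x in xrefs) {
    xid <- paste0(b$doc_ns, "Xref-", x[1], "-", x[2])
    tc_add(tc, owner_iri, b$objprop_map[["hasXref"]], xid)
    tc_add(tc, xid, RDF_TYPE, b$class_map[["Xref"]])
    tc_lit(tc, xid, b$dataprop_map[["xrefVocabulary"]], x[1])
    tc_lit(tc, xid, b$dataprop_map[["xrefCode"]], x[2])
  }
}

emit_entity <- function(tc, e, b) {
  iri <- paste0(b$doc_ns, e$id)
  tc_add(tc, iri, RDF_TYPE, b$class_map[[e$entity_class]])
  tc_lit(tc, iri, b$dataprop_map[["displayName"]], e$display_name)
  if (!is.null(e$outline)) {
    tc_lit(tc, iri, b$dataprop_map[["segmentation"]], outline_to_text(e$outline))
  }
  if (!is.null(e$bbox)) {
    tc_lit(tc, iri, b$dataprop_map[["boundingBox"]], bbox_to_text(e$bbox))
  }
  if (!is.null(e$subtype)) {
    tc_lit(tc, iri, b$dataprop_map[["otherSubtype"]], e$subtype)
  }
  emit_xrefs(tc, iri, e$xrefs, b)
}

emit_param <- function(tc, q, b) {
  iri <- paste0(b$doc_ns, q$id)
  tc_add(tc, iri, RDF_TYPE, b$class_map[["Quantification"]])
  tc_lit(tc, iri, b$dataprop_map[["paramName"]], q$param_name)
  tc_dbl(tc, iri, b$dataprop_map[["hasValue"]], q$value)
  if (nzchar(q$unit)) tc_lit(tc, iri, b$dataprop_map[["unit"]], q$unit)
  emit_xrefs(tc, iri, q$xrefs, b)
}

emit_entity_graph <- function(tc, g, b) {
  ex <- function(id) mint(b$doc_ns, id)
  tc_add(tc, ex(g$id), RDF_TYPE, b$class_map[["EntityGraph"]])
  tc_add(tc, ex(g$id), b$objprop_map[["hasRoot"]], ex(g$root$id))
  for (e in c(list(g$root), g$components)) emit_entity(tc, e, b)
  for (f in g$features) {
    iri <- ex(f$id)
    tc_add(tc, iri, RDF_TYPE, b$class_map[["EntityAttribute"]])
    tc_lit(tc, iri, b$dataprop_map[["featureName"]], f$feature_name)
    emit_xrefs(tc, iri, f$xrefs, b)
  }
  for (q in g$params) emit_param(tc, q, b)
  edge <- function(pairs, prop) {
    tc_add(tc, ex(pairs$from), b$objprop_map[[prop]], ex(pairs$to))
  }
  edge(g$part_whole, "hasComponent")
  edge(g$express_links, "express")
  edge(g$feature_links, "hasAttribute")
  edge(g$quant_links, "quantification")
}

emit_phenotype <- function(tc, p, b) {
  ex <- function(id) mint(b$doc_ns, id)
  iri <- ex(p$id)
  tc_add(tc, iri, RDF_TYPE, b$class_map[[p$pathoml_class]])
  tc_lit(tc, iri, b$dataprop_map[["phenotypeKind"]], p$kind)
  tc_lit(tc, iri, b$dataprop_map[["displayName"]], p$label)
  tc_add(tc, iri, b$objprop_map[["present_Entity"]], ex(p$entities))
  for (r in p$relationships) {
    ri <- ex(r$id)
    tc_add(tc, iri, b$objprop_map[["has_Relationship"]], ri)
    tc_add(tc, ri, RDF_TYPE, b$class_map[["Relationship"]])
    tc_lit(tc, ri, b$dataprop_map[["predicateLabel"]], r$predicate)
    tc_lit(tc, ri, b$dataprop_map[["relationCategory"]], r$category)
    tc_add(tc, ri, b$objprop_map[["subject"]], ex(r$subjects))
    tc_add(tc, ri, b$objprop_map[["object"]], ex(r$objects))
  }
  emit_xrefs(tc, iri, p$xrefs, b)
}

emit_indicator <- function(tc, qi, b) {
  ex <- function(id) mint(b$doc_ns, id)
  iri <- ex(qi$id)
  tc_add(tc, iri, RDF_TYPE, b$class_map[["Quantitative_Indicators"]])
  tc_lit(tc, iri, b$dataprop_map[["indicatorName"]], qi$name)
  tc_dbl(tc, iri, b$dataprop_map[["hasValue"]], qi$value)
  if (nzchar(qi$formula)) {
    tc_lit(tc, iri, b$dataprop_map[["hasFormula"]], qi$formula)
  }
  for (q in qi$params) {
    tc_add(tc, iri, b$objprop_map[["has_quantity"]], ex(q$id))
    emit_param(tc, q, b)
  }
  emit_xrefs(tc, iri, qi$xrefs, b)
}

emit_process <- function(tc, pr, b) {
  ex <- function(id) mint(b$doc_ns, id)
  iri <- ex(pr$id)
  tc_add(tc, iri, RDF_TYPE, b$class_map[["DiagnosisProcess"]])
  tc_lit(tc, iri, b$dataprop_map[["diagnosisItem"]], pr$item)
  stages <- pr$stages
  for (k in seq_along(stages)) {
    s <- stages[[k]]
    si <- ex(s$id)
    tc_add(tc, iri, b$objprop_map[["diagnosisOrder"]], si)
    tc_add(tc, si, RDF_TYPE, b$class_map[["DiagnosisStage"]])
    tc_int(tc, si, b$dataprop_map[["stageIndex"]], s$index)
    if (k < length(stages)) {
      tc_add(tc, si, b$objprop_map[["nextStep"]], ex(stages[[k + 1]]$id))
    }
    tc_add(tc, si, b$objprop_map[["examinesPhenotype"]], ex(s$phenotypes))
    for (d in s$possibilities) {
      di <- ex(d$id)
      cls <- if (d$status == "established") "Final_Diagnosis"
             else "Differential_Diagnosis"
      tc_add(tc, si, b$objprop_map[["stepProcess"]], di)
      tc_add(tc, di, RDF_TYPE, b$class_map[[cls]])
      tc_lit(tc, di, b$dataprop_map[["diagnosisLabel"]], d$label)
      tc_add(tc, di, b$objprop_map[["hasSupportEvidence"]], ex(d$support))
      tc_add(tc, di, b$objprop_map[["hasContradictEvidence"]], ex(d$contradict))
      emit_xrefs(tc, di, d$xrefs, b)
    }
  }
  emit_xrefs(tc, iri, pr$xrefs, b)
}

# Full document -> triple table (deduplicated).
doc_to_triples <- function(doc, binding = pathoml_binding()) {
  b <- binding
  ex <- function(id) mint(b$doc_ns, id)
  tc <- tc_new()
  tc_add(tc, sub("#$", "", b$doc_ns), RDF_TYPE, paste0(OWL_NS, "Ontology"))
  di <- ex(doc$id)
  doc_class <- "PathoDocument"
  if (!is.null(doc$slide_meta)) {
    m <- doc$slide_meta
    doc_class <- switch(m$modality %||% "x", HE = "HE_Slide",
                        IHC = "IHC_Slide", report = "Pathology_Report",
                        "PathoDocument")
    if (!is.null(m$height)) tc_int(tc, di, b$dataprop_map[["slideHeight"]], m$height)
    if (!is.null(m$width)) tc_int(tc, di, b$dataprop_map[["slideWidth"]], m$width)
    if (!is.null(m$magnification)) {
      tc_dbl(tc, di, b$dataprop_map[["magnification"]], m$magnification)
    }
    if (!is.null(m$antigen)) tc_lit(tc, di, b$dataprop_map[["antigen"]], m$antigen)
  }
  tc_add(tc, di, RDF_TYPE, b$class_map[[doc_class]])
  if (nzchar(doc$provenance)) {
    tc_lit(tc, di, b$dataprop_map[["provenance"]], doc$provenance)
  }
  for (g in doc$entity_graphs) {
    tc_add(tc, di, b$objprop_map[["has_EntityGraph"]], ex(g$id))
    emit_entity_graph(tc, g, b)
  }
  for (p in doc$phenotypes) {
    tc_add(tc, di, b$objprop_map[["has_Phenotype"]], ex(p$id))
    emit_phenotype(tc, p, b)
  }
  for (qi in doc$indicators) {
    tc_add(tc, di, b$objprop_map[["has_Phenotype"]], ex(qi$id))
    emit_indicator(tc, qi, b)
  }
  for (pr in doc$processes) {
    tc_add(tc, di, b$objprop_map[["has_Process"]], ex(pr$id))
    emit_process(tc, pr, b)
  }
  tr <- tc_table(tc)
  tr[!duplicated(triple_key(tr)), , drop = FALSE]
}

# --- Turtle ---------------------------------------------------------------

turtle_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# Shorten IRIs to qnames under the binding's prefixes, else <iri>. Vectorized.
turtle_term <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  unmatched <- rep(TRUE, length(iri))
  for (px in names(prefixes)) {
    ns <- prefixes[[px]]
    hit <- unmatched & startsWith(iri, ns)
    if (any(hit)) {
      local <- substring(iri[hit], nchar(ns) + 1)
      ok <- grepl("^[A-Za-z0-9_.-]*$", local) & !grepl("^[.]|[.]$", local)
      idx <- which(hit)[ok]
      out[idx] <- paste0(px, ":", local[ok])
      unmatched[idx] <- FALSE
    }
  }
  out
}

triples_to_turtle <- function(tr, binding = pathoml_binding()) {
  prefixes <- c(ex = binding$doc_ns, owl = OWL_NS, pml = binding$schema_ns,
                rdf = RDF_NS, xsd = XSD_NS)
  header <- paste0("@prefix ", names(prefixes), ": <", prefixes, "> .")
  # Pre-render all terms once.
  tr$sq <- turtle_term(tr$s, prefixes)
  tr$pq <- ifelse(tr$p == RDF_TYPE, "a", turtle_term(tr$p, prefixes))
  oq <- character(nrow(tr))
  is_iri <- tr$o_type == "iri"
  oq[is_iri] <- turtle_term(tr$o[is_iri], prefixes)
  lit_idx <- which(!is_iri)
  if (length(lit_idx) > 0) {
    base <- paste0("\"", turtle_escape(tr$o[lit_idx]), "\"")
    has_dt <- !is.na(tr$dt[lit_idx])
    base[has_dt] <- paste0(base[has_dt], "^^",
                           turtle_term(tr$dt[lit_idx][has_dt], prefixes))
    oq[lit_idx] <- base
  }
  tr$oq <- oq
  blocks <- character()
  for (s in pg_sort(unique(tr$sq))) {
    rows <- tr[tr$sq == s, , drop = FALSE]
    lines <- character()
    # rdf:type first (as 'a'), then predicates in lexicographic qname order.
    for (pq in unique(c("a", pg_sort(rows$pq)))) {
      sel <- rows$oq[rows$pq == pq]
      if (length(sel) == 0) next
      lines <- c(lines, paste0("  ", pq, " ",
                               paste(pg_sort(sel), collapse = ", ")))
    }
    blocks <- c(blocks, paste0(s, "\n", paste(lines, collapse = " ;\n"), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

# --- RDF/XML --------------------------------------------------------------

triples_to_rdfxml <- function(tr, binding = pathoml_binding()) {
  doc <- xml2::xml_new_root("rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:owl" = OWL_NS,
    "xmlns:pml" = binding$schema_ns, "xmlns:ex" = binding$doc_ns,
    "xmlns:xsd" = XSD_NS)
  prefixes <- c(rdf = RDF_NS, owl = OWL_NS, pml = binding$schema_ns,
                ex = binding$doc_ns)
  qname <- function(iri) {
    for (px in names(prefixes)) {
      if (startsWith(iri, prefixes[[px]])) {
        return(paste0(px, ":", substring(iri, nchar(prefixes[[px]]) + 1)))
      }
    }
    NA_character_
  }
  for (s in pg_sort(unique(tr$s))) {
    rows <- tr[tr$s == s, , drop = FALSE]
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    pred_q <- vapply(rows$p, function(p) qname(p) %||% p, "")
    ord <- order(ifelse(rows$p == RDF_TYPE, "", pred_q),
                 rows$o, method = "radix")
    for (i in ord) {
      row <- rows[i, ]
      pq <- qname(row$p)
      if (is.na(pq)) next  # only schema-bound predicates occur
      if (row$o_type == "iri") {
        xml2::xml_add_child(node, pq, "rdf:resource" = row$o)
      } else {
        kid <- xml2::xml_add_child(node, pq)
        xml2::xml_text(kid) <- row$o
        if (!is.na(row$dt)) xml2::xml_attr(kid, "rdf:datatype") <- row$dt
      }
    }
  }
  as.character(doc)
}

#' Serialize a pathology document to PathoML
#'
#' Writes one ontology document containing a named individual per graph node,
#' typed by its PathoML class; one triple per edge using the bound object
#' property; and scalar fields as data-property assertions. Segmentation
#' outlines are serialized into the `segmentation` data property as
#' `"x0,y0 x1,y1 ..."` pixel-coordinate strings. The Turtle dialect is
#' canonical: individuals are sorted by IRI and predicates lexicographically,
#' so two writes of the same document are byte-identical.
#'
#' @param doc A [patho_document()]; must validate cleanly.
#' @param dialect `"turtle"` (default) or `"rdfxml"`.
#' @param file Optional path; when given, the text is also written there.
#' @param binding A [pathoml_binding()].
#' @return The ontology text, invisibly when `file` is given.
#' @export
write_pathoml <- function(doc, dialect = c("turtle", "rdfxml"), file = NULL,
                          binding = pathoml_binding()) {
  dialect <- match.arg(dialect)
  v <- validate_document(doc)
  if (nrow(v) > 0) {
    pg_stop("pg_validation_error",
            paste0("document has ", nrow(v), " violation(s): ",
                   paste(utils::head(v$message, 5), collapse = "; ")),
            violations = v)
  }
  tr <- doc_to_triples(doc, binding)
  txt <- if (dialect == "turtle") triples_to_turtle(tr, binding)
         else triples_to_rdfxml(tr, binding)
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
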