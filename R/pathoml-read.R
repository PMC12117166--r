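# Parsing: Turtle / RDF-XML -> triples -> model. The Turtle reader covers the
# profile this package writes (prefixed names, 'a', predicate and object
# lists, plain/typed string literals, bare numerals) — not full Turtle.

turtle_unescape <- function(x) {
  # Single pass so an escaped backslash never re-triggers a later rule.
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        esc <- chars[i + 1]
        out <- c(out, switch(esc, n = "\n", t = "\t", r = "\r",
                             "\"" = "\"", "\\" = "\\",
                             pg_stop("pg_parse_error",
                                     sprintf("unknown escape \\%s", esc))))
        i <- i + 2
      } else {
        out <- c(out, chars[i])
        i <- i + 1
      }
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Single-pass regex tokenizer over the Turtle profile this package emits.
tokenize_turtle <- function(txt) {
  pat <- paste0(
    "<[^>]*>",                              # IRIREF
    '|"(?:\\\\.|[^"\\\\])*"',               # string literal
    "|@[A-Za-z]+",                          # directive
    "|\\^\\^",                              # datatype marker
    "|[;,\\[\\]]",                          # punctuation
    "|[+-]?[0-9][0-9eE.+-]*",               # numeral (may swallow a final .)
    "|[A-Za-z][A-Za-z0-9_:.-]*",            # pname / keyword (ditto)
    "|\\.",                                 # statement terminator
    "|#[^\n]*",                             # comment
    "|[^\\s]")                              # anything else -> error token
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  raw <- regmatches(txt, list(m))[[1]]
  raw <- raw[!startsWith(raw, "#")]
  # A '.' glued to the end of a name/number token is the statement terminator.
  glued <- grepl("^[A-Za-z+0-9-]", raw) & endsWith(raw, ".") & nchar(raw) > 1
  if (any(glued)) {
    expanded <- vector("list", length(raw))
    for (i in seq_along(raw)) {
      expanded[[i]] <- if (glued[i]) c(substring(raw[i], 1, nchar(raw[i]) - 1), ".")
                       else raw[i]
    }
    raw <- unlist(expanded, use.names = FALSE)
  }
  tokens <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    tk <- raw[i]
    first <- substring(tk, 1, 1)
    tokens[[i]] <-
      if (first == "<") {
        if (!endsWith(tk, ">")) pg_stop("pg_parse_error", "unterminated IRI")
        list(type = "iri", value = substring(tk, 2, nchar(tk) - 1))
      } else if (first == "\"") {
        list(type = "string",
             value = turtle_unescape(substring(tk, 2, nchar(tk) - 1)))
      } else if (first == "@") {
        list(type = "directive", value = tk)
      } else if (tk %in% c(";", ",", ".", "^^", "[", "]")) {
        list(type = tk, value = tk)
      } else if (grepl("^[+-]?[0-9]", tk)) {
        list(type = "number", value = tk)
      } else if (grepl("^[A-Za-z]", tk)) {
        list(type = if (grepl(":", tk, fixed = TRUE)) "pname" else "word",
             value = tk)
      } else {
        pg_stop("pg_parse_error", sprintf("unexpected character '%s'", tk))
      }
  }
  tokens
}

parse_turtle <- function(txt) {
  tokens <- tokenize_turtle(txt)
  prefixes <- list()
  acc <- tc_new()
  k <- 1
  n <- length(tokens)
  peek <- function() if (k <= n) tokens[[k]] else list(type = "eof")
  advance <- function() { t <- tokens[[k]]; k <<- k + 1; t }
  expect <- function(type) {
    t <- advance()
    if (t$type != type) pg_stop("pg_parse_error",
                                sprintf("expected %s, got %s", type, t$type))
    t
  }
  resolve <- function(t) {
    if (t$type == "iri") return(t$value)
    if (t$type == "pname") {
      parts <- regmatches(t$value, regexpr(":", t$value), invert = TRUE)[[1]]
      px <- parts[1]; local <- parts[2]
      if (is.null(prefixes[[px]])) {
        pg_stop("pg_parse_error", sprintf("undeclared prefix '%s'", px))
      }
      return(paste0(prefixes[[px]], local))
    }
    pg_stop("pg_parse_error", sprintf("expected IRI, got %s", t$type))
  }
  parse_object <- function() {
    t <- advance()
    if (t$type %in% c("iri", "pname")) {
      return(list(o = resolve(t), o_type = "iri", dt = NA_character_))
    }
    if (t$type == "string") {
      dt <- NA_character_
      if (peek()$type == "^^") { advance(); dt <- resolve(advance()) }
      return(list(o = t$value, o_type = "literal", dt = dt))
    }
    if (t$type == "number") {
      dt <- paste0(XSD_NS, if (grepl("[.eE]", t$value)) "double" else "integer")
      return(list(o = t$value, o_type = "literal", dt = dt))
    }
    pg_stop("pg_parse_error", sprintf("unexpected object token %s", t$type))
  }
  while (k <= n) {
    t <- peek()
    if (t$type == "directive" && t$value == "@prefix") {
      advance()
      px <- expect("pname")$value
      px <- sub(":$", "", px)
      iri <- expect("iri")$value
      expect(".")
      prefixes[[px]] <- iri
      next
    }
    s <- resolve(advance())
    repeat {
      pt <- advance()
      p <- if (pt$type == "word" && pt$value == "a") RDF_TYPE else resolve(pt)
      repeat {
        obj <- parse_object()
        tc_add(acc, s, p, obj$o, obj$o_type, obj$dt)
        if (peek()$type == ",") { advance(); next }
        break
      }
      t2 <- advance()
      if (t2$type == ";") {
        if (peek()$type == ".") { advance(); break }  # tolerate '; .'
        next
      }
      if (t2$type == ".") break
      pg_stop("pg_parse_error",
              sprintf("expected ';' or '.', got %s", t2$type))
    }
  }
  tc_table(acc)
}

parse_rdfxml <- function(txt) {
  doc <- xml2::read_xml(txt)
  acc <- tc_new()
  ns <- xml2::xml_ns(doc)
  for (node in xml2::xml_children(doc)) {
    s <- xml2::xml_attr(node, "about")
    if (is.na(s)) pg_stop("pg_parse_error", "rdf:Description without rdf:about")
    # A typed element form (<pml:Class rdf:about=...>) contributes rdf:type.
    nm <- xml2::xml_name(node, ns = ns)
    if (nm != "rdf:Description") {
      iri <- sub("^([a-zA-Z0-9]+):", "", nm)
      px <- sub(":.*$", "", nm)
      tc_add(acc, s, RDF_TYPE, paste0(ns[[px]], iri))
    }
    for (kid in xml2::xml_children(node)) {
      knm <- xml2::xml_name(kid, ns = ns)
      px <- sub(":.*$", "", knm)
      local <- sub("^[^:]*:", "", knm)
      p <- paste0(ns[[px]], local)
      res <- xml2::xml_attr(kid, "resource")
      if (!is.na(res)) {
        tc_add(acc, s, p, res)
      } else {
        dt <- xml2::xml_attr(kid, "datatype")
        tc_add(acc, s, p, xml2::xml_text(kid), "literal",
               if (is.na(dt)) NA_character_ else dt)
      }
    }
  }
  tc_table(acc)
}

#' Parse PathoML text into an RDF triple table
#'
#' Low-level access to the serialized graph: one row per triple, with subject,
#' predicate, object, object type (`iri`/`literal`) and datatype IRI. The
#' dialect is sniffed from the content.
#'
#' @param text Ontology text (Turtle or RDF/XML).
#' @return Data frame with columns `s`, `p`, `o`, `o_type`, `dt`.
#' @export
pathoml_triples <- function(text) {
  if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", text)) parse_rdfxml(text)
  else parse_turtle(text)
}

iri_local <- function(iri) sub(".*[#/]", "", iri)

# --- triples -> model -----------------------------------------------------

triples_to_doc <- function(tr, binding = pathoml_binding()) {
  b <- binding
  inv_class <- stats::setNames(names(b$class_map), unname(b$class_map))
  op <- b$objprop_map
  dp <- b$dataprop_map

  types <- tr[tr$p == RDF_TYPE & tr$o_type == "iri", , drop = FALSE]
  types <- types[types$o != paste0(OWL_NS, "Ontology"), , drop = FALSE]
  unknown <- setdiff(unique(types$o), unname(b$class_map))
  if (length(unknown) > 0) {
    pg_stop("pg_parse_error",
            sprintf("unknown class IRI: %s", paste(unknown, collapse = ", ")))
  }
  type_of <- stats::setNames(inv_class[types$o], types$s)
  declared <- unique(types$s)

  # Every object-property target must be a declared individual.
  obj_rows <- tr[tr$o_type == "iri" & tr$p %in% unname(op), , drop = FALSE]
  dangling <- setdiff(unique(obj_rows$o), declared)
  if (length(dangling) > 0) {
    pg_resolution_error(
      sprintf("object property target(s) not declared: %s",
              paste(vapply(dangling, iri_local, ""), collapse = ", ")),
      ids = dangling)
  }

  get_lit <- function(s, prop) {
    v <- tr$o[tr$s == s & tr$p == dp[[prop]] & tr$o_type == "literal"]
    if (length(v) == 0) NULL else v[1]
  }
  get_objs <- function(s, prop) {
    pg_sort(tr$o[tr$s == s & tr$p == op[[prop]] & tr$o_type == "iri"])
  }
  xrefs_of <- function(s) {
    xs <- get_objs(s, "hasXref")
    lapply(xs, function(xi) c(get_lit(xi, "xrefVocabulary") %||% "",
                              get_lit(xi, "xrefCode") %||% ""))
  }

  subjects_of_class <- function(classes) {
    declared[type_of[declared] %in% classes]
  }

  # Entities.
  ent_subjects <- subjects_of_class(entity_classes())
  entities <- list()
  for (s in ent_subjects) {
    seg <- get_lit(s, "segmentation")
    bb <- get_lit(s, "boundingBox")
    entities[[s]] <- entity_node(
      id = iri_local(s), entity_class = type_of[[s]],
      display_name = get_lit(s, "displayName") %||% iri_local(s),
      outline = if (!is.null(seg)) text_to_outline(seg) else NULL,
      bbox = if (!is.null(bb)) text_to_bbox(bb) else NULL,
      subtype = get_lit(s, "otherSubtype"),
      xrefs = xrefs_of(s))
  }

  features <- list()
  for (s in subjects_of_class("EntityAttribute")) {
    owner <- tr$s[tr$p == op[["hasAttribute"]] & tr$o == s]
    f <- feature_node(iri_local(s), get_lit(s, "featureName") %||% iri_local(s),
                      owner_id = if (length(owner) > 0) iri_local(owner[1]) else "")
    f$xrefs <- xrefs_of(s)
    features[[s]] <- f
  }
  params <- list()
  for (s in subjects_of_class("Quantification")) {
    feat <- tr$s[tr$p == op[["quantification"]] & tr$o == s]
    q <- quant_param(iri_local(s), get_lit(s, "paramName") %||% iri_local(s),
                     value = as.numeric(get_lit(s, "hasValue") %||% "NaN"),
                     unit = get_lit(s, "unit") %||% "",
                     feature_id = if (length(feat) > 0) iri_local(feat[1]) else "")
    q$xrefs <- xrefs_of(s)
    params[[s]] <- q
  }

  pairs_between <- function(prop, from_set, to_set) {
    rows <- tr[tr$p == op[[prop]] & tr$s %in% from_set & tr$o %in% to_set, ,
               drop = FALSE]
    pg_pairs(vapply(rows$s, iri_local, ""), vapply(rows$o, iri_local, ""))
  }

  # Entity graphs: membership by traversal from the root.
  graphs <- list()
  for (s in subjects_of_class("EntityGraph")) {
    root_iri <- get_objs(s, "hasRoot")
    if (length(root_iri) == 0) {
      pg_resolution_error(sprintf("entity graph '%s' lacks a root", iri_local(s)))
    }
    root_iri <- root_iri[1]
    pw_all <- tr[tr$p == op[["hasComponent"]], c("s", "o"), drop = FALSE]
    ex_all <- tr[tr$p == op[["express"]], c("s", "o"), drop = FALSE]
    member_iris <- reachable_from(root_iri,
                                  pg_pairs(pw_all$s, pw_all$o),
                                  pg_pairs(ex_all$s, ex_all$o))
    member_iris <- intersect(member_iris, ent_subjects)
    comp_iris <- setdiff(member_iris, root_iri)
    feat_iris <- tr$o[tr$p == op[["hasAttribute"]] & tr$s %in% member_iris]
    feat_iris <- intersect(unique(feat_iris), names(features))
    par_iris <- tr$o[tr$p == op[["quantification"]] & tr$s %in% feat_iris]
    par_iris <- intersect(unique(par_iris), names(params))
    graphs[[s]] <- build_entity_graph(
      root = entities[[root_iri]],
      components = unname(entities[pg_sort(comp_iris)]),
      features = unname(features[pg_sort(feat_iris)]),
      params = unname(params[pg_sort(par_iris)]),
      part_whole = pairs_between("hasComponent", member_iris, member_iris),
      feature_links = pairs_between("hasAttribute", member_iris, feat_iris),
      quant_links = pairs_between("quantification", feat_iris, par_iris),
      express_links = pairs_between("express", member_iris, member_iris),
      id = iri_local(s))
  }

  # Phenotypes vs quantitative indicators (both may be typed
  # Quantitative_Indicators; phenotypes always carry phenotypeKind).
  phen_classes <- phenotype_pathoml_classes()
  phenos <- list()
  indicators <- list()
  for (s in subjects_of_class(phen_classes)) {
    kind <- get_lit(s, "phenotypeKind")
    if (is.null(kind)) {
      par_iris <- get_objs(s, "has_quantity")
      indicators[[s]] <- quant_indicator(
        id = iri_local(s), name = get_lit(s, "indicatorName") %||% iri_local(s),
        params = unname(params[par_iris]),
        value = as.numeric(get_lit(s, "hasValue") %||% "NaN"),
        formula = get_lit(s, "hasFormula") %||% "",
        xrefs = xrefs_of(s))
    } else {
      rels <- list()
      for (ri in get_objs(s, "has_Relationship")) {
        rels[[length(rels) + 1]] <- relationship_edge(
          id = iri_local(ri),
          predicate = get_lit(ri, "predicateLabel") %||% "",
          category = get_lit(ri, "relationCategory") %||% "spatial",
          subjects = vapply(get_objs(ri, "subject"), iri_local, ""),
          objects = vapply(get_objs(ri, "object"), iri_local, ""))
      }
      phenos[[s]] <- phenotype(
        id = iri_local(s), kind = kind, pathoml_class = type_of[[s]],
        label = get_lit(s, "displayName") %||% iri_local(s),
        entities = vapply(get_objs(s, "present_Entity"), iri_local, ""),
        relationships = rels, xrefs = xrefs_of(s))
    }
  }

  # Diagnoses, stages, processes.
  diag_of <- function(s) {
    d <- diagnosis(iri_local(s), get_lit(s, "diagnosisLabel") %||% iri_local(s),
                   status = if (type_of[[s]] == "Final_Diagnosis") "established"
                            else "excluded",
                   support = vapply(get_objs(s, "hasSupportEvidence"), iri_local, ""),
                   contradict = vapply(get_objs(s, "hasContradictEvidence"),
                                       iri_local, ""))
    d$xrefs <- xrefs_of(s)
    d
  }
  processes <- list()
  for (s in subjects_of_class("DiagnosisProcess")) {
    stage_iris <- get_objs(s, "diagnosisOrder")
    idx <- vapply(stage_iris, function(si)
      as.integer(get_lit(si, "stageIndex") %||% "0"), 1L)
    stage_iris <- stage_iris[order(idx)]
    stages <- lapply(stage_iris, function(si) {
      diagnosis_stage(
        id = iri_local(si),
        index = as.integer(get_lit(si, "stageIndex") %||% "0"),
        possibilities = lapply(get_objs(si, "stepProcess"), diag_of),
        phenotypes = vapply(get_objs(si, "examinesPhenotype"), iri_local, ""))
    })
    pr <- build_diagnosis_process(stages, id = iri_local(s),
                                  item = get_lit(s, "diagnosisItem") %||% "")
    pr$xrefs <- xrefs_of(s)
    processes[[s]] <- pr
  }

  # Document individual and metadata.
  doc_subjects <- subjects_of_class(c("PathoDocument", "HE_Slide", "IHC_Slide",
                                      "Pathology_Report"))
  doc_id <- "document"
  slide_meta <- NULL
  provenance <- ""
  if (length(doc_subjects) > 0) {
    ds <- doc_subjects[1]
    doc_id <- iri_local(ds)
    provenance <- get_lit(ds, "provenance") %||% ""
    cls <- type_of[[ds]]
    if (cls != "PathoDocument") {
      slide_meta <- list(
        modality = switch(cls, HE_Slide = "HE", IHC_Slide = "IHC",
                          Pathology_Report = "report"))
      h <- get_lit(ds, "slideHeight"); w <- get_lit(ds, "slideWidth")
      mg <- get_lit(ds, "magnification"); ag <- get_lit(ds, "antigen")
      if (!is.null(h)) slide_meta$height <- as.integer(h)
      if (!is.null(w)) slide_meta$width <- as.integer(w)
      if (!is.null(mg)) slide_meta$magnification <- as.numeric(mg)
      if (!is.null(ag)) slide_meta$antigen <- ag
    }
  }

  patho_document(
    entity_graphs = unname(graphs[pg_sort(names(graphs))]),
    phenotypes = unname(phenos[pg_sort(names(phenos))]),
    indicators = unname(indicators[pg_sort(names(indicators))]),
    processes = unname(processes[pg_sort(names(processes))]),
    slide_meta = slide_meta, provenance = provenance, id = doc_id)
}

#' Parse a PathoML document
#'
#' Inverse of [write_pathoml()]: reads Turtle or RDF/XML text carrying
#' entity/phenotype/diagnosis graphs and reconstructs the in-memory document.
#' Reading the canonical output of [write_pathoml()] and writing it again is
#' byte-stable.
#'
#' @param text Ontology text, or a path to a file containing it.
#' @param binding A [pathoml_binding()]; its schema namespace identifies the
#'   PathoML terms.
#' @return A [patho_document()].
#' @export
read_pathoml <- function(text, binding = pathoml_binding()) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  triples_to_doc(pathoml_triples(text), binding)
}

#' Attach a controlled-vocabulary cross-reference to a node
#'
#' Records a `(vocabulary, code)` pair on any identifiable object of the
#' document — entity, feature, parameter, phenotype, indicator, diagnosis or
#' process — for serialization through `hasXref`. Attaching an identical xref
#' twice is a no-op.
#'
#' @param doc A [patho_document()].
#' @param node_id Id of the target object.
#' @param vocabulary,code Vocabulary name and code (e.g. `"HGNC"`, `"3430"`).
#' @return The modified document.
#' @export
attach_xref <- function(doc, node_id, vocabulary, code) {
  xr <- c(vocabulary, code)
  hit <- FALSE
  add <- function(obj) {
    if (!any(vapply(obj$xrefs, function(x) identical(unname(x), unname(xr)), TRUE))) {
      obj$xrefs <- c(obj$xrefs, list(xr))
    }
    hit <<- TRUE
    obj
  }
  for (gi in seq_along(doc$entity_graphs)) {
    g <- doc$entity_graphs[[gi]]
    if (g$root$id == node_id) doc$entity_graphs[[gi]]$root <- add(g$root)
    if (node_id %in% names(g$components)) {
      doc$entity_graphs[[gi]]$components[[node_id]] <- add(g$components[[node_id]])
    }
    if (node_id %in% names(g$features)) {
      doc$entity_graphs[[gi]]$features[[node_id]] <- add(g$features[[node_id]])
    }
    if (node_id %in% names(g$params)) {
      doc$entity_graphs[[gi]]$params[[node_id]] <- add(g$params[[node_id]])
    }
  }
  if (node_id %in% names(doc$phenotypes)) {
    doc$phenotypes[[node_id]] <- add(doc$phenotypes[[node_id]])
  }
  if (node_id %in% names(doc$indicators)) {
    doc$indicators[[node_id]] <- add(doc$indicators[[node_id]])
  }
  for (pi in seq_along(doc$processes)) {
    pr <- doc$processes[[pi]]
    if (pr$id == node_id) { doc$processes[[pi]] <- add(pr); next }
    for (si in seq_along(pr$stages)) {
      for (di in seq_along(pr$stages[[si]]$possibilities)) {
        d <- pr$stages[[si]]$possibilities[[di]]
        if (d$id == node_id) {
          doc$processes[[pi]]$stages[[si]]$possibilities[[di]] <- add(d)
        }
      }
    }
  }
  if (!hit) {
    pg_resolution_error(sprintf("no node with id '%s' in document", node_id),
                        ids = node_id)
  }
  doc
}

#' Test whether two documents serialize to the same graph
#'
#' Documents are compared as RDF triple sets (ids act as labels), which for
#' this profile coincides with graph isomorphism.
#'
#' @param a,b Two [patho_document()] objects.
#' @param binding A [pathoml_binding()].
#' @return Logical.
#' @export
doc_isomorphic <- function(a, b, binding = pathoml_binding()) {
  same_triples(doc_to_triples(a, binding), doc_to_triples(b, binding))
}
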