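#' Build a validated pathology entity graph
#'
#' Assembles a root entity, its components, pathological features and
#' quantitative parameters, together with the three relation sets, into a
#' single entity graph, and checks every structural invariant:
#'
#' * part-whole pairs relate the root or a component to a component;
#'   the part-whole relation is acyclic;
#' * feature links relate the root or a component to a feature of the graph;
#' * quantification links relate a feature to a parameter of the graph;
#' * express links pair a cellular-component node with a protein node;
#' * every component is connected to the root through part-whole or express
#'   edges (proteins enter the graph through `express`).
#'
#' @param root [entity_node()] — the entity the graph describes.
#' @param components List of [entity_node()] components.
#' @param features List of [feature_node()] objects.
#' @param params List of [quant_param()] objects.
#' @param part_whole,feature_links,quant_links,express_links Relation sets as
#'   two-column (from, to) data frames, matrices, or lists of id pairs.
#' @param id Graph identifier; defaults to `"EG-<root id>"`.
#' @return An object of class `pg_entity_graph`.
#' @examples
#' cell <- entity_node("Cell1", "NeoplasticCell")
#' mem  <- entity_node("Membrane1", "NeoplasticCellularComponent")
#' g <- build_entity_graph(cell, components = list(mem),
#'                         part_whole = list(c("Cell1", "Membrane1")))
#' @export
build_entity_graph <- function(root, components = list(), features = list(),
                               params = list(), part_whole = NULL,
                               feature_links = NULL, quant_links = NULL,
                               express_links = NULL, id = NULL) {
  stopifnot(inherits(root, "pg_entity"))
  g <- structure(list(
    id = id %||% paste0("EG-", root$id),
    root = root,
    components = stats::setNames(components,
                                 vapply(components, function(x) x$id, "")),
    features = stats::setNames(features,
                               vapply(features, function(x) x$id, "")),
    params = stats::setNames(params, vapply(params, function(x) x$id, "")),
    part_whole = as_pg_pairs(part_whole),
    feature_links = as_pg_pairs(feature_links),
    quant_links = as_pg_pairs(quant_links),
    express_links = as_pg_pairs(express_links)
  ), class = "pg_entity_graph")

  # Implicit links: features bound to owners and params to features by their
  # own fields are added to the relation sets when missing.
  for (f in g$features) {
    have <- any(g$feature_links$from == f$owner_id & g$feature_links$to == f$id)
    if (!have) g$feature_links <- rbind(g$feature_links,
                                        pg_pairs(f$owner_id, f$id))
  }
  for (q in g$params) {
    have <- any(g$quant_links$from == q$feature_id & g$quant_links$to == q$id)
    if (!have) g$quant_links <- rbind(g$quant_links,
                                      pg_pairs(q$feature_id, q$id))
  }

  v <- validate_entity_graph(g)
  if (nrow(v) > 0) {
    dangling <- v[v$clause == "resolution", , drop = FALSE]
    cyc <- v[v$clause == "part_whole_acyclic", , drop = FALSE]
    if (nrow(cyc) > 0) pg_cycle_error(cyc$message[1])
    if (nrow(dangling) > 0) {
      pg_resolution_error(paste(dangling$message, collapse = "; "),
                          ids = dangling$id)
    }
    pg_stop("pg_validation_error", paste(v$message, collapse = "; "))
  }
  g
}

# Detect a cycle in a pair set; returns NULL or the node sequence of one cycle.
find_cycle <- function(pairs) {
  if (nrow(pairs) == 0) return(NULL)
  adj <- split(pairs$to, pairs$from)
  color <- new.env(parent = emptyenv())
  stack <- character()
  found <- NULL
  visit <- function(u) {
    if (!is.null(found)) return()
    assign(u, 1L, envir = color)
    stack <<- c(stack, u)
    for (w in adj[[u]] %||% character()) {
      st <- if (exists(w, envir = color)) get(w, envir = color) else 0L
      if (st == 1L) {
        i <- match(w, stack)
        found <<- c(stack[i:length(stack)], w)
        return()
      }
      if (st == 0L) visit(w)
      if (!is.null(found)) return()
    }
    assign(u, 2L, envir = color)
    stack <<- stack[-length(stack)]
  }
  for (u in unique(pairs$from)) {
    st <- if (exists(u, envir = color)) get(u, envir = color) else 0L
    if (st == 0L) visit(u)
    if (!is.null(found)) break
  }
  found
}

# Nodes reachable from `start` over undirected use of the pair sets.
reachable_from <- function(start, ...) {
  pairs <- do.call(rbind, lapply(list(...), as_pg_pairs))
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(c(pairs$to[pairs$from %in% frontier],
                    pairs$from[pairs$to %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Expand a phenotype with the entity graphs of its entities
#'
#' Replaces each constituent entity of a phenotype by that entity's full graph
#' representation, enriching the phenotype with the entities' components,
#' features and quantitative parameters. The input phenotype is not modified;
#' expansion is idempotent for a fixed graph map.
#'
#' @param p A [phenotype()].
#' @param graphs Named list (or list) of `pg_entity_graph` objects; each entity
#'   id of `p` must resolve to a graph whose root is that entity.
#' @return A copy of `p` with `entity_graphs` populated.
#' @export
expand_phenotype <- function(p, graphs) {
  stopifnot(inherits(p, "pg_phenotype"))
  roots <- vapply(graphs, function(g) g$root$id, "")
  out <- p
  for (eid in p$entities) {
    if (!is.null(out$entity_graphs[[eid]])) next  # already expanded
    i <- match(eid, roots)
    if (is.na(i)) {
      pg_resolution_error(
        sprintf("no entity graph with root '%s' available for expansion", eid),
        ids = eid)
    }
    out$entity_graphs[[eid]] <- graphs[[i]]
  }
  out
}

# Total node count of an entity graph (root + components + features + params).
entity_graph_size <- function(g) {
  1L + length(g$components) + length(g$features) + length(g$params)
}

# Node count of an expanded phenotype: the phenotype node plus its expansion
# graphs (unexpanded entities count as single nodes).
phenotype_size <- function(p) {
  n <- 1L
  for (eid in p$entities) {
    g <- p$entity_graphs[[eid]]
    n <- n + if (is.null(g)) 1L else entity_graph_size(g)
  }
  n
}
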