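# Automated entity-graph construction from segmentation geometry: parse a
# GeoJSON scene, assign nuclei to tumor regions by polygon overlap, and
# assemble one entity graph per tumor with per-nucleus morphometrics.

scene_labels <- c("tumor", "neoplastic_nucleus", "non_neoplastic_nucleus")

#' Load a segmentation scene from GeoJSON
#'
#' Parses a FeatureCollection of Polygon features. Each feature must carry a
#' `properties.class` of `"tumor"`, `"neoplastic_nucleus"` or
#' `"non_neoplastic_nucleus"`. Coordinates are 0-based pixels in image
#' convention (y increases downward; GeoJSON itself is axis-agnostic here).
#' Bounding boxes and centroids are computed when absent. Image width/height
#' are taken from top-level `properties` or, failing that, from the geometry
#' extent.
#'
#' @param geojson_text GeoJSON text or path to a `.geojson` file.
#' @return Object of class `pg_scene`: list with `width`, `height`,
#'   `regions` (id, label, outline, bbox), `nuclei` (id, label, outline,
#'   bbox, centroid).
#' @export
load_scene <- function(geojson_text) {
  if (length(geojson_text) == 1 && !grepl("[{\n]", geojson_text) &&
      file.exists(geojson_text)) {
    geojson_text <- paste(readLines(geojson_text, warn = FALSE), collapse = "\n")
  }
  gj <- jsonlite::fromJSON(geojson_text, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    pg_stop("pg_parse_error", "not a GeoJSON FeatureCollection")
  }
  regions <- list(); nuclei <- list()
  feats <- gj$features %||% list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    cls <- f$properties$class
    if (is.null(cls)) {
      pg_stop("pg_parse_error",
              sprintf("feature %d lacks properties.class", i))
    }
    if (!cls %in% scene_labels) {
      pg_stop("pg_parse_error",
              sprintf("feature %d: unknown class '%s'", i, cls))
    }
    if (!identical(f$geometry$type, "Polygon")) {
      pg_stop("pg_parse_error",
              sprintf("feature %d: geometry must be Polygon, got %s",
                      i, f$geometry$type %||% "none"))
    }
    ring <- f$geometry$coordinates[[1]]
    outline <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    outline <- as_outline(outline)
    id <- f$properties$id %||% sprintf("feature-%d", i)
    bbox <- c(min(outline[, 1]), min(outline[, 2]),
              max(outline[, 1]), max(outline[, 2]))
    if (cls == "tumor") {
      regions[[length(regions) + 1]] <-
        list(id = id, label = "tumor", outline = outline, bbox = bbox)
    } else {
      nuclei[[length(nuclei) + 1]] <-
        list(id = id,
             label = if (cls == "neoplastic_nucleus") "neoplastic"
                     else "non_neoplastic",
             outline = outline, bbox = bbox,
             centroid = polygon_centroid(outline))
    }
  }
  width <- gj$properties$width %||% NULL
  height <- gj$properties$height %||% NULL
  all_out <- c(lapply(regions, `[[`, "outline"), lapply(nuclei, `[[`, "outline"))
  if (is.null(width)) {
    width <- if (length(all_out)) ceiling(max(vapply(all_out, function(o) max(o[, 1]), 0))) + 1 else 0
  }
  if (is.null(height)) {
    height <- if (length(all_out)) ceiling(max(vapply(all_out, function(o) max(o[, 2]), 0))) + 1 else 0
  }
  for (o in all_out) {
    if (any(o[, 1] < 0 | o[, 2] < 0 | o[, 1] >= width + 1e-9 | o[, 2] >= height + 1e-9)) {
      pg_stop("pg_parse_error", "feature coordinates out of image bounds")
    }
  }
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 regions = regions, nuclei = nuclei),
            class = "pg_scene")
}

#' @export
print.pg_scene <- function(x, ...) {
  neo <- sum(vapply(x$nuclei, function(n) n$label == "neoplastic", TRUE))
  cat("<segmentation scene>", x$width, "x", x$height, "px\n",
      " tumor regions:", length(x$regions),
      " nuclei:", length(x$nuclei), sprintf("(%d neoplastic)", neo), "\n")
  invisible(x)
}

#' Assign neoplastic nuclei to tumor regions by spatial overlap
#'
#' Each neoplastic nucleus is assigned to the tumor region with the maximal
#' overlap fraction (intersection area over nucleus area), provided that
#' fraction reaches `threshold`; ties break toward the lexicographically
#' smaller tumor id. Non-neoplastic nuclei are never assigned.
#'
#' @param scene A [load_scene()] result.
#' @param threshold Minimum overlap fraction of the nucleus area
#'   (default 0.5).
#' @return Object of class `pg_assignment`: data frame with columns
#'   `nucleus_id`, `tumor_id` (`NA` when unassigned), `overlap`.
#' @export
assign_parts <- function(scene, threshold = 0.5) {
  rows <- list()
  for (nu in scene$nuclei) {
    if (nu$label != "neoplastic") next
    best_id <- NA_character_; best_ov <- 0
    for (rg in scene$regions) {
      # Cheap reject on bounding boxes before polygon clipping.
      if (nu$bbox[3] < rg$bbox[1] || nu$bbox[1] > rg$bbox[3] ||
          nu$bbox[4] < rg$bbox[2] || nu$bbox[2] > rg$bbox[4]) next
      ov <- overlap_fraction(nu$outline, rg$outline)
      better <- ov > best_ov + 1e-12 ||
        (abs(ov - best_ov) <= 1e-12 && !is.na(best_id) && rg$id < best_id)
      if (is.na(best_id) || better) { best_id <- rg$id; best_ov <- ov }
    }
    if (is.na(best_id) || best_ov < threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        nucleus_id = nu$id, tumor_id = NA_character_, overlap = best_ov,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        nucleus_id = nu$id, tumor_id = best_id, overlap = best_ov,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(nucleus_id = character(), tumor_id = character(),
               overlap = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  class(out) <- c("pg_assignment", class(out))
  out
}

#' Build one entity graph per tumor region
#'
#' For every tumor region of the scene, assembles an entity graph whose root
#' is the tumor and whose components are the neoplastic nuclei assigned to it
#' (one `NeoplasticCell` node per nucleus, carrying its outline and bounding
#' box), with a part-whole edge per assignment and the five-descriptor
#' morphometric bundle ([feature_bundle()]) per nucleus.
#'
#' @param scene A [load_scene()] result.
#' @param assignment An [assign_parts()] result (computed when `NULL`).
#' @return List of `pg_entity_graph`, one per tumor region, in region order.
#' @export
build_pegs <- function(scene, assignment = NULL) {
  assignment <- assignment %||% assign_parts(scene)
  known <- c(vapply(scene$nuclei, `[[`, "", "id"),
             vapply(scene$regions, `[[`, "", "id"))
  bad <- setdiff(c(assignment$nucleus_id,
                   assignment$tumor_id[!is.na(assignment$tumor_id)]), known)
  if (length(bad) > 0) {
    pg_resolution_error(sprintf("assignment references unknown ids: %s",
                                paste(bad, collapse = ", ")), ids = bad)
  }
  nuclei_by_id <- stats::setNames(scene$nuclei,
                                  vapply(scene$nuclei, `[[`, "", "id"))
  pegs <- list()
  for (rg in scene$regions) {
    root <- entity_node(rg$id, "Tumor", outline = rg$outline, bbox = rg$bbox)
    nuc_ids <- assignment$nucleus_id[!is.na(assignment$tumor_id) &
                                       assignment$tumor_id == rg$id]
    comps <- list(); feats <- list(); pars <- list()
    pw <- pg_pairs()
    for (nid in nuc_ids) {
      nu <- nuclei_by_id[[nid]]
      comps[[length(comps) + 1]] <- entity_node(nid, "NeoplasticCell",
                                                outline = nu$outline,
                                                bbox = nu$bbox)
      fb <- feature_bundle(nu$outline, owner_id = nid)
      feats <- c(feats, fb$features)
      pars <- c(pars, fb$params)
      pw <- rbind(pw, pg_pairs(rg$id, nid))
    }
    pegs[[length(pegs) + 1]] <- build_entity_graph(
      root, components = comps, features = feats, params = pars,
      part_whole = pw, id = paste0("PEG-", rg$id))
  }
  pegs
}

#' Export entity graphs as GraphML for downstream graph learning
#'
#' Flattens a list of entity graphs into one attributed graph: vertices for
#' every entity, feature and parameter node (attributes: `kind`, `class`,
#' `label`, `value`, `bbox`), edges typed by relation
#' (`hasComponent`, `express`, `hasAttribute`, `quantification`), written
#' with a generic GraphML writer.
#'
#' @param pegs List of `pg_entity_graph`.
#' @param file Output path.
#' @return The igraph object, invisibly.
#' @export
export_for_ml <- function(pegs, file) {
  vname <- character(); vkind <- character(); vclass <- character()
  vlabel <- character(); vvalue <- numeric(); vbbox <- character()
  efrom <- character(); eto <- character(); etype <- character()
  for (g in pegs) {
    for (e in c(list(g$root), g$components)) {
      vname <- c(vname, e$id); vkind <- c(vkind, "entity")
      vclass <- c(vclass, e$entity_class); vlabel <- c(vlabel, e$display_name)
      vvalue <- c(vvalue, NA_real_)
      vbbox <- c(vbbox, if (is.null(e$bbox)) "" else bbox_to_text(e$bbox))
    }
    for (f in g$features) {
      vname <- c(vname, f$id); vkind <- c(vkind, "feature")
      vclass <- c(vclass, "EntityAttribute"); vlabel <- c(vlabel, f$feature_name)
      vvalue <- c(vvalue, NA_real_); vbbox <- c(vbbox, "")
    }
    for (q in g$params) {
      vname <- c(vname, q$id); vkind <- c(vkind, "param")
      vclass <- c(vclass, "Quantification"); vlabel <- c(vlabel, q$param_name)
      vvalue <- c(vvalue, q$value); vbbox <- c(vbbox, "")
    }
    add_edges <- function(pairs, type) {
      efrom <<- c(efrom, pairs$from); eto <<- c(eto, pairs$to)
      etype <<- c(etype, rep(type, nrow(pairs)))
    }
    add_edges(g$part_whole, "hasComponent")
    add_edges(g$express_links, "express")
    add_edges(g$feature_links, "hasAttribute")
    add_edges(g$quant_links, "quantification")
  }
  vertices <- data.frame(name = vname, kind = vkind, class = vclass,
                         label = vlabel, value = vvalue, bbox = vbbox,
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = efrom, to = eto, type = etype,
                      stringsAsFactors = FALSE)
  gr <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = vertices)
  igraph::write_graph(gr, file, format = "graphml")
  invisible(gr)
}
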