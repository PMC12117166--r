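# Shared generators for property-style tests. Everything is seeded by the
# caller; no fixture files on disk.

# Random simple (convex) polygon: hull of uniform points in a disc.
random_polygon <- function(n_pts = 12, cx = 0, cy = 0, r = 10) {
  pts <- cbind(cx + stats::runif(n_pts, -r, r), cy + stats::runif(n_pts, -r, r))
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

rotate_polygon <- function(outline, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  outline %*% t(R)
}

# Random entity graph: a part-whole tree under a Tumor root with features and
# parameters on random nodes, plus an optional membrane/protein express pair.
random_entity_graph <- function(tag, n_components = sample(0:5, 1)) {
  root <- entity_node(paste0(tag, "-root"), "Tumor")
  comps <- list(); pw <- pg_pairs(); feats <- list(); pars <- list()
  ids <- root$id
  for (i in seq_len(n_components)) {
    id <- sprintf("%s-c%d", tag, i)
    comps[[i]] <- entity_node(id, sample(c("NeoplasticCell", "Stroma",
                                           "Parenchyma", "Substance"), 1))
    pw <- rbind(pw, pg_pairs(sample(ids, 1), id))
    ids <- c(ids, id)
    if (stats::runif(1) < 0.5) {
      fid <- sprintf("%s-f%d", tag, i)
      feats[[length(feats) + 1]] <- feature_node(fid, "nuclear shape", id)
      pars[[length(pars) + 1]] <- quant_param(sprintf("%s-q%d", tag, i),
                                              "roundness",
                                              stats::runif(1), feature_id = fid)
    }
  }
  if (n_components > 0 && stats::runif(1) < 0.4) {
    mem <- entity_node(sprintf("%s-mem", tag), "NeoplasticCellularComponent")
    prot <- entity_node(sprintf("%s-prot", tag), "Protein")
    comps <- c(comps, list(mem, prot))
    pw <- rbind(pw, pg_pairs(sample(ids, 1), mem$id))
    return(build_entity_graph(root, comps, feats, pars, part_whole = pw,
                              express_links = pg_pairs(mem$id, prot$id)))
  }
  build_entity_graph(root, comps, feats, pars, part_whole = pw)
}

# Random document mixing entity graphs, phenotypes, an indicator and a
# two-stage process referencing the phenotypes.
random_document <- function(seed) {
  set.seed(seed)
  tag <- sprintf("d%d", seed)
  graphs <- lapply(seq_len(sample(2:3, 1)),
                   function(i) random_entity_graph(sprintf("%s-g%d", tag, i)))
  roots <- vapply(graphs, function(g) g$root$id, "")
  phenos <- list(
    phenotype(paste0(tag, "-p1"), "multi_cell", "Histopathological_Phenotype",
              label = "glandular pattern", entities = roots))
  if (stats::runif(1) < 0.6) {
    cellg <- build_entity_graph(entity_node(paste0(tag, "-cell"), "NeoplasticCell"))
    graphs <- c(graphs, list(cellg))
    phenos <- c(phenos, list(
      phenotype(paste0(tag, "-p2"), "single_cell", "Cytopathological_Phenotype",
                label = "apoptotic body", entities = cellg$root$id)))
  }
  indicators <- list()
  if (stats::runif(1) < 0.5) {
    indicators <- list(quant_indicator(
      paste0(tag, "-qi"), "mitotic count",
      params = list(quant_param(paste0(tag, "-qi-n"), "n_mitoses",
                                sample(1:30, 1), feature_id = "")),
      value = stats::runif(1)))
  }
  pids <- vapply(phenos, function(p) p$id, "")
  d1 <- diagnosis(paste0(tag, "-dx1"), "carcinoma", "established",
                  support = pids[1])
  d2 <- diagnosis(paste0(tag, "-dx2"), "benign lesion", "excluded",
                  contradict = pids[1])
  proc <- build_diagnosis_process(
    list(diagnosis_stage(paste0(tag, "-s1"), 1, list(d1, d2),
                         phenotypes = pids)),
    id = paste0(tag, "-proc"))
  patho_document(entity_graphs = graphs, phenotypes = phenos,
                 indicators = indicators, processes = list(proc),
                 slide_meta = list(modality = "HE", height = 512L,
                                   width = 512L, magnification = 20),
                 id = paste0(tag, "-doc"))
}

# Minimal GeoJSON scene builder for hand-constructed geometry cases.
manual_scene_json <- function(features, width = 200, height = 200) {
  feat <- lapply(features, function(f) {
    ring <- lapply(seq_len(nrow(f$outline)),
                   function(i) c(f$outline[i, 1], f$outline[i, 2]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(id = f$id, class = f$class),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  as.character(jsonlite::toJSON(
    list(type = "FeatureCollection",
         properties = list(width = width, height = height),
         features = feat),
    auto_unbox = TRUE, digits = NA))
}

rect_outline <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
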