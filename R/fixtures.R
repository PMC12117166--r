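# Deterministic generators for every input the tests and use cases need:
# segmentation scenes with known ground truth, IHC cohorts with prescribed
# staining distributions, and the worked exemplar documents.

#' Generate a synthetic segmentation scene
#'
#' Emulates the output of a tumor/nucleus segmentation stage: tumor regions
#' as random convex blobs on a non-overlapping grid layout, per-tumor nuclei
#' as small irregular polygons placed strictly inside their tumor, and stray
#' nuclei placed outside all tumors. The ground-truth assignment records which
#' tumor each nucleus was generated in. Identical spec + seed yields
#' byte-identical GeoJSON.
#'
#' @param n_tumors Number of tumor regions.
#' @param nuclei_per_tumor Neoplastic nuclei generated inside each tumor.
#' @param n_stray_nuclei Nuclei placed outside all tumors (alternating
#'   neoplastic / non-neoplastic labels).
#' @param size Image side length in px.
#' @param seed Integer seed.
#' @return List with `geojson` (text), `truth` (data frame `nucleus_id`,
#'   `tumor_id`), and `scene` (the parsed [load_scene()] object).
#' @export
make_scene <- function(n_tumors = 2, nuclei_per_tumor = 5, n_stray_nuclei = 3,
                       size = 1024, seed = 1) {
  stopifnot(n_tumors >= 0, nuclei_per_tumor >= 0, n_stray_nuclei >= 0)
  with_local_seed(seed, {
    features <- list()
    truth <- list()
    # Tumors on a grid: disjoint by construction.
    ncell <- max(1, ceiling(sqrt(max(n_tumors, 1))))
    cell <- size / ncell
    tumor_outlines <- list()
    for (t in seq_len(n_tumors)) {
      row <- (t - 1) %/% ncell; col <- (t - 1) %% ncell
      cx <- (col + 0.5) * cell; cy <- (row + 0.5) * cell
      r <- 0.32 * cell
      pts <- cbind(cx + stats::runif(24, -r, r), cy + stats::runif(24, -r, r))
      hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
      hull <- round(hull, 2)
      tid <- sprintf("tumor-%d", t)
      tumor_outlines[[tid]] <- hull
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(id = tid, class = "tumor"),
        geometry = list(type = "Polygon",
                        coordinates = list(outline_to_ring(hull))))
    }
    nucleus_polygon <- function(cx, cy) {
      rr <- stats::runif(10, 4, 7)
      th <- 2 * pi * (seq_len(10) - 1) / 10
      round(cbind(cx + rr * cos(th), cy + rr * sin(th)), 2)
    }
    # Minimum clearance from the tumor boundary so nuclei are strictly inside.
    margin <- 8
    k <- 0
    for (tid in names(tumor_outlines)) {
      hull <- tumor_outlines[[tid]]
      bb <- c(min(hull[, 1]), min(hull[, 2]), max(hull[, 1]), max(hull[, 2]))
      for (j in seq_len(nuclei_per_tumor)) {
        placed <- FALSE
        for (try in 1:200) {
          px <- stats::runif(1, bb[1], bb[3]); py <- stats::runif(1, bb[2], bb[4])
          if (!point_in_polygon(px, py, hull)) next
          if (distance_to_boundary(px, py, hull) < margin) next
          k <- k + 1
          nid <- sprintf("nucleus-%d", k)
          features[[length(features) + 1]] <- list(
            type = "Feature",
            properties = list(id = nid, class = "neoplastic_nucleus"),
            geometry = list(type = "Polygon",
                            coordinates = list(outline_to_ring(nucleus_polygon(px, py)))))
          truth[[length(truth) + 1]] <- data.frame(
            nucleus_id = nid, tumor_id = tid, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          pg_stop("pg_packing_error",
                  sprintf("could not place nucleus inside %s after 200 tries", tid))
        }
      }
    }
    for (j in seq_len(n_stray_nuclei)) {
      placed <- FALSE
      for (try in 1:500) {
        px <- stats::runif(1, 10, size - 10); py <- stats::runif(1, 10, size - 10)
        clear <- TRUE
        for (hull in tumor_outlines) {
          if (point_in_polygon(px, py, hull) ||
              distance_to_boundary(px, py, hull) < 10) { clear <- FALSE; break }
        }
        if (!clear) next
        k <- k + 1
        nid <- sprintf("nucleus-%d", k)
        cls <- if (j %% 2 == 1) "neoplastic_nucleus" else "non_neoplastic_nucleus"
        features[[length(features) + 1]] <- list(
          type = "Feature",
          properties = list(id = nid, class = cls),
          geometry = list(type = "Polygon",
                          coordinates = list(outline_to_ring(nucleus_polygon(px, py)))))
        if (cls == "neoplastic_nucleus") {
          truth[[length(truth) + 1]] <- data.frame(
            nucleus_id = nid, tumor_id = NA_character_, stringsAsFactors = FALSE)
        }
        placed <- TRUE
        break
      }
      if (!placed) pg_stop("pg_packing_error", "could not place stray nucleus")
    }
    gj <- list(type = "FeatureCollection",
               properties = list(width = size, height = size),
               features = features)
    txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
    truth_df <- if (length(truth) == 0) {
      data.frame(nucleus_id = character(), tumor_id = character(),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, truth)
    list(geojson = as.character(txt), truth = truth_df,
         scene = load_scene(as.character(txt)))
  })
}

outline_to_ring <- function(outline) {
  ring <- lapply(seq_len(nrow(outline)), function(i) c(outline[i, 1], outline[i, 2]))
  c(ring, ring[1])  # GeoJSON rings close explicitly
}

distance_to_boundary <- function(px, py, outline) {
  o <- as_outline(outline)
  n <- nrow(o)
  dmin <- Inf
  for (i in seq_len(n)) {
    a <- o[i, ]; b <- o[(i %% n) + 1, ]
    ab <- b - a
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / sum(ab^2)
    t <- min(1, max(0, t))
    d <- sqrt((px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2)
    dmin <- min(dmin, d)
  }
  dmin
}

# Largest-remainder apportionment of n among fractions; sums to n exactly.
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Generate a synthetic IHC cohort document
#'
#' Builds one single-cell immunophenotype per tumor cell, each with a membrane
#' component expressing the antigen and a staining-extent parameter drawn
#' uniformly within the cell's assigned bin. Bin counts are the
#' largest-remainder rounding of `fractions * n_cells`.
#'
#' @param fractions Length-4 numeric: target fractions for the complete
#'   `[0.9, 1]`, moderate `[0.7, 0.9)`, incomplete `[0.5, 0.7)` and unstained
#'   `[0, 0.5)` bins; must sum to 1.
#' @param n_cells Number of tumor cells.
#' @param seed Integer seed.
#' @param antigen Antigen label recorded in the slide metadata.
#' @return A [patho_document()]; the realized per-cell values are in
#'   `attr(, "values")` and bin counts in `attr(, "counts")`.
#' @export
make_cohort <- function(fractions = c(0.75, 0.15, 0.05, 0.05), n_cells = 20,
                        seed = 1, antigen = "HER2") {
  stopifnot(length(fractions) == 4, abs(sum(fractions) - 1) < 1e-9)
  counts <- apportion(fractions, n_cells)
  bins <- her2_bins()
  with_local_seed(seed, {
    values <- numeric(0)
    for (bi in 1:4) {
      if (counts[bi] == 0) next
      lo <- bins$lower[bi]
      hi <- bins$upper[bi] - if (bi == 1) 0 else 1e-6
      values <- c(values, stats::runif(counts[bi], lo, hi))
    }
    graphs <- list(); phenos <- list()
    for (i in seq_along(values)) {
      cell <- entity_node(sprintf("Cell%d", i), "NeoplasticCell")
      mem <- entity_node(sprintf("Membrane%d", i), "NeoplasticCellularComponent",
                         display_name = sprintf("Membrane%d", i))
      nuc <- entity_node(sprintf("Nucleus%d", i), "NeoplasticCellularComponent")
      prot <- entity_node(sprintf("%s-%d", antigen, i), "Protein",
                          display_name = antigen)
      feat <- feature_node(sprintf("StainingExtent%d", i), "staining extent",
                           owner_id = mem$id)
      par <- quant_param(sprintf("Quantification%d", i),
                         "staining completeness", values[i],
                         feature_id = feat$id)
      graphs[[i]] <- build_entity_graph(
        cell, components = list(mem, nuc, prot),
        features = list(feat), params = list(par),
        part_whole = pg_pairs(c(cell$id, cell$id), c(mem$id, nuc$id)),
        express_links = pg_pairs(mem$id, prot$id))
      phenos[[i]] <- phenotype(sprintf("Phenotype%d", i), "single_cell",
                               "Immunophenotype",
                               label = sprintf("%s immunophenotype", antigen),
                               entities = cell$id)
    }
    doc <- patho_document(
      entity_graphs = graphs, phenotypes = phenos,
      slide_meta = list(modality = "IHC", height = 1024L, width = 1024L,
                        magnification = 40, antigen = antigen),
      provenance = sprintf("synthetic cohort (n=%d, seed=%d)", n_cells, seed),
      id = "cohort")
    attr(doc, "values") <- values
    attr(doc, "counts") <- stats::setNames(counts, bins$bin)
    doc
  })
}

#' Worked exemplar documents
#'
#' Reconstructions of the package's reference examples: a HER2 single-cell
#' immunophenotype (`"her2_fig4"`), a back-to-back follicular pattern of
#' papillary thyroid carcinoma (`"follicle_fig5"`), a three-stage cervical
#' subtyping process ending in HPV-associated adenocarcinoma, usual type,
#' with a 40% intracytoplasmic-mucin indicator (`"cervical_fig6"`), a
#' lymphoma differential with three possibilities at its terminal stage
#' (`"lymphoma_fig7"`), and the cervical slide carrying three phenotypes used
#' by the subtyping reasoner (`"cervical_slide_fig11"`). Only the features the
#' examples state are encoded; unstated details are fixed minimally.
#'
#' @param name One of `"her2_fig4"`, `"follicle_fig5"`, `"cervical_fig6"`,
#'   `"lymphoma_fig7"`, `"cervical_slide_fig11"`.
#' @return A [patho_document()] that validates cleanly.
#' @export
exemplar_document <- function(name = c("her2_fig4", "follicle_fig5",
                                       "cervical_fig6", "lymphoma_fig7",
                                       "cervical_slide_fig11")) {
  name <- match.arg(name)
  switch(name,
    her2_fig4 = exemplar_her2(),
    follicle_fig5 = exemplar_follicle(),
    cervical_fig6 = exemplar_cervical_process(),
    lymphoma_fig7 = exemplar_lymphoma(),
    cervical_slide_fig11 = exemplar_cervical_slide())
}

# Single HER2-stained tumor cell: membrane 75% stained.
exemplar_her2 <- function() {
  cell <- entity_node("Cell1", "NeoplasticCell")
  mem <- entity_node("Membrane1", "NeoplasticCellularComponent")
  nuc <- entity_node("Nucleus1", "NeoplasticCellularComponent")
  her2 <- entity_node("HER2", "Protein")
  feat <- feature_node("Medium", "staining extent", owner_id = "Membrane1")
  par <- quant_param("Quantification1", "staining completeness", 0.75,
                     feature_id = "Medium")
  g <- build_entity_graph(cell, components = list(mem, nuc, her2),
                          features = list(feat), params = list(par),
                          part_whole = pg_pairs(c("Cell1", "Cell1"),
                                                c("Membrane1", "Nucleus1")),
                          express_links = pg_pairs("Membrane1", "HER2"))
  p <- phenotype("Phenotype1", "single_cell", "Immunophenotype",
                 label = "HER2 immunophenotype", entities = "Cell1")
  patho_document(entity_graphs = list(g), phenotypes = list(p),
                 slide_meta = list(modality = "IHC", height = 1024L,
                                   width = 1024L, magnification = 40,
                                   antigen = "HER2"),
                 id = "her2-exemplar")
}

# Two thyroid-carcinoma follicles in back-to-back arrangement.
exemplar_follicle <- function() {
  follicle <- function(k) {
    tum <- entity_node(sprintf("Tumor%d", k), "Tumor")
    par <- entity_node(sprintf("Parenchyma%d", k), "Parenchyma")
    st <- entity_node(sprintf("Stroma%d", k), "Stroma")
    sub <- entity_node(sprintf("Substance%d", k), "Substance",
                       display_name = "colloid")
    cells <- entity_node(sprintf("NeoplasticCell%d", k), "NeoplasticCell")
    build_entity_graph(tum, components = list(par, st, sub, cells),
      part_whole = pg_pairs(
        c(tum$id, tum$id, tum$id, par$id),
        c(par$id, st$id, sub$id, cells$id)))
  }
  g1 <- follicle(1); g2 <- follicle(2)
  rel <- relationship_edge("Relationship1", "back-to-back arrangement",
                           "spatial", subjects = "Tumor1", objects = "Tumor2")
  p <- phenotype("Phenotype2", "multi_cell", "Histopathological_Phenotype",
                 label = "follicular pattern",
                 entities = c("Tumor1", "Tumor2"),
                 relationships = list(rel))
  patho_document(entity_graphs = list(g1, g2), phenotypes = list(p),
                 slide_meta = list(modality = "HE", height = 1024L,
                                   width = 1024L, magnification = 20),
                 id = "follicle-exemplar")
}

# Shared cervical diagnostic phenotypes.
cervical_phenotypes <- function() {
  gl1 <- entity_node("Gland1", "Tumor", display_name = "glandular structure")
  gl2 <- entity_node("Gland2", "Tumor", display_name = "glandular structure")
  ab_cell <- entity_node("ApoptoticCell1", "Cell",
                         display_name = "cell with apoptotic body")
  mit_cell <- entity_node("MitoticCell1", "NeoplasticCell",
                          display_name = "cell in luminal mitosis")
  list(
    graphs = list(build_entity_graph(gl1), build_entity_graph(gl2),
                  build_entity_graph(ab_cell), build_entity_graph(mit_cell)),
    phenos = list(
      phenotype("GlandularPattern", "multi_cell", "Histopathological_Phenotype",
                label = "glandular pattern", entities = c("Gland1", "Gland2")),
      phenotype("ApoptoticBody", "single_cell", "Cytopathological_Phenotype",
                label = "apoptotic body", entities = "ApoptoticCell1"),
      phenotype("LuminalMitosis", "single_cell", "Cytopathological_Phenotype",
                label = "luminal mitosis", entities = "MitoticCell1")))
}

# Three-stage cervical subtyping process; terminal stage carries the 40%
# intracytoplasmic-mucin quantitative indicator.
exemplar_cervical_process <- function() {
  cp <- cervical_phenotypes()
  mucin <- quant_indicator(
    "MucinIndicator",
    name = "proportion of tumor cells with intracytoplasmic mucin",
    params = list(
      quant_param("MucinCellCount", "mucin_cell_count", 40, feature_id = ""),
      quant_param("TumorCellCount", "tumor_cell_count", 100, feature_id = "")),
    value = 0.40,
    formula = mathml_ratio("mucin_cell_count", "tumor_cell_count"))
  d1 <- diagnosis("Diagnosis1", "adenocarcinoma", "established",
                  support = "GlandularPattern")
  d2 <- diagnosis("Diagnosis2", "HPVA", "established",
                  support = c("ApoptoticBody", "LuminalMitosis"))
  d3 <- diagnosis("Diagnosis3", "HPVA, usual type", "established",
                  support = "MucinIndicator")
  proc <- build_diagnosis_process(list(
    diagnosis_stage("Stage1", 1, list(d1), phenotypes = "GlandularPattern"),
    diagnosis_stage("Stage2", 2, list(d2),
                    phenotypes = c("ApoptoticBody", "LuminalMitosis")),
    diagnosis_stage("Stage3", 3, list(d3), phenotypes = "MucinIndicator")),
    id = "Process1", item = "histologic type")
  patho_document(entity_graphs = cp$graphs, phenotypes = cp$phenos,
                 indicators = list(mucin), processes = list(proc),
                 slide_meta = list(modality = "report"),
                 id = "cervical-process-exemplar")
}

# Lymphoma differential: HE stage, then three subtypes separated by IHC.
exemplar_lymphoma <- function() {
  lymph_cell <- entity_node("AtypicalLymphoid1", "NeoplasticCell",
                            display_name = "atypical lymphoid cell")
  he_pheno <- phenotype("AtypicalLymphoidProliferation", "multi_cell",
                        "Histopathological_Phenotype",
                        label = "atypical lymphoid proliferation",
                        entities = "AtypicalLymphoid1",
                        relationships = list(
                          relationship_edge("Relationship2", "diffuse infiltration",
                                            "behavioral",
                                            subjects = "AtypicalLymphoid1",
                                            objects = "Node1")))
  node <- entity_node("Node1", "Tissue", display_name = "lymph node tissue")
  ihc <- function(id, marker) {
    cell_id <- paste0(marker, "Cell")
    list(graph = build_entity_graph(
           entity_node(cell_id, "NeoplasticCell",
                       display_name = sprintf("%s-positive tumor cell", marker))),
         pheno = phenotype(id, "single_cell", "Immunophenotype",
                           label = sprintf("%s positive", marker),
                           entities = cell_id))
  }
  lca <- ihc("LCAPositive", "LCA")
  cd20 <- ihc("CD20Positive", "CD20")
  bob1 <- ihc("BOB1Positive", "BOB1")
  he_pheno$entities <- c("AtypicalLymphoid1", "Node1")
  d_lymphoma <- diagnosis("DiagnosisLymphoma", "lymphoma", "established",
                          support = "AtypicalLymphoidProliferation")
  d_bcell <- diagnosis("DiagnosisBCell", "large B-cell lymphoma", "established",
                       support = c("LCAPositive", "CD20Positive", "BOB1Positive"))
  d_tnk <- diagnosis("DiagnosisTNK", "T-cell and NK-cell lymphoma", "excluded",
                     contradict = c("CD20Positive", "BOB1Positive"))
  d_hodgkin <- diagnosis("DiagnosisHodgkin", "Hodgkin lymphoma", "excluded",
                         contradict = c("LCAPositive", "CD20Positive",
                                        "BOB1Positive"))
  proc <- build_diagnosis_process(list(
    diagnosis_stage("StageA", 1, list(d_lymphoma),
                    phenotypes = "AtypicalLymphoidProliferation"),
    diagnosis_stage("StageB", 2, list(d_bcell, d_tnk, d_hodgkin),
                    phenotypes = c("LCAPositive", "CD20Positive",
                                   "BOB1Positive"))),
    id = "Process2", item = "lymphoma subtype")
  patho_document(
    entity_graphs = list(build_entity_graph(lymph_cell), build_entity_graph(node),
                         lca$graph, cd20$graph, bob1$graph),
    phenotypes = list(he_pheno, lca$pheno, cd20$pheno, bob1$pheno),
    processes = list(proc),
    slide_meta = list(modality = "report"),
    id = "lymphoma-exemplar")
}

# The cervical slide as seen by the subtyping reasoner: three phenotypes.
exemplar_cervical_slide <- function() {
  cp <- cervical_phenotypes()
  patho_document(entity_graphs = cp$graphs, phenotypes = cp$phenos,
                 slide_meta = list(modality = "HE", height = 2048L,
                                   width = 2048L, magnification = 20),
                 id = "cervical-slide-exemplar")
}
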