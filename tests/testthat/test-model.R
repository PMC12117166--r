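# Typed graph model: builders, invariants, validation soundness.

her2_cell_graph <- function() {
  cell <- entity_node("Cell1", "NeoplasticCell")
  mem <- entity_node("Membrane1", "NeoplasticCellularComponent")
  nuc <- entity_node("Nucleus1", "NeoplasticCellularComponent")
  her2 <- entity_node("HER2", "Protein")
  feat <- feature_node("Medium", "staining extent", owner_id = "Membrane1")
  par <- quant_param("Quantification1", "staining completeness", 0.75,
                     feature_id = "Medium")
  build_entity_graph(cell, components = list(mem, nuc, her2),
                     features = list(feat), params = list(par),
                     part_whole = pathograph:::pg_pairs(
                       c("Cell1", "Cell1"), c("Membrane1", "Nucleus1")),
                     express_links = pathograph:::pg_pairs("Membrane1", "HER2"))
}

test_that("a HER2-style cell graph has the expected node and edge counts", {
  g <- her2_cell_graph()
  expect_equal(1 + length(g$components), 4)  # cell, membrane, nucleus, protein
  expect_length(g$features, 1)
  expect_length(g$params, 1)
  expect_equal(nrow(g$part_whole), 2)
  expect_equal(nrow(g$express_links), 1)
  expect_equal(g$params[["Quantification1"]]$value, 0.75)
  expect_equal(nrow(validate_document(patho_document(entity_graphs = list(g)))), 0)
})

test_that("a lone root yields an empty but valid graph", {
  g <- build_entity_graph(entity_node("T1", "Tumor"))
  expect_length(g$components, 0)
  expect_length(g$features, 0)
  expect_length(g$params, 0)
  expect_equal(nrow(g$part_whole), 0)
})

test_that("builders raise typed errors for cycles and dangling references", {
  cell <- entity_node("Cell1", "NeoplasticCell")
  nuc <- entity_node("Nucleus1", "NeoplasticCellularComponent")
  expect_error(
    build_entity_graph(cell, components = list(nuc),
                       part_whole = list(c("Cell1", "Nucleus1"),
                                         c("Nucleus1", "Cell1"))),
    class = "pg_cycle_error")
  expect_error(
    build_entity_graph(cell, components = list(nuc),
                       part_whole = list(c("Cell1", "Ghost"))),
    class = "pg_resolution_error")
  expect_error(
    build_entity_graph(cell, components = list(nuc),
                       features = list(feature_node("f1", "x", "Ghost"))),
    class = "pg_resolution_error")
})

test_that("express edges must pair a cellular component with a protein", {
  cell <- entity_node("Cell1", "NeoplasticCell")
  nuc <- entity_node("Nucleus1", "NeoplasticCellularComponent")
  st <- entity_node("Stroma1", "Stroma")
  expect_error(
    build_entity_graph(cell, components = list(nuc, st),
                       part_whole = list(c("Cell1", "Nucleus1"),
                                         c("Cell1", "Stroma1")),
                       express_links = list(c("Nucleus1", "Stroma1"))),
    class = "pg_validation_error")
})

test_that("part-whole acyclicity agrees with an independent DAG oracle", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    ids <- paste0("n", 1:n)
    m <- sample(1:8, 1)
    pairs <- pathograph:::pg_pairs(sample(ids, m, replace = TRUE),
                                   sample(ids, m, replace = TRUE))
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    if (nrow(pairs) == 0) next
    ours <- is.null(pathograph:::find_cycle(pairs))
    ig <- igraph::graph_from_data_frame(pairs, directed = TRUE)
    expect_equal(ours, igraph::is_dag(ig), info = sprintf("case %d", i))
  }
})

test_that("validation flags systematic single-field corruptions", {
  # Each case mutates one clean document to break exactly one stated invariant
  # and must produce at least one violation citing that clause.
  base <- exemplar_document("her2_fig4")
  cases <- list(
    single_cell_cardinality = function(d) {
      d$phenotypes[["Phenotype1"]]$entities <- c("Cell1", "Nucleus1"); d
    },
    single_cell_class = function(d) {
      d$phenotypes[["Phenotype1"]]$entities <- "Membrane1"; d
    },
    resolution = function(d) {
      d$phenotypes[["Phenotype1"]]$entities <- "NoSuchCell"; d
    },
    part_whole_acyclic = function(d) {
      g <- d$entity_graphs[[1]]
      g$part_whole <- rbind(g$part_whole,
                            pathograph:::pg_pairs("Membrane1", "Nucleus1"),
                            pathograph:::pg_pairs("Nucleus1", "Membrane1"))
      d$entity_graphs[[1]] <- g; d
    },
    express_typing = function(d) {
      g <- d$entity_graphs[[1]]
      g$express_links <- pathograph:::pg_pairs("Cell1", "HER2")
      d$entity_graphs[[1]] <- g; d
    },
    connectivity = function(d) {
      g <- d$entity_graphs[[1]]
      g$part_whole <- g$part_whole[g$part_whole$to != "Nucleus1", , drop = FALSE]
      d$entity_graphs[[1]] <- g; d
    },
    outline = function(d) {
      d$entity_graphs[[1]]$root$outline <- cbind(c(0, 1), c(0, 1)); d
    },
    bbox = function(d) {
      d$entity_graphs[[1]]$root$outline <- rect_outline(0, 0, 10, 10)
      d$entity_graphs[[1]]$root$bbox <- c(0, 0, 5, 5); d
    })
  for (clause in names(cases)) {
    v <- validate_document(cases[[clause]](base))
    expect_gt(nrow(v), 0, label = clause)
    expect_true(clause %in% v$clause,
                info = sprintf("expected clause '%s', got: %s", clause,
                               paste(unique(v$clause), collapse = ", ")))
  }
})

test_that("evidence and uniqueness violations are caught at document level", {
  d <- exemplar_document("cervical_fig6")
  d_dup <- d
  d_dup$phenotypes[["GlandularPattern"]]$relationships <- list(
    relationship_edge("Stage1", "back-to-back arrangement", "spatial",
                      subjects = "Gland1", objects = "Gland2"))
  v <- validate_document(d_dup)
  expect_true("unique_ids" %in% v$clause)

  d_ev <- d
  d_ev$processes[[1]]$stages[[1]]$possibilities[[1]]$support <- "NoSuchPhenotype"
  v2 <- validate_document(d_ev)
  expect_true(any(v2$clause == "resolution" & v2$type == "Diagnosis"))

  d_both <- d
  d_both$processes[[1]]$stages[[1]]$possibilities[[1]]$contradict <- "GlandularPattern"
  expect_true("evidence_disjoint" %in% validate_document(d_both)$clause)
})

test_that("multi-cell phenotypes need two entities or a relationship", {
  p <- phenotype("P1", "multi_cell", "Histopathological_Phenotype",
                 entities = "onlyone")
  v <- pathograph:::validate_phenotype(p)
  expect_true("multi_cell_cardinality" %in% v$clause)
  r <- relationship_edge("R1", "envelops", "behavioral",
                         subjects = "a", objects = "a")
  p2 <- phenotype("P2", "multi_cell", "Histopathological_Phenotype",
                  entities = "a", relationships = list(r))
  expect_true("subject_object_disjoint" %in%
                pathograph:::validate_phenotype(p2)$clause)
})

test_that("phenotype expansion pulls in entity-graph nodes and is idempotent", {
  doc <- exemplar_document("her2_fig4")
  p <- doc$phenotypes[["Phenotype1"]]
  g <- doc$entity_graphs[[1]]
  ex <- expand_phenotype(p, doc$entity_graphs)
  expect_named(ex$entity_graphs, "Cell1")
  # phenotype + (root + 3 components + 1 feature + 1 param)
  expect_equal(pathograph:::phenotype_size(ex), 1 + 6)
  expect_length(p$entity_graphs, 0)  # original untouched
  ex2 <- expand_phenotype(ex, doc$entity_graphs)
  expect_identical(ex, ex2)
  expect_error(expand_phenotype(p, list()), class = "pg_resolution_error")
})

test_that("expanded multi-cell phenotype size is the sum of its graphs", {
  doc <- exemplar_document("follicle_fig5")
  p <- doc$phenotypes[[1]]
  ex <- expand_phenotype(p, doc$entity_graphs)
  sizes <- vapply(doc$entity_graphs, pathograph:::entity_graph_size, 1L)
  expect_equal(pathograph:::phenotype_size(ex), 1L + sum(sizes))
})

test_that("diagnosis processes enforce stage ordering rules", {
  d1 <- diagnosis("D1", "adenocarcinoma", "established", support = "p")
  s1 <- diagnosis_stage("S1", 1, list(d1))
  expect_error(build_diagnosis_process(list()), class = "pg_value_error")
  expect_error(build_diagnosis_process(list(s1, diagnosis_stage("S2", 1, list(d1)))),
               class = "pg_value_error")
  p <- build_diagnosis_process(list(s1))
  expect_length(p$stages, 1)

  two_est <- diagnosis_stage("ST", 2, list(
    diagnosis("Da", "x", "established", support = "p"),
    diagnosis("Db", "y", "established", support = "p")))
  v <- pathograph:::validate_process(
    structure(list(id = "P", stages = list(s1, two_est), item = ""),
              class = "pg_process"))
  expect_true("terminal_established" %in% v$clause)
})

test_that("the cervical and lymphoma processes carry their stated structure", {
  cp <- exemplar_document("cervical_fig6")$processes[[1]]
  expect_length(cp$stages, 3)
  terminal <- cp$stages[[3]]$possibilities
  expect_equal(vapply(terminal, function(d) d$label, ""), "HPVA, usual type")
  expect_equal(vapply(terminal, function(d) d$status, ""), "established")

  lp <- exemplar_document("lymphoma_fig7")$processes[[1]]
  st2 <- lp$stages[[2]]
  expect_length(st2$possibilities, 3)
  statuses <- vapply(st2$possibilities, function(d) d$status, "")
  expect_equal(sum(statuses == "established"), 1)
  expect_equal(sum(statuses == "excluded"), 2)
})
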