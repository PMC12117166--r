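# PathoML serialization: roundtrips, canonical determinism, dialects, xrefs.

exemplar_names <- c("her2_fig4", "follicle_fig5", "cervical_fig6",
                    "lymphoma_fig7", "cervical_slide_fig11")

test_that("write -> read roundtrip is graph-isomorphic on all exemplars", {
  for (nm in exemplar_names) {
    d <- exemplar_document(nm)
    d2 <- read_pathoml(write_pathoml(d))
    expect_true(doc_isomorphic(d, d2), label = nm)
  }
})

test_that("write -> read roundtrip holds on random documents", {
  for (seed in 1:10) {
    d <- random_document(seed)
    d2 <- read_pathoml(write_pathoml(d))
    expect_true(doc_isomorphic(d, d2), label = sprintf("seed %d", seed))
    expect_identical(write_pathoml(d2), write_pathoml(d))
  }
})

test_that("canonical Turtle is byte-deterministic and write-read-write stable", {
  d <- exemplar_document("cervical_fig6")
  t1 <- write_pathoml(d)
  t2 <- write_pathoml(d)
  expect_identical(t1, t2)
  expect_identical(write_pathoml(read_pathoml(t1)), t1)
})

test_that("Turtle and RDF/XML serialize to identical triple sets", {
  for (nm in exemplar_names) {
    d <- exemplar_document(nm)
    ttl <- pathoml_triples(write_pathoml(d, dialect = "turtle"))
    owl <- pathoml_triples(write_pathoml(d, dialect = "rdfxml"))
    expect_true(pathograph:::same_triples(ttl, owl), label = nm)
    expect_true(doc_isomorphic(d, read_pathoml(write_pathoml(d, dialect = "rdfxml"))),
                label = paste(nm, "rdfxml roundtrip"))
  }
})

test_that("an empty document serializes to a header-only ontology", {
  txt <- write_pathoml(patho_document())
  tr <- pathoml_triples(txt)
  # the ontology header and the document individual are the only subjects
  expect_lte(length(unique(tr$s)), 2)
  d2 <- read_pathoml(txt)
  expect_length(d2$entity_graphs, 0)
  expect_length(d2$phenotypes, 0)
})

test_that("the reconstructed diagnosis process preserves stage order", {
  d2 <- read_pathoml(write_pathoml(exemplar_document("cervical_fig6")))
  pr <- d2$processes[[1]]
  expect_equal(vapply(pr$stages, function(s) s$index, 1L), 1:3)
  expect_equal(vapply(pr$stages, function(s) s$id, ""),
               c("Stage1", "Stage2", "Stage3"))
  expect_equal(d2$indicators[[1]]$value, 0.40)
})

test_that("triple count equals the independently counted assertions for a PEG scene", {
  sc <- make_scene(n_tumors = 2, nuclei_per_tumor = 5, n_stray_nuclei = 0,
                   seed = 21)
  pegs <- build_pegs(sc$scene)
  doc <- patho_document(entity_graphs = pegs, id = "scene")
  tr <- pathoml_triples(write_pathoml(doc))
  # Independent count from the model structure: per graph, typing + names +
  # geometry + relation edges; plus graph/root/doc plumbing and the header.
  expected <- 1 + 1  # ontology header + document typing
  for (g in pegs) {
    n_ent <- 1 + length(g$components)
    expected <- expected + 1 + 1 + 1          # graph typing, hasRoot, has_EntityGraph
    expected <- expected + n_ent * 4          # entity: type, name, segmentation, bbox
    expected <- expected + length(g$features) * 2  # type, featureName
    expected <- expected + length(g$params) * 3 +  # type, paramName, hasValue
      sum(vapply(g$params, function(q) nzchar(q$unit), TRUE))  # + unit
    expected <- expected + nrow(g$part_whole) + nrow(g$express_links) +
      nrow(g$feature_links) + nrow(g$quant_links)
  }
  expect_equal(nrow(tr), expected)
})

test_that("unknown class IRIs and dangling targets are rejected by name", {
  bad_class <- paste(
    "@prefix pml: <http://www.pathoml.org/pathoml#> .",
    "@prefix ex: <http://example.org/pathograph/doc#> .",
    "ex:Thing1 a pml:NoSuchClass .", sep = "\n")
  err <- expect_error(read_pathoml(bad_class), class = "pg_parse_error")
  expect_match(conditionMessage(err), "NoSuchClass")

  dangling <- paste(
    "@prefix pml: <http://www.pathoml.org/pathoml#> .",
    "@prefix ex: <http://example.org/pathograph/doc#> .",
    "ex:Stage1 a pml:DiagnosisStage ;",
    "  pml:stepProcess ex:Undeclared .", sep = "\n")
  err2 <- expect_error(read_pathoml(dangling), class = "pg_resolution_error")
  expect_match(conditionMessage(err2), "Undeclared")
})

test_that("serialization refuses documents that do not validate", {
  d <- exemplar_document("her2_fig4")
  d$phenotypes[["Phenotype1"]]$entities <- c("Cell1", "Nucleus1")
  err <- expect_error(write_pathoml(d), class = "pg_validation_error")
  expect_gt(nrow(err$violations), 0)
})

test_that("xrefs roundtrip, deduplicate, and attach to diagnoses", {
  d <- exemplar_document("her2_fig4")
  d <- attach_xref(d, "HER2", "HGNC", "3430")
  d <- attach_xref(d, "HER2", "HGNC", "3430")  # idempotent
  txt <- write_pathoml(d)
  tr <- pathoml_triples(txt)
  b <- pathoml_binding()
  hx <- tr[tr$p == b$objprop_map[["hasXref"]], , drop = FALSE]
  expect_equal(nrow(hx), 1)
  d2 <- read_pathoml(txt)
  prot <- d2$entity_graphs[[1]]$components[["HER2"]]
  expect_equal(prot$xrefs, list(c("HGNC", "3430")))

  dl <- exemplar_document("lymphoma_fig7")
  dl <- attach_xref(dl, "DiagnosisBCell", "ICD-O", "9680/3")
  d2l <- read_pathoml(write_pathoml(dl))
  dx <- d2l$processes[[1]]$stages[[2]]$possibilities
  bcell <- Filter(function(x) x$id == "DiagnosisBCell", dx)[[1]]
  expect_equal(bcell$xrefs, list(c("ICD-O", "9680/3")))
  expect_error(attach_xref(d, "NoSuchNode", "X", "1"),
               class = "pg_resolution_error")
})

test_that("segmentation outlines survive the roundtrip exactly", {
  poly <- rect_outline(10.25, 20.5, 30.75, 42)
  g <- build_entity_graph(entity_node("T1", "Tumor", outline = poly))
  d2 <- read_pathoml(write_pathoml(patho_document(entity_graphs = list(g))))
  got <- d2$entity_graphs[[1]]$root
  expect_equal(got$outline, poly, ignore_attr = TRUE)
  expect_equal(got$bbox, c(10.25, 20.5, 30.75, 42))
})

test_that("MathML formulas survive XML escaping in both dialects", {
  d <- exemplar_document("cervical_fig6")
  for (dialect in c("turtle", "rdfxml")) {
    d2 <- read_pathoml(write_pathoml(d, dialect = dialect))
    f <- d2$indicators[[1]]$formula
    expect_equal(eval_mathml(f, c(mucin_cell_count = 40, tumor_cell_count = 100)),
                 0.4, tolerance = 1e-12)
  }
})
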