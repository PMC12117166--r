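# Scene ingestion, part-whole assignment, automated graph construction,
# GraphML export.

test_that("GeoJSON scenes parse with computed boxes and centroids", {
  json <- manual_scene_json(list(
    list(id = "t1", class = "tumor", outline = rect_outline(0, 0, 100, 100)),
    list(id = "n1", class = "neoplastic_nucleus", outline = rect_outline(10, 10, 20, 20)),
    list(id = "n2", class = "neoplastic_nucleus", outline = rect_outline(30, 30, 40, 40)),
    list(id = "n3", class = "non_neoplastic_nucleus", outline = rect_outline(60, 60, 70, 70))))
  sc <- load_scene(json)
  expect_length(sc$regions, 1)
  expect_length(sc$nuclei, 3)
  expect_equal(sc$nuclei[[1]]$centroid, c(15, 15))
  expect_equal(sc$nuclei[[1]]$bbox, c(10, 10, 20, 20))
  expect_equal(sc$width, 200)

  empty <- load_scene('{"type":"FeatureCollection","features":[]}')
  expect_length(empty$regions, 0)
  expect_length(empty$nuclei, 0)
})

test_that("malformed GeoJSON is rejected with a pointed message", {
  no_class <- '{"type":"FeatureCollection","features":[{"type":"Feature",
    "properties":{},"geometry":{"type":"Polygon",
    "coordinates":[[[0,0],[1,0],[1,1],[0,0]]]}}]}'
  err <- expect_error(load_scene(no_class), class = "pg_parse_error")
  expect_match(conditionMessage(err), "feature 1")
  not_poly <- '{"type":"FeatureCollection","features":[{"type":"Feature",
    "properties":{"class":"tumor"},"geometry":{"type":"Point","coordinates":[1,1]}}]}'
  expect_error(load_scene(not_poly), class = "pg_parse_error")
  expect_error(load_scene('{"type":"Feature"}'), class = "pg_parse_error")
})

test_that("scene parsing recovers the generator's declared counts", {
  sc <- make_scene(n_tumors = 3, nuclei_per_tumor = 4, n_stray_nuclei = 2,
                   seed = 5)
  expect_length(sc$scene$regions, 3)
  expect_length(sc$scene$nuclei, 3 * 4 + 2)
  labels <- vapply(sc$scene$nuclei, `[[`, "", "label")
  expect_equal(sum(labels == "neoplastic"), 12 + 1)  # one stray is neoplastic
})

test_that("nuclei are assigned to the maximal-overlap tumor above threshold", {
  json <- manual_scene_json(list(
    list(id = "A", class = "tumor", outline = rect_outline(0, 0, 60, 100)),
    list(id = "B", class = "tumor", outline = rect_outline(60, 0, 120, 100)),
    # fully inside A
    list(id = "in_a", class = "neoplastic_nucleus",
         outline = rect_outline(10, 10, 20, 20)),
    # straddles A (0.6) and B (0.4)
    list(id = "straddle", class = "neoplastic_nucleus",
         outline = rect_outline(54, 40, 64, 50)),
    # outside all tumors
    list(id = "outside", class = "neoplastic_nucleus",
         outline = rect_outline(150, 150, 160, 160)),
    # non-neoplastic inside A: never assigned
    list(id = "nn", class = "non_neoplastic_nucleus",
         outline = rect_outline(30, 30, 40, 40))))
  a <- assign_parts(load_scene(json))
  row <- function(id) a[a$nucleus_id == id, ]
  expect_equal(row("in_a")$tumor_id, "A")
  expect_equal(row("in_a")$overlap, 1.0)
  expect_equal(row("straddle")$tumor_id, "A")
  expect_equal(row("straddle")$overlap, 0.6, tolerance = 1e-9)
  expect_true(is.na(row("outside")$tumor_id))
  expect_false("nn" %in% a$nucleus_id)
})

test_that("exact overlap ties break toward the smaller tumor id", {
  json <- manual_scene_json(list(
    list(id = "B", class = "tumor", outline = rect_outline(60, 0, 120, 100)),
    list(id = "A", class = "tumor", outline = rect_outline(0, 0, 60, 100)),
    list(id = "split", class = "neoplastic_nucleus",
         outline = rect_outline(55, 40, 65, 50))))
  a <- assign_parts(load_scene(json))
  expect_equal(a$tumor_id, "A")
})

test_that("assignment respects the overlap threshold", {
  json <- manual_scene_json(list(
    list(id = "A", class = "tumor", outline = rect_outline(0, 0, 60, 100)),
    list(id = "edge", class = "neoplastic_nucleus",
         outline = rect_outline(56, 40, 66, 50))))  # 0.4 inside A
  sc <- load_scene(json)
  expect_true(is.na(assign_parts(sc)$tumor_id))
  expect_equal(assign_parts(sc, threshold = 0.3)$tumor_id, "A")
})

test_that("one entity graph per tumor with the documented node counts", {
  json <- manual_scene_json(list(
    list(id = "t1", class = "tumor", outline = rect_outline(0, 0, 100, 100)),
    list(id = "n1", class = "neoplastic_nucleus", outline = rect_outline(10, 10, 20, 20)),
    list(id = "n2", class = "neoplastic_nucleus", outline = rect_outline(30, 10, 40, 20)),
    list(id = "n3", class = "neoplastic_nucleus", outline = rect_outline(50, 10, 60, 20)),
    list(id = "n4", class = "neoplastic_nucleus", outline = rect_outline(70, 10, 80, 20)),
    list(id = "t2", class = "tumor", outline = rect_outline(120, 120, 180, 180))))
  sc <- load_scene(json)
  pegs <- build_pegs(sc)
  expect_length(pegs, 2)
  g <- pegs[[1]]
  expect_equal(1 + length(g$components), 5)     # tumor + 4 nuclei
  expect_equal(nrow(g$part_whole), 4)
  expect_length(g$params, 20)                   # 4 nuclei x 5 descriptors
  expect_equal(g$root$entity_class, "Tumor")
  expect_true(all(vapply(g$components, function(e)
    e$entity_class == "NeoplasticCell", TRUE)))
  # empty tumor: a lone root
  expect_length(pegs[[2]]$components, 0)
  # every constructed graph passes document validation
  expect_equal(nrow(validate_document(patho_document(entity_graphs = pegs))), 0)
})

test_that("component counts are conserved across the scene", {
  sc <- make_scene(n_tumors = 3, nuclei_per_tumor = 4, n_stray_nuclei = 3,
                   seed = 9)
  a <- assign_parts(sc$scene)
  pegs <- build_pegs(sc$scene, a)
  expect_length(pegs, 3)
  expect_equal(sum(vapply(pegs, function(g) length(g$components), 1L)),
               sum(!is.na(a$tumor_id)))
})

test_that("assignment referencing unknown ids is rejected", {
  sc <- make_scene(1, 2, 0, seed = 2)
  a <- assign_parts(sc$scene)
  a$nucleus_id[1] <- "ghost"
  expect_error(build_pegs(sc$scene, a), class = "pg_resolution_error")
})

test_that("GraphML export preserves node/edge counts and attributes", {
  sc <- make_scene(2, 3, 0, seed = 4)
  pegs <- build_pegs(sc$scene)
  f <- tempfile(fileext = ".graphml")
  on.exit(unlink(f))
  export_for_ml(pegs, f)
  gr <- igraph::read_graph(f, format = "graphml")
  n_nodes <- sum(vapply(pegs, pathograph:::entity_graph_size, 1L))
  n_edges <- sum(vapply(pegs, function(g)
    nrow(g$part_whole) + nrow(g$express_links) + nrow(g$feature_links) +
      nrow(g$quant_links), 1L))
  expect_equal(igraph::vcount(gr), n_nodes)
  expect_equal(igraph::ecount(gr), n_edges)
  # attribute values survive the roundtrip
  v <- igraph::as_data_frame(gr, what = "vertices")
  one_param <- pegs[[1]]$params[[1]]
  expect_equal(v$value[v$name == one_param$id], one_param$value)
  expect_setequal(unique(igraph::E(gr)$type),
                  c("hasComponent", "hasAttribute", "quantification"))
})

test_that("an empty graph list exports an empty GraphML document", {
  f <- tempfile(fileext = ".graphml")
  on.exit(unlink(f))
  export_for_ml(list(), f)
  gr <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(gr), 0)
})
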