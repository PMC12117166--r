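# Structural subsumption reasoning and knowledge-base construction.

test_that("slide concepts collect one atom per phenotype, deduplicated", {
  slide <- slide_to_concept(exemplar_document("cervical_slide_fig11"))
  expect_setequal(slide$atoms,
                  c("glandular pattern", "apoptotic body", "luminal mitosis"))
  expect_length(slide_to_concept(patho_document())$atoms, 0)  # top concept
  dup <- concept_expr(c("Apoptotic  Body", "apoptotic body", "x"))
  expect_equal(dup$atoms, c("apoptotic body", "x"))
})

test_that("the cervical knowledge base accumulates atoms along the stages", {
  doc <- exemplar_document("cervical_fig6")
  kb <- process_to_kb(doc$processes[[1]], doc)
  expect_equal(kb$definitions[["adenocarcinoma"]]$atoms, "glandular pattern")
  expect_setequal(kb$definitions[["HPVA"]]$atoms,
                  c("glandular pattern", "apoptotic body", "luminal mitosis"))
  expect_setequal(kb$definitions[["HPVA, usual type"]]$atoms,
                  c("glandular pattern", "apoptotic body", "luminal mitosis",
                    "proportion of tumor cells with intracytoplasmic mucin"))
  # non-cumulative mode keeps only per-stage atoms
  kb2 <- process_to_kb(doc$processes[[1]], doc, cumulative = FALSE)
  expect_setequal(kb2$definitions[["HPVA"]]$atoms,
                  c("apoptotic body", "luminal mitosis"))
})

test_that("the lymphoma knowledge base carries support and contradictions", {
  doc <- exemplar_document("lymphoma_fig7")
  kb <- suppressWarnings(process_to_kb(doc$processes[[1]], doc))
  expect_true(all(c("lca positive", "cd20 positive", "bob1 positive") %in%
                    kb$definitions[["large B-cell lymphoma"]]$atoms))
  expect_setequal(kb$exclusions[["T-cell and NK-cell lymphoma"]],
                  c("cd20 positive", "bob1 positive"))
  expect_setequal(kb$exclusions[["Hodgkin lymphoma"]],
                  c("lca positive", "cd20 positive", "bob1 positive"))
  # diagnoses with no support draw a warning each and no definition
  w <- capture_warnings(process_to_kb(doc$processes[[1]], doc))
  expect_length(w, 2)
  expect_match(w, "no supporting evidence", all = TRUE)
  expect_false("Hodgkin lymphoma" %in% names(kb$definitions))
})

test_that("subsumption is atom-set containment, with TOP above everything", {
  C <- concept_expr(c("a", "b", "c"))
  expect_true(subsumes_concept(C, concept_expr("a")))
  expect_false(subsumes_concept(concept_expr("a"), C))
  expect_true(subsumes_concept(C, concept_expr(character())))
  expect_true(subsumes_concept(concept_expr(character()), concept_expr(character())))
})

test_that("subsumption matches the brute-force oracle on a 6-label lattice", {
  labels <- letters[1:6]
  subsets <- lapply(0:63, function(m) labels[bitwAnd(m, 2^(0:5)) > 0])
  concepts <- lapply(subsets, concept_expr)
  for (i in seq_along(concepts)) {
    for (j in seq_along(concepts)) {
      oracle <- all(subsets[[j]] %in% subsets[[i]])
      expect_identical(subsumes_concept(concepts[[i]], concepts[[j]]), oracle)
    }
  }
})

test_that("subsumption is reflexive and transitive on random concepts", {
  set.seed(17)
  labs <- paste0("ph", 1:8)
  rand_concept <- function() concept_expr(sample(labs, sample(0:5, 1)))
  for (i in 1:500) {
    A <- rand_concept(); B <- rand_concept(); C <- rand_concept()
    expect_true(subsumes_concept(A, A))
    if (subsumes_concept(A, B) && subsumes_concept(B, C)) {
      expect_true(subsumes_concept(A, C))
    }
    # with an empty hierarchy, equivalence is atom-set equality
    if (subsumes_concept(A, B) && subsumes_concept(B, A)) {
      expect_identical(A$atoms, B$atoms)
    }
  }
})

test_that("a phenotype hierarchy licenses descendant matches and rejects cycles", {
  hier <- data.frame(child = c("apical mitosis", "luminal mitosis"),
                     parent = c("mitosis", "mitosis"))
  slide <- concept_expr("apical mitosis")
  expect_true(subsumes_concept(slide, concept_expr("mitosis"), hier))
  expect_false(subsumes_concept(slide, concept_expr("luminal mitosis"), hier))
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(subsumes_concept(slide, concept_expr("mitosis"), cyc),
               class = "pg_cycle_error")
})

test_that("the cervical slide is implied by adenocarcinoma and equivalent to HPVA", {
  doc <- exemplar_document("cervical_fig6")
  kb <- process_to_kb(doc$processes[[1]], doc)
  slide <- slide_to_concept(exemplar_document("cervical_slide_fig11"))
  expect_true(subsumes_concept(slide, kb$definitions[["adenocarcinoma"]]))
  expect_true(subsumes_concept(slide, kb$definitions[["HPVA"]]))
  expect_true(subsumes_concept(kb$definitions[["HPVA"]], slide))
  res <- infer_subtype(slide, kb)
  expect_setequal(res$implied, c("adenocarcinoma", "HPVA"))
  expect_equal(res$equivalent, "HPVA")
  expect_equal(res$reported_subtype, "HPVA")
  expect_false(res$unresolved)
})

test_that("the lymphoma differential reports large B-cell and excludes the rest", {
  doc <- exemplar_document("lymphoma_fig7")
  kb <- suppressWarnings(process_to_kb(doc$processes[[1]], doc))
  res <- infer_subtype(slide_to_concept(doc), kb)
  expect_equal(res$reported_subtype, "large B-cell lymphoma")
  expect_setequal(res$excluded,
                  c("T-cell and NK-cell lymphoma", "Hodgkin lymphoma"))
})

test_that("an excluded diagnosis is never reported, and empty KBs yield nothing", {
  kb <- structure(list(
    definitions = list(X = concept_expr(c("a", "b"), name = "X"),
                       Y = concept_expr("a", name = "Y")),
    exclusions = list(X = "c"),
    hierarchy = NULL), class = "pg_kb")
  slide <- concept_expr(c("a", "b", "c"))
  res <- infer_subtype(slide, kb)
  expect_true("X" %in% res$implied)
  expect_true("X" %in% res$excluded)
  expect_equal(res$reported_subtype, "Y")  # most specific non-excluded

  empty <- infer_subtype(slide, structure(list(definitions = list(),
                                               exclusions = list(),
                                               hierarchy = NULL),
                                          class = "pg_kb"))
  expect_length(empty$implied, 0)
  expect_true(is.na(empty$reported_subtype))
})

test_that("infer matches brute-force containment over random knowledge bases", {
  set.seed(29)
  labs <- paste0("ph", 1:8)
  for (rep in 1:25) {
    n_dx <- sample(1:6, 1)
    defs <- lapply(seq_len(n_dx), function(i)
      sample(labs, sample(1:4, 1)))
    names(defs) <- paste0("dx", seq_len(n_dx))
    kb <- structure(list(
      definitions = lapply(names(defs), function(n)
        concept_expr(defs[[n]], name = n)) |> stats::setNames(names(defs)),
      exclusions = list(), hierarchy = NULL), class = "pg_kb")
    slide_atoms <- sample(labs, sample(0:6, 1))
    res <- infer_subtype(concept_expr(slide_atoms), kb)
    oracle <- names(defs)[vapply(defs, function(d)
      all(d %in% normalize_atom(slide_atoms)), TRUE)]
    expect_setequal(res$implied, oracle)
  }
})
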