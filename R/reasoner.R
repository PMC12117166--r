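# Structural subsumption reasoning for histologic subtyping. The logic
# fragment is conjunctions of existential phenotype atoms over a single
# "exhibits" role (EL without nesting); for this fragment, atom-set
# containment (modulo a phenotype hierarchy) is a sound and complete
# decision procedure for subsumption.

#' Normalize a phenotype label into a reasoning atom
#'
#' Case-folded, trimmed, internal whitespace collapsed. Used for atom identity
#' whenever no cross-reference code is available.
#'
#' @param x Character vector of labels.
#' @return Normalized character vector.
#' @export
normalize_atom <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Atom identity for a phenotype-like object: first xref as vocab:code, else
# the normalized label.
phenotype_atom <- function(p) {
  if (length(p$xrefs) > 0) {
    x <- p$xrefs[[1]]
    return(paste0(x[1], ":", x[2]))
  }
  normalize_atom(if (!is.null(p$label)) p$label else p$name)
}

#' Create a concept expression
#'
#' A conjunction of existential phenotype atoms (each atom reads "exhibits
#' some <phenotype>"). The empty conjunction is the top concept.
#'
#' @param atoms Character vector of phenotype labels; normalized and
#'   deduplicated.
#' @param name Optional concept name.
#' @return Object of class `pg_concept`.
#' @export
concept_expr <- function(atoms = character(), name = NULL) {
  structure(list(atoms = pg_sort(unique(normalize_atom(atoms))), name = name),
            class = "pg_concept")
}

#' @export
print.pg_concept <- function(x, ...) {
  if (length(x$atoms) == 0) {
    cat("<concept>", x$name %||% "", "TOP\n")
  } else {
    cat("<concept>", x$name %||% "",
        paste(sprintf("∃exhibits.%s", x$atoms), collapse = " ⊓ "), "\n")
  }
  invisible(x)
}

#' Translate a slide document into a concept expression
#'
#' One existential atom per phenotype (and quantitative indicator) present in
#' the document; duplicates collapse.
#'
#' @param doc A [patho_document()].
#' @return A [concept_expr()].
#' @export
slide_to_concept <- function(doc) {
  atoms <- c(vapply(doc$phenotypes, phenotype_atom, ""),
             vapply(doc$indicators, phenotype_atom, ""))
  concept_expr(unname(atoms), name = doc$id)
}

#' Build a diagnostic knowledge base from a diagnosis process
#'
#' Each diagnosis's defining concept is the conjunction of the atoms of its
#' supporting phenotypes; in cumulative mode (default) a diagnosis at stage
#' *i* also inherits the atoms of diagnoses established at earlier stages,
#' implementing the progressive narrowing of a staged differential diagnosis.
#' Contradicting evidence yields per-diagnosis exclusion atom sets, handled
#' outside the logic as a post-filter (the fragment has no negation).
#'
#' @param dp A [build_diagnosis_process()] result.
#' @param phenotype_labels Named character vector mapping phenotype/indicator
#'   ids to atom labels, or a [patho_document()] containing them.
#' @param cumulative Inherit established-diagnosis atoms along the stage chain.
#' @return Object of class `pg_kb`: list with `definitions` (named list of
#'   [concept_expr()]), `exclusions` (named list of atom vectors), `hierarchy`.
#' @export
process_to_kb <- function(dp, phenotype_labels = NULL, cumulative = TRUE) {
  if (inherits(phenotype_labels, "pg_document")) {
    doc <- phenotype_labels
    phenotype_labels <- c(
      vapply(doc$phenotypes, phenotype_atom, ""),
      vapply(doc$indicators, phenotype_atom, ""))
  }
  label_of <- function(pid) {
    if (!is.null(phenotype_labels) && pid %in% names(phenotype_labels)) {
      phenotype_labels[[pid]]
    } else normalize_atom(pid)
  }
  definitions <- list()
  exclusions <- list()
  inherited <- character()
  for (s in dp$stages) {
    established_here <- character()
    for (d in s$possibilities) {
      atoms <- normalize_atom(vapply(d$support, label_of, ""))
      contra <- normalize_atom(vapply(d$contradict, label_of, ""))
      if (length(atoms) == 0) {
        warning(sprintf("diagnosis '%s' has no supporting evidence; excluded from definitions",
                        d$label))
      } else {
        all_atoms <- if (cumulative) unique(c(inherited, atoms)) else atoms
        definitions[[d$label]] <- concept_expr(all_atoms, name = d$label)
        if (d$status == "established") {
          established_here <- unique(c(established_here, all_atoms))
        }
      }
      if (length(contra) > 0) {
        exclusions[[d$label]] <- pg_sort(unique(c(exclusions[[d$label]], contra)))
      }
    }
    if (cumulative) inherited <- unique(c(inherited, established_here))
  }
  structure(list(definitions = definitions, exclusions = exclusions,
                 hierarchy = NULL), class = "pg_kb")
}

# Ancestor closure of a child->parent hierarchy given as a two-column pair set.
hierarchy_ancestors <- function(hierarchy) {
  if (is.null(hierarchy) || nrow(as_pg_pairs(hierarchy)) == 0) return(list())
  h <- as_pg_pairs(hierarchy)
  h$from <- normalize_atom(h$from); h$to <- normalize_atom(h$to)
  cyc <- find_cycle(h)
  if (!is.null(cyc)) {
    pg_cycle_error(sprintf("phenotype hierarchy is cyclic: %s",
                           paste(cyc, collapse = " -> ")), cycle = cyc)
  }
  anc <- list()
  for (node in unique(c(h$from, h$to))) {
    seen <- character(); frontier <- node
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(h$to[h$from %in% frontier]), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    anc[[node]] <- seen
  }
  anc
}

# Does atom `a` match atom `d` (equal, or a is a descendant of d)?
atom_matches <- function(a, d, ancestors) {
  a == d || d %in% (ancestors[[a]] %||% character())
}

#' Structural subsumption between concept expressions
#'
#' `subsumes_concept(C, D, ...)` decides `C` is subsumed by `D` (every atom of
#' `D` is matched by an atom of `C`, where a match is label equality or the
#' slide's label being a descendant of the definition's label in the phenotype
#' hierarchy). For the conjunctive-existential fragment this structural check
#' is sound and complete.
#'
#' @param C,D [concept_expr()] objects (or character atom vectors).
#' @param hierarchy Optional child-parent label pairs (two-column).
#' @return Logical: `TRUE` iff `C` is subsumed by `D` (`C ⊑ D`).
#' @export
subsumes_concept <- function(C, D, hierarchy = NULL) {
  ca <- if (inherits(C, "pg_concept")) C$atoms else normalize_atom(C)
  da <- if (inherits(D, "pg_concept")) D$atoms else normalize_atom(D)
  if (length(da) == 0) return(TRUE)       # everything is subsumed by TOP
  if (is.null(hierarchy)) return(all(da %in% ca))
  anc <- hierarchy_ancestors(hierarchy)
  all(vapply(da, function(d) any(vapply(ca, atom_matches, TRUE, d = d,
                                        ancestors = anc)), TRUE))
}

#' Infer a histologic subtype by subsumption
#'
#' Checks the slide concept against every definition in the knowledge base.
#' A diagnosis is *implied* when the slide is subsumed by its definition,
#' *equivalent* on mutual subsumption, and *excluded* when any of its
#' exclusion atoms is present in the slide. The reported subtype is the unique
#' equivalent diagnosis if one exists, otherwise the most specific implied
#' diagnosis (largest definition); ties are reported unresolved. An excluded
#' diagnosis is never reported.
#'
#' @param slide A [concept_expr()] (e.g. from [slide_to_concept()]).
#' @param kb A [process_to_kb()] result.
#' @param hierarchy Optional phenotype hierarchy (overrides `kb$hierarchy`).
#' @return List with `reported_subtype` (character or `NA`), `implied`,
#'   `equivalent`, `excluded`, `unresolved` (logical), and `proof`
#'   (per-diagnosis matched atoms).
#' @export
infer_subtype <- function(slide, kb, hierarchy = NULL) {
  hierarchy <- hierarchy %||% kb$hierarchy
  anc <- hierarchy_ancestors(hierarchy)
  excluded <- character()
  for (lab in names(kb$exclusions)) {
    ex_atoms <- kb$exclusions[[lab]]
    hit <- any(vapply(slide$atoms, function(a)
      any(vapply(ex_atoms, function(d) atom_matches(a, d, anc), TRUE)), TRUE))
    if (length(slide$atoms) > 0 && hit) excluded <- c(excluded, lab)
  }
  implied <- character(); equivalent <- character(); proof <- list()
  for (lab in names(kb$definitions)) {
    def <- kb$definitions[[lab]]
    if (subsumes_concept(slide, def, hierarchy)) {
      implied <- c(implied, lab)
      proof[[lab]] <- def$atoms
      if (subsumes_concept(def, slide, hierarchy)) {
        equivalent <- c(equivalent, lab)
      }
    }
  }
  candidates_eq <- setdiff(equivalent, excluded)
  candidates_im <- setdiff(implied, excluded)
  unresolved <- FALSE
  if (length(candidates_eq) == 1) {
    reported <- candidates_eq
  } else if (length(candidates_im) > 0) {
    sizes <- vapply(candidates_im,
                    function(l) length(kb$definitions[[l]]$atoms), 1L)
    best <- candidates_im[sizes == max(sizes)]
    if (length(best) == 1) reported <- best
    else { reported <- NA_character_; unresolved <- TRUE }
  } else {
    reported <- NA_character_
  }
  list(reported_subtype = reported, implied = implied,
       equivalent = equivalent, excluded = pg_sort(unique(excluded)),
       unresolved = unresolved, proof = proof)
}
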