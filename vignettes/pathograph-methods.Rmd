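---
title: "Graph representation of pathology knowledge: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph representation of pathology knowledge: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathograph)
```

## The graph model

`pathograph` organizes pathology knowledge into three graph families that
share one id space inside a document.

**Entity graphs.** A pathological entity *a* (a tumor region, a cell, a
cellular component, a protein) is described by
*G_a = ({a} ∪ E_a ∪ C_a ∪ Q_a, R_ee ∪ R_ec ∪ R_cq)*: components *E_a* under
the part–whole relation *R_ee*, pathological features *C_a* attached by
*R_ec*, quantitative parameters *Q_a* attached to features by *R_cq*, and
component→protein *express* edges for antigens residing in a component. The
enforced invariants are: the relation sets respect their domains and ranges
(*R_ee ⊆ ({a} ∪ E_a) × E_a*, etc.); *R_ee* is acyclic; express edges pair a
cellular-component node with a protein node; outlines, when present, are
simple polygons of positive area contained in their bounding boxes.

One invariant deserves a note. Components must be *connected* to the root,
and we check connectivity over the union of part–whole and express edges
rather than part–whole alone: a protein expressed by a membrane belongs to
the cell's graph even though a protein is not a mereological part of the
membrane. Requiring part–whole reachability alone would reject exactly the
canonical single-cell immunophenotype graph (cell → membrane → *expresses* →
antigen) the model is built to represent.

**Phenotype graphs.** Single-cell phenotypes reference exactly one cell-kind
entity; multi-cell phenotypes reference at least two entities or one
relationship edge, where relationship edges carry a controlled predicate
("back-to-back arrangement", "invades", "envelops", ...), a
spatial/behavioral category flag, and disjoint subject and object sets.
Quantitative phenotypic indicators carry a numeric value, the parameters the
value is computed from, and a content-MathML formula; when the formula is
evaluable over the parameters (all identifiers bind to parameter names),
validation recomputes it and requires agreement with the stored value to a
relative 1e-9. `expand_phenotype()` replaces constituent entities by their
full entity graphs; expansion is a derived view — it is idempotent and is
deliberately **not** serialized, since it is recomputable from the document's
graphs.

**Diagnosis graphs.** A diagnostic process is an ordered chain of stages;
each stage holds diagnostic possibilities split into established and
excluded, with support/contradict evidence pointing at phenotypes or
indicators declared anywhere in the document (pathologists reuse slide
findings across stages, so evidence visibility is document-wide). The stage
order is stored as list order — every process in scope is a linear chain —
and the successor pairs are materialized only at serialization time. The
terminal stage may establish at most one outcome; non-terminal stages may
establish an intermediate diagnosis that later stages refine (more than one
draws a warning, since the model permits it but no worked example needs it).
Whether a stage's examined phenotypes must be disjoint across stages is left
unconstrained.

## PathoML serialization

Documents serialize to an OWL-style ontology: one named individual per node,
typed by its class; one triple per edge through a fixed object-property
binding (`hasComponent`, `express`, `hasAttribute`, `quantification`,
`present_Entity`, `subject`/`object`, `has_quantity`, `diagnosisOrder`,
`nextStep`, `stepProcess`, `hasSupportEvidence`, `hasContradictEvidence`,
`hasXref`, ...); scalars as data properties (`hasValue`, `hasFormula`,
`segmentation`, slide height/width/magnification, ...). Where a published
schema might model some node kinds as data properties rather than
individuals, this implementation individualizes *all* nodes and keeps scalars
as data properties — a uniform choice that makes the write→read roundtrip
total.

Design choices a reader may want to know:

* **Namespaces.** A fixed schema namespace plus a per-document namespace for
  individuals, both configurable through `pathoml_binding()`.
* **Canonical Turtle.** Individuals sorted by id, predicates sorted
  lexicographically (`rdf:type` first, as `a`), objects sorted within a
  predicate. Numbers are printed with the shortest decimal string that parses
  back to the identical double. Consequently two writes of one document are
  byte-identical, and write→read→write is a fixed point — the property the
  roundtrip tests pin down. RDF/XML is provided as a second dialect; both
  dialects parse to identical triple sets.
* **Segmentation encoding.** Outlines are stored in the `segmentation` data
  property as `"x0,y0 x1,y1 ..."`, 0-based pixel coordinates, image
  convention (y down), polygon closed implicitly.
* **Formulas.** Content MathML, stored as an XML-literal string and never
  interpreted at parse time; evaluation happens only in validation and only
  when every identifier binds.
* **Stage chain.** Emitted as both `nextStep` pairs and `diagnosisOrder`
  membership, so either encoding suffices to reconstruct the order (indices
  disambiguate).
* The Turtle reader covers the profile the writer emits (prefixed names,
  object/predicate lists, typed literals, numerals) — it is an I/O
  component, not a general RDF library.

## Automated entity-graph construction

Scenes arrive as GeoJSON FeatureCollections of polygons labelled `tumor`,
`neoplastic_nucleus`, or `non_neoplastic_nucleus`. Construction has three
steps: (1) per-nucleus morphometry, (2) part–whole assignment by spatial
overlap, (3) assembly of one entity graph per tumor region (root `Tumor`
node; one `NeoplasticCell` component per assigned nucleus, carrying its
outline and bounding box as node attributes). A nucleus contributes one
entity node rather than a cell/nucleus pair: the counts in the automated
workflow are defined per detected nucleus, and a single node per nucleus
keeps the graph in bijection with the segmentation.

**Overlap criterion.** A neoplastic nucleus is assigned to the tumor with the
maximal overlap fraction — intersection area over nucleus area — provided
the fraction reaches the threshold (default 0.5, a config key; ties break
toward the smaller tumor id so the assignment is a deterministic function of
the scene). Non-neoplastic nuclei are parsed but never assigned, and
non-tumor regions never become graph roots. Intersection areas are computed
exactly by Sutherland–Hodgman clipping when the tumor polygon is convex
(the synthetic tumors are convex by construction); for non-convex regions a
deterministic 48×48 grid point-in-polygon estimate over the nucleus bounding
box stands in — adequate because assignment only compares fractions against
0.5 and against each other.

**Morphometry.** The five-descriptor bundle fixes the feature set to area,
perimeter, roundness, shape factor, and solidity (configurable). Roundness
is the isoperimetric ratio 4πA/P² (1 for a circle) and the shape factor is
its reciprocal P²/4πA; the two are kept as separate parameters because
downstream feature vectors treat them as distinct named quantities. An
axis-ratio definition of roundness was considered and rejected: the
isoperimetric form is scale/rotation invariant without an ellipse fit, and
the reciprocal pair is self-consistent (their product is exactly 1, which the
tests assert). Units are pixels; physical units would require magnification
metadata and are out of scope.

**Membrane staining.** Staining extent is the stained fraction of the
membrane path length: stained arcs are index ranges over the outline's
vertex sequence (fractional endpoints interpolate linearly), arcs may wrap
past the origin, overlapping arcs are rejected. For a circular membrane this
reduces to θ/2π for a stained arc of angle θ.

## HER2 scoring

Per-cell staining completeness is retrieved by a graph-pattern query over the
serialized ontology (tumor cell → membrane component → staining-extent
attribute → quantification value); the generated query text is attached to
the result so an assessment can be audited. Membrane components are
recognized by display name and staining attributes by feature name
(case-insensitive), mirroring how the query would be phrased over class and
property names. A cell with conflicting staining values is an error, not a
silent choice.

The four assessment bins partition [0, 1]: complete [0.9, 1], moderate
[0.7, 0.9), incomplete [0.5, 0.7), unstained [0, 0.5). The printed form of
the moderate bin's upper bound ("9") is read as 0.9 — the only value under
which the bins partition the unit interval. Boundaries are half-open from
below per the printed interval notation, so exactly 0.9 counts as complete.

Classification applies the criteria in strict precedence — 3+ if the
complete fraction exceeds 0.10, else 2+ if moderate exceeds 0.10, else 1+ if
incomplete exceeds 0.10, else 0. The printed criteria are not mutually
exclusive and do not cover the simplex; precedence makes the function total
and deterministic, and when the else-branch is reached without >90% unstained
cells the call is still 0 but carries a warning flagging the deviation from
the printed 0-criterion. Thresholds are strict inequalities exactly as
printed; the test suite recovers the 3+ threshold empirically (the largest
non-3+ complete percentage in 100-cell cohorts is 10).

## Subsumption reasoning

The logic fragment is conjunction plus existential restriction over a single
"exhibits" role, without nesting — the smallest fragment in which every
worked example is expressible. In it, structural subsumption (every atom of
the subsumer matched by an atom of the subsumee, modulo an optional phenotype
hierarchy) is sound and complete, so the decision procedure is exact
set containment and the acceptance tests can compare it against a brute-force
oracle over the full 2^8 × 2^8 lattice of atom sets.

Knowledge bases are compiled from diagnosis processes: a diagnosis is defined
by the conjunction of its supporting phenotype atoms, and in cumulative mode
(default) inherits the atoms of diagnoses established at earlier stages —
implementing the progressive narrowing of a staged differential. A per-stage
(non-cumulative) mode is a switch. Contradicting evidence cannot live inside
a negation-free fragment, so exclusions are a post-filter: a diagnosis with
an exclusion atom present in the slide is never reported, whatever the
subsumption says. Atom identity is the first cross-reference code when one
is attached, else the case-folded, whitespace-collapsed label. Diagnoses with
no supporting evidence draw a warning and contribute no definition (they can
still exclude).

The reported subtype is the unique equivalent diagnosis when one exists;
otherwise the most specific implied diagnosis (largest definition), with ties
reported unresolved rather than broken arbitrarily. A slide with more atoms
than a definition is implied but not equivalent — "implied, most specific"
is the deliberate reading of that situation.

## Synthetic data

The generators produce every input the tests need; they emulate the *outputs*
of a segmentation stage, not images.

* `make_scene()` lays convex tumor blobs on a non-overlapping grid
  (24 random points' convex hull per blob), places per-tumor nuclei strictly
  inside with an 8 px boundary margin (nucleus radii 4–7 px, so containment
  is guaranteed, which is what makes the 100%-recovery acceptance check a
  property of the builder rather than luck), and scatters stray nuclei
  outside all tumors. Ground truth records the intended assignment.
* `make_cohort()` realizes a prescribed staining distribution exactly:
  largest-remainder rounding of fraction×n gives bin counts summing to n,
  and values are drawn uniformly within each bin.
* `exemplar_document()` reconstructs the worked examples (the 75%-stained
  HER2 cell, the back-to-back follicles, the three-stage cervical process
  with its 40% intracytoplasmic-mucin indicator, the three-possibility
  lymphoma differential, the three-phenotype cervical slide). Exemplars
  encode only what the examples state; unstated details (e.g. follicle
  component counts) are fixed minimally. The slide exemplar labels its
  mitotic finding "luminal mitosis" to match the diagnostic knowledge; the
  synonymous "apical mitosis" phrasing can be bridged with the phenotype
  hierarchy, but the exemplars do not need it.

All generators run on a local RNG stream seeded from the spec (the caller's
RNG state is saved and restored), so identical spec+seed yields
byte-identical output. What passing tests on these fixtures show is that the
pipeline is correct on geometry and documents with known ground truth; they
do not show robustness to real segmentation noise — overlapping tumors,
nuclei cut by region borders, mislabelled classes — nor anything about
staining calls from raw pixels, which the package never performs.

## Problem sizes and numerical notes

The default test run uses deliberately small instances: cohorts of 20–100
cells, scenes of 2–3 tumors with 3–5 nuclei each (50 seeds in the acceptance
property), 50 random documents for the roundtrip property, the full 65,536
pair lattice for the subsumption oracle, and Monte-Carlo area checks with
60,000 samples per polygon. Numerical choices: doubles are serialized with
shortest-roundtrip formatting; the indicator formula check uses relative
1e-9; polygon simplicity is checked by exact segment crossing (convex
polygons short-circuit); clipping orientation is normalized before
Sutherland–Hodgman; degenerate (zero-area) polygons are rejected rather than
scored.

## Limitations

* The Turtle/RDF-XML readers cover the package's own serialization profile,
  not arbitrary RDF (no blank nodes, collections, or `@base`).
* The reasoner's fragment has no negation, role chains, or nominals;
  contradictions are handled outside the logic.
* HER2 scoring implements the four-bin completeness criteria only — not a
  full clinical guideline with staining-intensity rules.
* Non-convex tumor regions fall back to a grid estimate of overlap; exact
  clipping of arbitrary simple polygons is not implemented.
* GraphML export is a hook for downstream graph learning; no training is
  performed in-package.
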