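# pathograph

Pathology knowledge — what a diseased tissue is made of, how its entities are
arranged, and how a pathologist reasons from findings to a diagnosis — is
usually locked inside slide pixels and free-text reports. `pathograph`
represents that knowledge as typed graphs and makes it computable. It is
aimed at computational-pathology developers and knowledge engineers who need
slide findings and diagnostic reasoning in a standardized, queryable form.

The package implements three graph families and the machinery around them:

* **Pathology entity graphs** — for a pathological entity *a*, the graph
  *G_a = ({a} ∪ E_a ∪ C_a ∪ Q_a, R_ee ∪ R_ec ∪ R_cq)*: the entity, its
  components (part–whole relation *R_ee*, acyclic), its pathological features
  (*R_ec*) and their quantitative parameters (*R_cq*), plus
  component→protein *express* edges. Entity graphs are built by hand or
  automatically from segmentation geometry (GeoJSON polygons), with the
  five-descriptor nuclear morphometry bundle (area, perimeter, roundness
  4πA/P², shape factor P²/4πA, solidity A/A_hull) attached per nucleus.
* **Phenotype graphs** — single-cell phenotypes (one cell), multi-cell
  phenotypes (entities plus spatial/behavioral relationship edges such as
  "back-to-back arrangement" or "invades"), and quantitative phenotypic
  indicators with content-MathML formulas. Phenotypes can be *expanded* with
  the entity graphs of their constituents.
* **Diagnosis graphs** — staged differential-diagnosis processes: each stage
  carries diagnostic possibilities split into established and excluded, with
  supporting and contradicting phenotype evidence.

Documents bundle these graphs with slide metadata and serialize to
**PathoML**, an OWL-based markup (canonical Turtle and RDF/XML), with a
verified write→read→write roundtrip. On top of the representation sit two
analyses:

* **Quantitative HER2 scoring** — a graph-pattern query retrieves membrane
  staining completeness per tumor cell (for a circular membrane,
  staining extent = θ/2π); the cohort distribution over the four bins
  complete [0.9, 1], moderate [0.7, 0.9), incomplete [0.5, 0.7), unstained
  [0, 0.5) yields the HER2 status by strict precedence: 3+ if >10% complete,
  else 2+ if >10% moderate, else 1+ if >10% incomplete, else 0.
* **Subsumption-based subtyping** — slide phenotypes and diagnostic knowledge
  are translated into conjunctions of existential phenotype atoms
  (∃exhibits.⟨phenotype⟩); a structural subsumption check (sound and complete
  for this fragment) decides which diagnoses the slide implies, which it is
  equivalent to, and which its findings exclude.

## Worked example

Score a synthetic HER2 immunohistochemistry cohort whose staining distribution
is 75% complete / 15% moderate / 5% incomplete / 5% unstained, going the long
way around through the PathoML serialization and the graph-pattern query:

```r
library(pathograph)

cohort <- make_cohort(fractions = c(0.75, 0.15, 0.05, 0.05),
                      n_cells = 20, seed = 1)
doc <- read_pathoml(write_pathoml(cohort))
rep <- her2_report(doc)
str(rep[c("status", "score", "fractions", "n_cells")])
#> List of 4
#>  $ status   : chr "3+"
#>  $ score    : num 3
#>  $ fractions:List of 4
#>   ..$ complete  : num 0.75
#>   ..$ moderate  : num 0.15
#>   ..$ incomplete: num 0.05
#>   ..$ unstained : num 0.05
#>  $ n_cells  : int 20
```

More than 10% of tumor cells show complete membrane staining, so the slide is
called HER2 3+ (score grade 3); the recovered bin fractions are exactly the
generator's.

Automatic subtyping of a cervical slide carrying three phenotypes (glandular
pattern, apoptotic body, luminal mitosis) against a three-stage diagnostic
process:

```r
kb_doc <- exemplar_document("cervical_fig6")
kb <- process_to_kb(kb_doc$processes[[1]], kb_doc)
print(kb$definitions[["HPVA"]])
#> <concept> HPVA ∃exhibits.apoptotic body ⊓ ∃exhibits.glandular pattern ⊓ ∃exhibits.luminal mitosis

slide <- slide_to_concept(exemplar_document("cervical_slide_fig11"))
res <- infer_subtype(slide, kb)
str(res[c("reported_subtype", "implied", "equivalent")])
#> List of 3
#>  $ reported_subtype: chr "HPVA"
#>  $ implied         : chr [1:2] "adenocarcinoma" "HPVA"
#>  $ equivalent      : chr "HPVA"
```

The slide's findings imply adenocarcinoma (they contain its defining glandular
pattern) and are equivalent to the HPV-associated adenocarcinoma concept, so
HPVA is reported.

A command-line wrapper covers the same pipelines
(`inst/cli/pathograph.R <build-peg|her2|subtype|validate|convert|fixtures|config>`).

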