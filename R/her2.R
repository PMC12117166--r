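# Quantitative HER2 scoring: graph-pattern query over the serialized
# ontology, bin distribution of membrane staining completeness, and the
# status call.

#' Query membrane staining completeness per tumor cell
#'
#' Executes a graph-pattern query over the document's serialized ontology:
#' individuals typed `NeoplasticCell`, linked through `hasComponent` to a
#' membrane component, whose staining-extent attribute is quantified by a
#' parameter with a `hasValue` assertion. The generated query pattern is
#' attached to the result (`attr(, "query")`) and logged so the assessment is
#' reviewable.
#'
#' @param doc A [patho_document()] (or PathoML text / a triple table from
#'   [pathoml_triples()]).
#' @param binding A [pathoml_binding()].
#' @param quiet Suppress the query log message.
#' @return Data frame with columns `cell_id`, `completeness`, one row per
#'   tumor cell carrying a membrane staining-extent parameter.
#' @export
query_completeness <- function(doc, binding = pathoml_binding(), quiet = FALSE) {
  b <- binding
  tr <- if (is.data.frame(doc)) doc
        else if (is.character(doc)) pathoml_triples(doc)
        else doc_to_triples(doc, b)
  query_text <- paste(
    "SELECT ?cell ?value WHERE {",
    "  ?cell a pml:NeoplasticCell ;",
    "        pml:hasComponent ?membrane .",
    "  ?membrane pml:hasAttribute ?attr .",
    "  ?attr pml:featureName ?fname ;",
    "        pml:quantification ?q .",
    "  ?q pml:hasValue ?value .",
    "  FILTER regex(str(?membrane), 'membrane', 'i')",
    "  FILTER regex(?fname, 'staining (extent|completeness)', 'i')",
    "}", sep = "\n")
  if (!quiet) message("graph-pattern query:\n", query_text)

  op <- b$objprop_map; dp <- b$dataprop_map
  cells <- tr$s[tr$p == RDF_TYPE & tr$o == b$class_map[["NeoplasticCell"]]]
  name_of <- function(s) {
    v <- tr$o[tr$s == s & tr$p == dp[["displayName"]]]
    if (length(v) == 0) iri_local(s) else v[1]
  }
  out <- list()
  for (cell in pg_sort(unique(cells))) {
    comps <- tr$o[tr$s == cell & tr$p == op[["hasComponent"]]]
    membranes <- comps[grepl("membrane", vapply(comps, name_of, ""),
                             ignore.case = TRUE)]
    vals <- numeric()
    for (m in membranes) {
      attrs <- tr$o[tr$s == m & tr$p == op[["hasAttribute"]]]
      for (a in attrs) {
        fname <- tr$o[tr$s == a & tr$p == dp[["featureName"]]]
        if (length(fname) == 0 ||
            !grepl("staining (extent|completeness)", fname[1],
                   ignore.case = TRUE)) next
        qs <- tr$o[tr$s == a & tr$p == op[["quantification"]]]
        for (q in qs) {
          v <- tr$o[tr$s == q & tr$p == dp[["hasValue"]]]
          if (length(v) > 0) vals <- c(vals, as.numeric(v[1]))
        }
      }
    }
    if (length(unique(vals)) > 1) {
      pg_ambiguity_error(
        sprintf("cell '%s' carries %d conflicting staining values",
                iri_local(cell), length(unique(vals))), ids = iri_local(cell))
    }
    if (length(vals) > 0) {
      out[[length(out) + 1]] <- data.frame(cell_id = iri_local(cell),
                                           completeness = vals[1],
                                           stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0) {
    data.frame(cell_id = character(), completeness = numeric(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  attr(res, "query") <- query_text
  res
}

her2_bins <- function() {
  data.frame(bin = c("complete", "moderate", "incomplete", "unstained"),
             lower = c(0.9, 0.7, 0.5, 0.0),
             upper = c(1.0, 0.9, 0.7, 0.5),
             stringsAsFactors = FALSE)
}

#' Staining-completeness distribution
#'
#' Bins per-cell membrane staining completeness into the four assessment bins
#' — complete `[0.9, 1]`, moderate `[0.7, 0.9)`, incomplete `[0.5, 0.7)`,
#' unstained `[0, 0.5)` — and returns the cohort fractions. Boundaries are
#' half-open from below, so a value of exactly 0.9 counts as complete.
#'
#' @param values Numeric vector of completeness values in `[0, 1]`.
#' @return Object of class `pg_staining_distribution`: list with `fractions`
#'   (named: complete, moderate, incomplete, unstained), `counts`, `n_cells`.
#' @export
staining_distribution <- function(values) {
  if (length(values) == 0) {
    pg_stop("pg_empty_cohort", "no staining values: empty cohort")
  }
  if (any(values < 0 | values > 1)) {
    pg_stop("pg_value_error", "staining completeness must lie in [0, 1]")
  }
  counts <- c(
    complete = sum(values >= 0.9),
    moderate = sum(values >= 0.7 & values < 0.9),
    incomplete = sum(values >= 0.5 & values < 0.7),
    unstained = sum(values < 0.5))
  structure(list(fractions = counts / length(values), counts = counts,
                 n_cells = length(values)),
            class = "pg_staining_distribution")
}

#' Classify HER2 status from a staining distribution
#'
#' Applies the assessment criteria in strict precedence: `3+` when more than
#' 10% of tumor cells show complete membrane staining; else `2+` when more
#' than 10% show moderate staining; else `1+` when more than 10% show
#' incomplete staining; else `0`. The printed criterion for status 0 requires
#' more than 90% unstained cells; when the else-branch is reached without
#' meeting it, the call is still `0` but a warning is recorded on the result.
#'
#' @param dist A [staining_distribution()] (or a numeric vector of four
#'   fractions in bin order).
#' @return Object of class `pg_her2_call`: list with `status` (`"3+"`, `"2+"`,
#'   `"1+"`, `"0"`), `score` (3, 2, 1, 0), `distribution`, `warnings`.
#' @export
classify_her2 <- function(dist) {
  if (is.numeric(dist)) {
    stopifnot(length(dist) == 4)
    dist <- structure(list(
      fractions = stats::setNames(dist, c("complete", "moderate",
                                          "incomplete", "unstained")),
      counts = NULL, n_cells = NA_integer_),
      class = "pg_staining_distribution")
  }
  f <- dist$fractions
  warnings <- character()
  if (f[["complete"]] > 0.10) {
    status <- "3+"
  } else if (f[["moderate"]] > 0.10) {
    status <- "2+"
  } else if (f[["incomplete"]] > 0.10) {
    status <- "1+"
  } else {
    status <- "0"
    if (f[["unstained"]] <= 0.90) {
      warnings <- c(warnings,
        "status 0 assigned although <=90% of tumor cells are unstained")
    }
  }
  structure(list(status = status,
                 score = c("3+" = 3, "2+" = 2, "1+" = 1, "0" = 0)[[status]],
                 distribution = dist, warnings = warnings),
            class = "pg_her2_call")
}

#' Full HER2 assessment of a PathoML document
#'
#' Convenience pipeline: [query_completeness()] then
#' [staining_distribution()] then [classify_her2()], returning a JSON-ready
#' report.
#'
#' @inheritParams query_completeness
#' @return List with `status`, `score`, `fractions`, `n_cells`, `warnings`,
#'   `per_cell` (data frame), `query`.
#' @export
her2_report <- function(doc, binding = pathoml_binding(), quiet = TRUE) {
  per_cell <- query_completeness(doc, binding = binding, quiet = quiet)
  dist <- staining_distribution(per_cell$completeness)
  call <- classify_her2(dist)
  list(status = call$status, score = call$score,
       fractions = as.list(dist$fractions), n_cells = dist$n_cells,
       warnings = call$warnings, per_cell = per_cell,
       query = attr(per_cell, "query"))
}

#' @export
print.pg_staining_distribution <- function(x, ...) {
  cat("<staining distribution> n =", x$n_cells, "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' @export
print.pg_her2_call <- function(x, ...) {
  cat("<HER2 call>", x$status, "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
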