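# Content-MathML support for quantitative-indicator formulas. Formulas are
# stored as literal XML and only interpreted when all referenced identifiers
# resolve to parameter names; supported operators cover arithmetic.

#' Evaluate a content-MathML formula over named parameter values
#'
#' Supports `apply` with `plus`, `minus`, `times`, `divide`, `power`, numeric
#' constants (`cn`) and identifiers (`ci`) bound to `values` by name.
#'
#' @param mathml Content-MathML string (with or without a `math` wrapper).
#' @param values Named numeric vector binding identifiers.
#' @return Numeric scalar.
#' @export
eval_mathml <- function(mathml, values = c()) {
  doc <- xml2::read_xml(mathml)
  node <- doc
  if (xml2::xml_name(node) == "math") {
    node <- xml2::xml_child(node)
  }
  eval_node <- function(nd) {
    nm <- xml2::xml_name(nd)
    if (nm == "cn") return(as.numeric(xml2::xml_text(nd)))
    if (nm == "ci") {
      key <- trimws(xml2::xml_text(nd))
      if (!key %in% names(values)) {
        pg_resolution_error(sprintf("unbound identifier '%s' in formula", key))
      }
      return(as.numeric(values[[key]]))
    }
    if (nm == "apply") {
      kids <- xml2::xml_children(nd)
      op <- xml2::xml_name(kids[[1]])
      args <- vapply(kids[-1], eval_node, 0)
      return(switch(op,
        plus = sum(args),
        times = prod(args),
        minus = if (length(args) == 1) -args else args[1] - sum(args[-1]),
        divide = args[1] / args[2],
        power = args[1]^args[2],
        pg_stop("pg_value_error", sprintf("unsupported MathML operator '%s'", op))
      ))
    }
    pg_stop("pg_value_error", sprintf("unsupported MathML element '%s'", nm))
  }
  eval_node(node)
}

# Convenience builder for the common ratio formula <ci>a</ci> / <ci>b</ci>.
mathml_ratio <- function(numerator, denominator) {
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         "<apply><divide/><ci>", numerator, "</ci><ci>", denominator,
         "</ci></apply></math>")
}
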