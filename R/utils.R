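# Internal helpers shared across modules.

# Locale-independent sort; canonical serialization depends on this being stable
# across platforms, so always radix.
pg_sort <- function(x) {
  if (is.null(x) || length(x) == 0) return(character())
  sort(x, method = "radix")
}

pg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pg_resolution_error <- function(msg, ids = character()) {
  pg_stop("pg_resolution_error", msg, ids = ids)
}
pg_cycle_error <- function(msg, cycle = character()) {
  pg_stop("pg_cycle_error", msg, cycle = cycle)
}
pg_geometry_error <- function(msg) pg_stop("pg_geometry_error", msg)
pg_ambiguity_error <- function(msg, ids = character()) {
  pg_stop("pg_ambiguity_error", msg, ids = ids)
}

# Ordered-pair relation sets are stored as two-column character data frames.
pg_pairs <- function(from = character(), to = character()) {
  data.frame(from = as.character(from), to = as.character(to),
             stringsAsFactors = FALSE)
}

as_pg_pairs <- function(x) {
  if (is.null(x)) return(pg_pairs())
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    return(pg_pairs(x[[1]], x[[2]]))
  }
  if (is.matrix(x)) return(pg_pairs(x[, 1], x[, 2]))
  if (is.list(x)) {
    if (length(x) == 0) return(pg_pairs())
    return(pg_pairs(vapply(x, `[`, "", 1), vapply(x, `[`, "", 2)))
  }
  stop("cannot interpret relation set")
}

# Deterministic id factory: <Class>-<counter>, counters per class.
pg_id_factory <- function() {
  counters <- new.env(parent = emptyenv())
  function(class) {
    n <- if (exists(class, envir = counters)) get(class, envir = counters) else 0L
    n <- n + 1L
    assign(class, n, envir = counters)
    paste0(class, "-", n)
  }
}

# Run code under a fixed seed without touching the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shortest decimal string that parses back to exactly x; keeps canonical
# serializations byte-stable under write -> read -> write.
pg_format_double <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) stop("non-finite value cannot be serialized")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = -1)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g", width = -1)
  }, "")
}

# Violation records returned by validators.
pg_violation <- function(type, id, clause, message) {
  data.frame(type = type, id = id, clause = clause, message = message,
             stringsAsFactors = FALSE)
}

pg_no_violations <- function() {
  data.frame(type = character(), id = character(), clause = character(),
             message = character(), stringsAsFactors = FALSE)
}

rbind_violations <- function(...) {
  xs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(xs) == 0) return(pg_no_violations())
  do.call(rbind, xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
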