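# Polygon morphometrics. All coordinates are pixels (image convention);
# results are pixel-squared areas and dimensionless shape descriptors.

as_outline <- function(outline) {
  outline <- as.matrix(outline)
  storage.mode(outline) <- "double"
  if (ncol(outline) != 2) pg_geometry_error("outline must be an n x 2 matrix")
  # Drop a duplicated closing vertex.
  n <- nrow(outline)
  if (n >= 2 && all(outline[1, ] == outline[n, ])) outline <- outline[-n, , drop = FALSE]
  outline
}

# Proper segment crossing test for non-adjacent edges (shared endpoints and
# collinear touching are not treated as self-intersection).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

is_simple_polygon <- function(outline) {
  n <- nrow(outline)
  if (n < 3) return(FALSE)
  if (is_convex_polygon(outline)) return(TRUE)  # convex => simple; skips O(n^2)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next  # adjacent around the wrap
      if (segments_cross(outline[i, ], outline[idx(i + 1), ],
                         outline[j, ], outline[idx(j + 1), ])) return(FALSE)
    }
  }
  TRUE
}

#' Polygon area (shoelace)
#'
#' Signed shoelace area, returned as a positive value regardless of vertex
#' orientation. The polygon must be simple (non-self-intersecting).
#'
#' @param outline `n x 2` numeric matrix of vertices (a duplicated closing
#'   vertex is tolerated).
#' @return Area in px^2.
#' @export
polygon_area <- function(outline) {
  o <- as_outline(outline)
  if (nrow(o) < 3) pg_geometry_error("polygon needs at least 3 vertices")
  if (!is_simple_polygon(o)) pg_geometry_error("polygon is self-intersecting")
  x <- o[, 1]; y <- o[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#' @inheritParams polygon_area
#' @return Perimeter in px.
#' @export
polygon_perimeter <- function(outline) {
  o <- as_outline(outline)
  d <- rbind(o[-1, , drop = FALSE], o[1, , drop = FALSE]) - o
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(outline) {
  o <- as_outline(outline)
  x <- o[, 1]; y <- o[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(o))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Even-odd point-in-polygon test.
point_in_polygon <- function(px, py, outline) {
  o <- as_outline(outline)
  n <- nrow(o)
  x <- o[, 1]; y <- o[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    jj <- j[k]
    cond <- ((y[k] > py) != (y[jj] > py)) &
      (px < (x[jj] - x[k]) * (py - y[k]) / (y[jj] - y[k]) + x[k])
    inside <- xor(inside, cond & !is.na(cond))
  }
  inside
}

is_convex_polygon <- function(outline) {
  o <- as_outline(outline)
  n <- nrow(o)
  if (n < 4) return(TRUE)
  s <- 0
  for (i in seq_len(n)) {
    a <- o[i, ]; b <- o[(i %% n) + 1, ]; c_ <- o[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Sutherland-Hodgman clip of `subject` against a convex `clip` polygon.
clip_polygon_convex <- function(subject, clip) {
  clip <- as_outline(clip)
  # Ensure counter-clockwise orientation of the clip polygon (shoelace sign).
  x <- clip[, 1]; y <- clip[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  }
  out <- as_outline(subject)
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[(i %% nc) + 1, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    }
    inter <- function(p, q) {
      # Intersection of segment pq with the infinite edge line ab.
      dx <- q[1] - p[1]; dy <- q[2] - p[2]
      ex <- b[1] - a[1]; ey <- b[2] - a[2]
      denom <- ex * dy - ey * dx
      t <- (ex * (a[2] - p[2]) - ey * (a[1] - p[1])) / denom
      c(p[1] + t * dx, p[2] + t * dy)
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (k in seq_len(np)) {
      p <- inp[k, ]; q <- inp[(k %% np) + 1, ]
      pi_ <- inside(p); qi <- inside(q)
      if (pi_ && qi) out <- rbind(out, q)
      else if (pi_ && !qi) out <- rbind(out, inter(p, q))
      else if (!pi_ && qi) out <- rbind(out, inter(p, q), q)
    }
  }
  out
}

# Fraction of polygon `inner`'s area overlapping polygon `outer`.
# Exact (Sutherland-Hodgman) when `outer` is convex; otherwise a deterministic
# dense-grid point-in-polygon estimate.
overlap_fraction <- function(inner, outer, grid_n = 48) {
  ai <- polygon_area(inner)
  if (ai <= 0) return(0)
  if (is_convex_polygon(outer)) {
    clp <- clip_polygon_convex(inner, outer)
    if (nrow(clp) < 3) return(0)
    x <- clp[, 1]; y <- clp[, 2]
    a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    return(min(1, a / ai))
  }
  o <- as_outline(inner)
  xs <- seq(min(o[, 1]), max(o[, 1]), length.out = grid_n)
  ys <- seq(min(o[, 2]), max(o[, 2]), length.out = grid_n)
  gx <- rep(xs, times = grid_n); gy <- rep(ys, each = grid_n)
  in_inner <- point_in_polygon(gx, gy, inner)
  if (!any(in_inner)) return(0)
  in_outer <- point_in_polygon(gx[in_inner], gy[in_inner], outer)
  mean(in_outer)
}

#' Shape descriptors of a simple polygon
#'
#' Computes the standard nuclear-morphometry descriptors:
#' roundness `4*pi*A/P^2` (1 for a circle), shape factor `P^2/(4*pi*A)`
#' (the compactness ratio, reciprocal of roundness), and solidity
#' `A / area(convex hull)`.
#'
#' @inheritParams polygon_area
#' @return List with `area`, `perimeter`, `roundness`, `shape_factor`,
#'   `solidity`.
#' @export
shape_params <- function(outline) {
  o <- as_outline(outline)
  a <- polygon_area(o)
  if (a <= 0) pg_geometry_error("degenerate (zero-area) polygon")
  p <- polygon_perimeter(o)
  hull <- o[grDevices::chull(o[, 1], o[, 2]), , drop = FALSE]
  hull_a <- polygon_area(hull)
  list(area = a, perimeter = p,
       roundness = 4 * pi * a / p^2,
       shape_factor = p^2 / (4 * pi * a),
       solidity = a / hull_a)
}

#' Membrane staining extent
#'
#' Fraction of a cell membrane's perimeter covered by antigen staining. Arcs
#' are index ranges over the outline's vertex sequence, traversed forward with
#' wrap-around; fractional endpoints interpolate along the edge linearly. For a
#' circular membrane with a stained arc of angle `theta`, the extent equals
#' `theta / (2*pi)`.
#'
#' @param membrane_outline `n x 2` vertex matrix of the (closed) membrane.
#' @param stained_arcs List of numeric pairs `c(start, end)` of (possibly
#'   fractional) vertex positions in `[1, n+1)`; traversal runs forward from
#'   start to end, wrapping past vertex `n` back to 1.
#' @return List with `total_perimeter`, `stained_length`, `extent`, and
#'   `theta` (`extent * 2*pi`, the equivalent circular arc).
#' @export
staining_extent <- function(membrane_outline, stained_arcs = list()) {
  o <- as_outline(membrane_outline)
  n <- nrow(o)
  if (n < 3) pg_geometry_error("membrane outline needs at least 3 vertices")
  seg_len <- {
    d <- rbind(o[-1, , drop = FALSE], o[1, , drop = FALSE]) - o
    sqrt(rowSums(d^2))
  }
  cum <- c(0, cumsum(seg_len))   # arc length at vertex positions 1..n+1
  total <- cum[n + 1]
  pos_to_len <- function(pos) {
    # Vertex position in [1, n+1) -> arc length from vertex 1.
    pos <- (pos - 1) %% n + 1
    i <- floor(pos)
    frac <- pos - i
    cum[i] + frac * seg_len[i]
  }
  intervals <- list()
  stained <- 0
  for (arc in stained_arcs) {
    if (length(arc) != 2) pg_geometry_error("each arc must be c(start, end)")
    s <- pos_to_len(arc[1]); e <- pos_to_len(arc[2])
    if (abs((arc[2] - arc[1]) %% n) < 1e-12 && arc[2] != arc[1]) {
      # Full-loop arc (e.g. c(1, n+1)): whole membrane.
      ivs <- list(c(0, total))
    } else if (e >= s) {
      ivs <- list(c(s, e))
    } else {
      ivs <- list(c(s, total), c(0, e))
    }
    for (iv in ivs) {
      for (prev in intervals) {
        if (iv[1] < prev[2] - 1e-9 && prev[1] < iv[2] - 1e-9) {
          pg_geometry_error("stained arcs overlap")
        }
      }
      intervals <- c(intervals, list(iv))
      stained <- stained + (iv[2] - iv[1])
    }
  }
  if (stained > total + 1e-9) pg_geometry_error("stained length exceeds perimeter")
  stained <- min(stained, total)
  list(total_perimeter = total, stained_length = stained,
       extent = stained / total, theta = 2 * pi * stained / total)
}

#' Standard morphometric feature bundle for a nucleus
#'
#' Computes the package's five-descriptor set (area, perimeter, roundness,
#' shape factor, solidity) for one nucleus outline and wraps each as a named
#' feature with one quantitative parameter, ready for insertion into an entity
#' graph.
#'
#' @param nucleus_outline `n x 2` vertex matrix.
#' @param owner_id Entity id the features describe.
#' @param id_prefix Prefix for generated feature/parameter ids.
#' @param feature_set Character vector selecting and ordering the descriptors;
#'   defaults to all five.
#' @return List with `features` (five [feature_node()]) and `params`
#'   (five [quant_param()]).
#' @export
feature_bundle <- function(nucleus_outline, owner_id,
                           id_prefix = owner_id,
                           feature_set = c("area", "perimeter", "roundness",
                                           "shape_factor", "solidity")) {
  sp <- shape_params(nucleus_outline)
  units <- c(area = "px^2", perimeter = "px", roundness = "",
             shape_factor = "", solidity = "")
  feats <- list(); pars <- list()
  for (nm in feature_set) {
    fid <- paste0(id_prefix, "-feat-", nm)
    qid <- paste0(id_prefix, "-param-", nm)
    feats[[nm]] <- feature_node(fid, gsub("_", " ", nm), owner_id)
    pars[[nm]] <- quant_param(qid, gsub("_", " ", nm), sp[[nm]],
                              unit = units[[nm]], feature_id = fid)
  }
  list(features = unname(feats), params = unname(pars))
}

# Regular n-gon as an outline matrix; the geometry workhorse for fixtures.
regular_polygon <- function(cx, cy, r, n, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}
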