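#' Areal geometry objects
#'
#' An `areal_geometry` holds an ordered set of areas together with their
#' centroids and, optionally, polygon outlines or lattice cell indices.
#' Centroids are planar coordinates; distances derived from them are
#' Euclidean, in whatever length unit the coordinates carry.
#'
#' @param area_ids character or integer vector of unique area identifiers.
#' @param centroids numeric matrix with one row per area and columns (x, y).
#' @param shapes optional list of polygon outlines, one per area; each a
#'   closed two-column coordinate matrix (first vertex repeated last).
#' @param lattice optional list with elements `rows`, `cols`, `spacing`,
#'   `row`, `col` describing a rectangular lattice (row-major ordering).
#' @param units length-unit tag carried through for transparency, e.g.
#'   `"km"` or `"lattice"`.
#' @return An object of class `areal_geometry`.
#' @export
areal_geometry <- function(area_ids, centroids, shapes = NULL, lattice = NULL,
                           units = "unit") {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  if (n < 1L) stop("geometry needs at least one area")
  if (anyDuplicated(area_ids)) stop("area_ids must be unique")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != n || ncol(centroids) != 2L)
    stop("centroids must be an N x 2 matrix matching area_ids")
  if (!is.null(shapes)) {
    if (length(shapes) != n) stop("shapes must have one polygon per area")
    for (s in shapes) {
      s <- as.matrix(s)
      if (nrow(s) < 4L || any(s[1L, ] != s[nrow(s), ]))
        stop("each polygon must be closed (first vertex repeated last) with >= 3 distinct vertices")
      if (abs(polygon_area(s)) <= 0)
        stop("degenerate polygon with zero area")
    }
  }
  structure(
    list(area_ids = area_ids, centroids = centroids, shapes = shapes,
         lattice = lattice, units = units),
    class = "areal_geometry"
  )
}

#' @export
print.areal_geometry <- function(x, ...) {
  kind <- if (!is.null(x$lattice)) {
    sprintf("%d x %d lattice", x$lattice$rows, x$lattice$cols)
  } else if (!is.null(x$shapes)) "polygon map" else "centroid-only map"
  cat(sprintf("areal_geometry: %d areas (%s), units = %s\n",
              length(x$area_ids), kind, x$units))
  invisible(x)
}

n_areas <- function(geom) length(geom$area_ids)

# signed shoelace area of a closed ring
polygon_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

# centroid of a closed ring (shoelace moments)
polygon_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1L]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1L]) * cr) / (6 * a)
  c(cx, cy)
}

#' Rectangular lattice geometry
#'
#' Builds an `rows x cols` lattice of square cells, ordered row-major, with
#' centroids on a regular grid. Cells are squares of side `spacing` centred
#' on the grid points, so the full polygon machinery (contiguity, GeoJSON
#' export) works on lattices too.
#'
#' @param rows,cols positive integers.
#' @param spacing positive centroid spacing (= cell side).
#' @return An [areal_geometry] with `rows * cols` areas.
#' @examples
#' g <- grid_lattice(12, 12)
#' n_distinct <- length(g$area_ids)  # 144
#' @export
grid_lattice <- function(rows, cols, spacing = 1) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("rows and cols must be positive integers")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  rows <- as.integer(rows); cols <- as.integer(cols)
  row_idx <- rep(seq_len(rows), each = cols)
  col_idx <- rep(seq_len(cols), times = rows)
  cx <- (col_idx - 1) * spacing
  cy <- (row_idx - 1) * spacing
  h <- spacing / 2
  shapes <- lapply(seq_along(cx), function(i) {
    cbind(c(cx[i] - h, cx[i] + h, cx[i] + h, cx[i] - h, cx[i] - h),
          c(cy[i] - h, cy[i] - h, cy[i] + h, cy[i] + h, cy[i] - h))
  })
  areal_geometry(
    area_ids = sprintf("cell_%03d", seq_along(cx)),
    centroids = cbind(cx, cy),
    shapes = shapes,
    lattice = list(rows = rows, cols = cols, spacing = spacing,
                   row = row_idx, col = col_idx),
    units = "lattice"
  )
}

#' Pairwise Euclidean centroid distances
#'
#' @param geom an [areal_geometry].
#' @return A symmetric N x N matrix with zero diagonal; `dimnames` carry the
#'   area ids. Coincident centroids (e.g. one area nested in another) give a
#'   zero off-diagonal distance, which is valid input for the kernels that
#'   sanitise non-finite weights downstream.
#' @export
pairwise_centroid_distance <- function(geom) {
  stopifnot(inherits(geom, "areal_geometry"))
  d <- as.matrix(stats::dist(geom$centroids))
  dimnames(d) <- list(geom$area_ids, geom$area_ids)
  d
}

#' First-order contiguity graph
#'
#' Neighbours are areas whose boundaries touch. On a lattice this is queen
#' contiguity (common edge or vertex) when `include_vertex = TRUE` and rook
#' (common edge only) otherwise. For polygon maps, boundaries are compared
#' vertex-wise after snapping coordinates to `snap`: two areas are
#' neighbours if they share at least two boundary vertices (a common edge),
#' or at least one when `include_vertex = TRUE`.
#'
#' @param geom an [areal_geometry] with shapes or lattice indices.
#' @param include_vertex logical; count single shared vertices as contact.
#' @param snap coordinate snapping tolerance for polygon vertex matching.
#' @return A `contiguity_graph`: list with `n`, `area_ids` and
#'   `neighbours`, a list of integer vectors of first-order neighbour
#'   indices.
#' @export
contiguity <- function(geom, include_vertex = TRUE, snap = 1e-9) {
  stopifnot(inherits(geom, "areal_geometry"))
  n <- n_areas(geom)
  if (!is.null(geom$lattice)) {
    lat <- geom$lattice
    nb <- lapply(seq_len(n), function(i) {
      dr <- abs(lat$row - lat$row[i])
      dc <- abs(lat$col - lat$col[i])
      hit <- if (include_vertex) pmax(dr, dc) == 1L else (dr + dc) == 1L
      which(hit)
    })
  } else if (!is.null(geom$shapes)) {
    nb <- polygon_contiguity(geom$shapes, include_vertex, snap)
  } else {
    stop("unsupported operation: geometry has centroids only (no shapes or lattice)")
  }
  structure(list(n = n, area_ids = geom$area_ids, neighbours = nb),
            class = "contiguity_graph")
}

# vertex-sharing contiguity for polygon lists
polygon_contiguity <- function(shapes, include_vertex, snap) {
  n <- length(shapes)
  keys <- lapply(shapes, function(s) {
    s <- as.matrix(s)
    s <- s[-nrow(s), , drop = FALSE]             # drop repeated closing vertex
    unique(paste(round(s[, 1L] / snap), round(s[, 2L] / snap)))
  })
  # invert: vertex key -> areas touching it
  vert <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (k in keys[[i]]) {
      vert[[k]] <- c(vert[[k]], i)
    }
  }
  shared <- matrix(0L, n, n)
  for (k in ls(vert)) {
    ar <- unique(vert[[k]])
    if (length(ar) > 1L) {
      for (a in ar) shared[a, ar] <- shared[a, ar] + 1L
    }
  }
  diag(shared) <- 0L
  need <- if (include_vertex) 1L else 2L
  lapply(seq_len(n), function(i) which(shared[i, ] >= need))
}

#' @export
print.contiguity_graph <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat(sprintf("contiguity_graph: %d areas, %d undirected edges, mean degree %.2f\n",
              x$n, sum(deg) / 2, mean(deg)))
  invisible(x)
}

contiguity_igraph <- function(graph) {
  deg <- lengths(graph$neighbours)
  from <- rep(seq_len(graph$n), deg)
  to <- unlist(graph$neighbours, use.names = FALSE)
  keep <- from < to
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (any(keep)) g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  g
}

# binary first-order adjacency matrix from a contiguity graph
adjacency_matrix <- function(graph) {
  a <- matrix(0, graph$n, graph$n)
  for (i in seq_len(graph$n)) a[i, graph$neighbours[[i]]] <- 1
  dimnames(a) <- list(graph$area_ids, graph$area_ids)
  a
}

#' Neighbourhood order (graph distance) matrix
#'
#' Computes the order of adjacency between every pair of areas: 1 for
#' first-order neighbours, 2 for neighbours of neighbours, and so on, as
#' shortest-path lengths in the first-order contiguity graph. Pairs further
#' apart than `max_order`, and pairs in different connected components,
#' receive `NA` (the unreachable sentinel).
#'
#' @param graph a `contiguity_graph`.
#' @param max_order positive integer; orders above this are not resolved.
#' @return Integer N x N matrix, zero diagonal, symmetric, `NA` sentinel.
#' @export
adjacency_order <- function(graph, max_order = 3L) {
  stopifnot(inherits(graph, "contiguity_graph"), max_order >= 1)
  g <- contiguity_igraph(graph)
  d <- igraph::distances(g)
  ord <- matrix(NA_integer_, graph$n, graph$n)
  ok <- is.finite(d) & d <= max_order
  ord[ok] <- as.integer(d[ok])
  dimnames(ord) <- list(graph$area_ids, graph$area_ids)
  ord
}
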