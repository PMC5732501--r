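#' Read a GAL adjacency-list file
#'
#' Reads the plain-text GAL dialect used by spdep/PySAL: an optional header
#' line (either `N` alone or `0 N <shapefile> <id>`), then for each area a
#' line `id count` followed by a line listing the neighbour ids.
#'
#' @param path file path.
#' @return A `contiguity_graph`.
#' @export
read_gal <- function(path) {
  tok_lines <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  tok_lines <- tok_lines[lengths(tok_lines) > 0L]
  hdr <- tok_lines[[1L]]
  n <- if (length(hdr) == 1L) as.integer(hdr[1L]) else as.integer(hdr[2L])
  body <- unlist(tok_lines[-1L], use.names = FALSE)
  ids <- character(n)
  nbr_ids <- vector("list", n)
  pos <- 1L
  for (i in seq_len(n)) {
    ids[i] <- body[pos]
    k <- as.integer(body[pos + 1L])
    nbr_ids[[i]] <- if (k > 0L) body[pos + 2L + seq_len(k) - 1L] else character()
    pos <- pos + 2L + k
  }
  if (anyDuplicated(ids)) stop("duplicate area ids in GAL file")
  nb <- lapply(nbr_ids, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx)) stop("GAL file references unknown area id: ",
                         paste(v[is.na(idx)], collapse = ", "))
    sort(idx)
  })
  # enforce symmetry (a GAL file should be symmetric; tolerate one-sided lists)
  for (i in seq_len(n)) for (j in nb[[i]]) {
    if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
  }
  structure(list(n = n, area_ids = ids, neighbours = nb),
            class = "contiguity_graph")
}

#' Write a contiguity graph as a GAL file
#'
#' @param graph a `contiguity_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "contiguity_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(graph$n), con)
  for (i in seq_len(graph$n)) {
    nb <- graph$neighbours[[i]]
    writeLines(paste(graph$area_ids[i], length(nb)), con)
    writeLines(paste(graph$area_ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read polygon features from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon features; the
#' area identifier is taken from a named property. Centroids are computed
#' from the outer ring by the shoelace formula (area-weighted over
#' MultiPolygon parts); only the outer rings are retained for contiguity.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the area id.
#' @param units length-unit tag for the coordinates.
#' @return An [areal_geometry].
#' @export
read_geojson <- function(path, id_property = "id", units = "unit") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_property]]
    if (is.null(v)) v <- f$id
    if (is.null(v)) stop("feature without '", id_property, "' property")
    as.character(v)
  }, character(1))
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    storage.mode(m) <- "double"
    m
  }
  shapes <- vector("list", length(feats))
  cents <- matrix(0, length(feats), 2L)
  for (i in seq_along(feats)) {
    geomj <- feats[[i]]$geometry
    rings <- switch(geomj$type,
      Polygon = list(ring_mat(geomj$coordinates[[1L]])),
      MultiPolygon = lapply(geomj$coordinates, function(p) ring_mat(p[[1L]])),
      stop("unsupported geometry type: ", geomj$type))
    areas <- vapply(rings, function(r) abs(polygon_area(r)), numeric(1))
    cent <- vapply(rings, polygon_centroid, numeric(2))
    cents[i, ] <- as.numeric(cent %*% (areas / sum(areas)))
    # concatenate parts into one closed outline per area (vertex-based
    # contiguity only needs the union of boundary vertices)
    shapes[[i]] <- do.call(rbind, rings)
    if (any(shapes[[i]][1L, ] != shapes[[i]][nrow(shapes[[i]]), ]))
      shapes[[i]] <- rbind(shapes[[i]], shapes[[i]][1L, ])
  }
  areal_geometry(ids, cents, shapes = shapes, units = units)
}

#' Write an areal geometry and per-area values as GeoJSON
#'
#' Emits a FeatureCollection with one Polygon per area and the columns of
#' `values` as feature properties — a minimal choropleth export.
#'
#' @param geom an [areal_geometry] with shapes.
#' @param path output path.
#' @param values optional data frame of per-area properties (N rows).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geom, path, values = NULL) {
  stopifnot(inherits(geom, "areal_geometry"))
  if (is.null(geom$shapes)) stop("geometry has no shapes to export")
  n <- n_areas(geom)
  if (!is.null(values)) stopifnot(nrow(values) == n)
  feats <- lapply(seq_len(n), function(i) {
    props <- list(id = geom$area_ids[i])
    if (!is.null(values)) props <- c(props, as.list(values[i, , drop = FALSE]))
    ring <- geom$shapes[[i]]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a weights matrix to disk
#'
#' Two plain-text formats: a dense CSV (`format = "csv"`, area ids as header
#' and row names) or the sparse triple dialect (`format = "gwt"`: lines
#' `i j w` for nonzero entries). The spec label and construction parameters
#' go to a sidecar JSON header `<path>.json`.
#'
#' @param W a `weights_matrix`.
#' @param path output file.
#' @param format `"csv"` or `"gwt"`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path, format = c("csv", "gwt")) {
  stopifnot(inherits(W, "weights_matrix"))
  format <- match.arg(format)
  ids <- rownames(W$w)
  if (format == "csv") {
    df <- data.frame(area_id = ids, W$w, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    nz <- which(W$w != 0, arr.ind = TRUE)
    df <- data.frame(i = ids[nz[, 1L]], j = ids[nz[, 2L]],
                     w = W$w[nz])
    utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  side <- c(list(label = W$spec$label, family = W$spec$family,
                 kernel = W$spec$kernel, standardised = W$standardised,
                 n = nrow(W$w), format = format),
            W$spec$params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a weights matrix written by [write_weights()]
#'
#' @param path the data file written by [write_weights()]; the sidecar
#'   `<path>.json` must sit next to it.
#' @return A `weights_matrix`.
#' @export
read_weights <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(side$format, "csv")) {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1L]])
    w <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    tr <- utils::read.table(path, header = FALSE,
                            col.names = c("i", "j", "w"),
                            colClasses = c("character", "character", "numeric"))
    ids <- sort(unique(c(tr$i, tr$j)))
    w <- matrix(0, length(ids), length(ids))
    w[cbind(match(tr$i, ids), match(tr$j, ids))] <- tr$w
  }
  dimnames(w) <- list(ids, ids)
  params <- side[setdiff(names(side),
                         c("label", "family", "kernel", "standardised", "n",
                           "format"))]
  new_weights_matrix(w, spec = list(label = side$label, family = side$family,
                                    kernel = side$kernel, params = params),
                     standardised = isTRUE(side$standardised))
}
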