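#' Spatial weights matrices
#'
#' A `weights_matrix` wraps an N x N nonnegative matrix of pairwise
#' influence between areas together with the label and parameters of the
#' construction that produced it. Before row standardisation the matrix is
#' symmetric with a zero diagonal, as required for the structured random
#' effects to form a Markov random field.
#'
#' @param w numeric N x N matrix, finite, nonnegative, zero diagonal.
#' @param spec list with `label`, `family`, `kernel`, `params`.
#' @param standardised logical; `TRUE` once rows have been scaled to sum
#'   to one.
#' @return A `weights_matrix` object.
#' @export
new_weights_matrix <- function(w, spec = list(label = "custom",
                                              family = "custom",
                                              kernel = "custom",
                                              params = list()),
                               standardised = FALSE) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weights matrix must be square")
  if (any(!is.finite(w))) stop("weights matrix contains non-finite entries")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (any(diag(w) != 0)) stop("weights matrix must have a zero diagonal")
  if (!standardised && max(abs(w - t(w))) > 1e-12)
    stop("unstandardised weights matrix must be symmetric")
  structure(list(w = w, spec = spec, standardised = standardised),
            class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  cat(sprintf("weights_matrix %s (%s/%s): %d areas, %d nonzero entries%s\n",
              x$spec$label, x$spec$family, x$spec$kernel, nrow(x$w),
              sum(x$w != 0), if (x$standardised) ", row-standardised" else ""))
  invisible(x)
}

#' The 17 studied weights specifications
#'
#' Labels of the four families compared in the study: adjacency (`A1`
#' binary first-order, `A2` third-order with geometrically decaying order
#' weights), geographic distance (`D1`-`D3` inverse distance to the powers
#' 1, 2, 5; `D4` exponential decay; `D5` Gaussian decay), covariate
#' distance (`C1`-`C5`, same kernels on absolute covariate differences) and
#' hybrid (`H1`-`H5`, kernels on the product of geographic and covariate
#' distances).
#'
#' @format A character vector of 17 labels.
#' @export
weights_spec_labels <- c("A1", "A2", paste0("D", 1:5), paste0("C", 1:5),
                         paste0("H", 1:5))

#' Adjacency-based weights of order n
#'
#' `w_ij = omega_k` when areas i and j are k-th order neighbours for
#' `k <= n`, and 0 otherwise. With `n = 1`, `omega = 1` this is the binary
#' first-order adjacency matrix. Order is shortest-path length in the
#' first-order contiguity graph.
#'
#' @param graph a `contiguity_graph`.
#' @param n highest neighbour order assigned a weight.
#' @param omega positive weights for orders `1:n`, typically decreasing.
#' @return An unstandardised `weights_matrix`.
#' @export
adjacency_weights <- function(graph, n = 1L, omega = 1) {
  stopifnot(inherits(graph, "contiguity_graph"))
  if (length(omega) != n) stop("omega must have length n")
  if (any(omega <= 0)) stop("omega must be positive")
  ord <- adjacency_order(graph, max_order = n)
  w <- matrix(0, graph$n, graph$n)
  for (k in seq_len(n)) w[which(ord == k)] <- omega[k]
  dimnames(w) <- list(graph$area_ids, graph$area_ids)
  label <- if (n == 1L) "A1" else "A2"
  new_weights_matrix(w, spec = list(
    label = label, family = "adjacency", kernel = "binary-order",
    params = list(n = n, omega = omega)))
}

#' Inverse distance power kernel
#'
#' Raw (unsanitised) weights `w_ij = (1 / d_ij)^k`. Zero distances yield
#' non-finite entries by design; [sanitise_symmetrise()] repairs them.
#'
#' @param dist symmetric nonnegative distance matrix with zero diagonal.
#' @param k positive integer exponent.
#' @return A raw numeric matrix with zero diagonal, possibly non-finite
#'   off-diagonal entries.
#' @export
inverse_power_weights <- function(dist, k = 1L) {
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  w <- (1 / dist)^k
  diag(w) <- 0
  w
}

#' Decay and bandwidth scale from the mean pairwise distance
#'
#' The decay parameter of the exponential kernel and the bandwidth of the
#' Gaussian kernel are tied to the scale of the map:
#' `lambda = numerator / mean(d_ij)` over all pairs `i != j`, and
#' `b = 1 / lambda`. This makes the resulting weights invariant to a
#' rescaling of the distance units.
#'
#' @param dist symmetric distance matrix (N >= 2).
#' @param numerator the scale constant (default 10).
#' @return List with `lambda` and `b`.
#' @export
decay_scale <- function(dist, numerator = 10) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 2L) stop("need at least two areas to compute a mean distance")
  mean_d <- mean(dist[row(dist) != col(dist)])
  if (mean_d <= 0) stop("mean pairwise distance is zero; decay scale undefined")
  lambda <- numerator / mean_d
  list(lambda = lambda, b = 1 / lambda)
}

#' Exponential decay kernel
#'
#' `w_ij = exp(-lambda * d_ij)` off the diagonal; diagonal zero.
#'
#' @param dist distance matrix.
#' @param lambda positive decay rate.
#' @return Raw numeric matrix.
#' @export
exponential_decay_weights <- function(dist, lambda) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  w <- exp(-lambda * dist)
  diag(w) <- 0
  w
}

#' Gaussian decay kernel
#'
#' `w_ij = exp(-d_ij^2 / (2 b^2))` off the diagonal; diagonal zero.
#'
#' @param dist distance matrix.
#' @param b positive bandwidth.
#' @return Raw numeric matrix.
#' @export
gaussian_decay_weights <- function(dist, b) {
  if (!is.numeric(b) || b <= 0) stop("b must be positive")
  w <- exp(-dist^2 / (2 * b^2))
  diag(w) <- 0
  w
}

#' Covariate distances
#'
#' `delta_ij = |x_i - x_j|`: the absolute difference between covariate
#' values, used in place of geographic distance for the covariate-smoothing
#' weights families.
#'
#' @param x per-area covariate vector.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
covariate_distances <- function(x) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(x), names(x))
  d
}

#' Hybrid geographic-covariate distances
#'
#' Elementwise product `d_ij * delta_ij` of geographic and covariate
#' distances.
#'
#' @param d geographic distance matrix.
#' @param delta covariate distance matrix of the same shape.
#' @return Elementwise product matrix.
#' @export
hybrid_distances <- function(d, delta) {
  if (!all(dim(d) == dim(delta))) stop("distance matrices must have the same shape")
  d * delta
}

#' Sanitise non-finite weights and enforce symmetry
#'
#' Kernels of inverse distances produce non-finite weights wherever the
#' distance is zero (nested areas with a common centroid; tied covariate
#' values). Per row, non-finite entries are replaced by the maximum finite
#' off-diagonal value in that row; symmetry is then restored by overwriting
#' the lower triangle with the transpose of the upper triangle.
#'
#' @param raw square numeric matrix with zero diagonal.
#' @param spec spec list recorded on the result.
#' @return An unstandardised, finite, symmetric `weights_matrix`.
#' @export
sanitise_symmetrise <- function(raw, spec = list(label = "custom",
                                                 family = "custom",
                                                 kernel = "custom",
                                                 params = list())) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  if (n != ncol(raw)) stop("matrix must be square")
  if (any(diag(raw) != 0)) stop("diagonal must be zero")
  for (i in seq_len(n)) {
    row <- raw[i, ]
    bad <- !is.finite(row)
    bad[i] <- FALSE
    if (any(bad)) {
      finite_off <- row[-i][is.finite(row[-i])]
      if (length(finite_off) == 0L)
        stop("unrecoverable row ", i, ": no finite off-diagonal weight to substitute")
      raw[i, bad] <- max(finite_off)
    }
  }
  up <- upper.tri(raw)
  tr <- t(raw)
  raw[t(up)] <- tr[t(up)]                     # lower triangle <- t(upper)
  new_weights_matrix(raw, spec = spec)
}

#' Row-standardise a weights matrix
#'
#' Divides each row by its sum so that nonzero rows sum to one. Rows that
#' are entirely zero (islands) are left as zeros with a warning; the ICAR
#' conditional is undefined for such areas and the model pins their
#' structured effect to zero.
#'
#' @param W an unstandardised `weights_matrix`.
#' @return The standardised `weights_matrix`.
#' @export
row_standardise <- function(W) {
  stopifnot(inherits(W, "weights_matrix"))
  if (W$standardised) return(W)
  rs <- rowSums(W$w)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " island row(s) with zero weight sum left unstandardised")
  rs[zero] <- 1
  W$w <- W$w / rs
  W$standardised <- TRUE
  W
}

#' Build one of the 17 studied weights matrices
#'
#' Dispatches on the spec label. Family A uses contiguity orders of the
#' polygon/lattice graph; family D the Euclidean centroid distances; family
#' C the covariate distances, with the decay and bandwidth parameters
#' recomputed from those distances; family H the elementwise product of
#' geographic and covariate distances (decay scale from the hybrid
#' distances). Inverse-power kernels are passed through
#' [sanitise_symmetrise()]. The returned matrix is unstandardised and
#' symmetric; row standardisation happens inside the model (or explicitly
#' via [row_standardise()]).
#'
#' @param label one of [weights_spec_labels].
#' @param geom an [areal_geometry].
#' @param x per-area covariate (required for the C and H families).
#' @param include_vertex queen-style vertex contiguity for family A.
#' @param decay_numerator the constant in `lambda = numerator / mean(d)`.
#' @param omega order weights for A2.
#' @return An unstandardised `weights_matrix`.
#' @examples
#' g <- grid_lattice(3, 3)
#' W <- build_weights("A1", g)
#' sum(W$w) / 2  # 20 undirected queen edges
#' @export
build_weights <- function(label, geom, x = NULL, include_vertex = TRUE,
                          decay_numerator = 10,
                          omega = exp(-c(0, 0.5, 1))) {
  label <- match.arg(label, weights_spec_labels)
  family <- substr(label, 1L, 1L)
  variant <- as.integer(substr(label, 2L, 2L))
  if (family %in% c("C", "H") && is.null(x))
    stop("spec ", label, " requires a covariate")
  if (family == "A") {
    graph <- contiguity(geom, include_vertex = include_vertex)
    return(if (variant == 1L) adjacency_weights(graph, n = 1L, omega = 1)
           else adjacency_weights(graph, n = 3L, omega = omega))
  }
  dist <- switch(family,
    D = pairwise_centroid_distance(geom),
    C = covariate_distances(x),
    H = hybrid_distances(pairwise_centroid_distance(geom),
                         covariate_distances(x)))
  fam_name <- c(D = "geographic", C = "covariate", H = "hybrid")[[family]]
  if (variant <= 3L) {
    k <- c(1L, 2L, 5L)[variant]
    raw <- inverse_power_weights(dist, k)
    return(sanitise_symmetrise(raw, spec = list(
      label = label, family = fam_name, kernel = "inverse-power",
      params = list(k = k))))
  }
  sc <- decay_scale(dist, numerator = decay_numerator)
  if (variant == 4L) {
    raw <- exponential_decay_weights(dist, sc$lambda)
    kernel <- "exponential-decay"
    params <- list(lambda = sc$lambda)
  } else {
    raw <- gaussian_decay_weights(dist, sc$b)
    kernel <- "gaussian-decay"
    params <- list(b = sc$b)
  }
  new_weights_matrix(raw, spec = list(label = label, family = fam_name,
                                      kernel = kernel, params = params))
}

#' Mean non-negligible neighbour count by threshold
#'
#' For a row-standardised matrix and each threshold `t`, the mean over
#' areas of the number of positive weights not less than `t`. At `t = 0`
#' this is the mean number of structural neighbours; the profile is
#' non-increasing in the threshold.
#'
#' @param W a row-standardised `weights_matrix`.
#' @param thresholds increasing numeric vector.
#' @return Data frame with columns `threshold` and `mean_neighbours`.
#' @export
neighbour_profile <- function(W, thresholds = seq(0, 0.25, by = 0.01)) {
  stopifnot(inherits(W, "weights_matrix"))
  if (!W$standardised) stop("neighbour_profile expects a row-standardised matrix")
  counts <- vapply(thresholds, function(t) {
    mean(rowSums(W$w > 0 & W$w >= t))
  }, numeric(1))
  data.frame(threshold = thresholds, mean_neighbours = counts)
}
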