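#' Synthetic areal data generator configuration
#'
#' Collects every knob of the synthetic generator. The three regimes mimic
#' three underlying spatial random fields (USRF) on a 12 x 12 lattice: pure
#' noise, a smooth strongly autocorrelated surface, and clusters of larger
#' correlated values in a noisy background built from a convolution of two
#' Gaussian Markov random fields. Expected counts come from a
#' Gaussian/Gamma mixture on the log scale centred near 2, the covariate is
#' a noisy rescaling of the USRF, and observed counts are Poisson around
#' the exponentiated component sum.
#'
#' @param rows,cols lattice dimensions (default 12 x 12).
#' @param regime `"noise"`, `"smooth"` or `"clusters"`.
#' @param rho proper-CAR autocorrelation parameter in (0, 1) used for
#'   smooth fields; values near 1 emulate the strong positive
#'   autocorrelation of an intrinsic field.
#' @param usrf_sd marginal standard deviation of the USRF on the
#'   log-relative-risk scale (per regime defaults: 0.2 noise, 0.8 smooth,
#'   0.8 clusters overall level).
#' @param smooth_passes neighbourhood-averaging passes applied to the
#'   smooth-regime field (a conditional-autoregressive draw is locally
#'   rough; convolution makes the surface genuinely smooth).
#' @param cov_a,cov_sd covariate loading on the USRF and noise sd. The
#'   default noise sd is `sqrt(3) * usrf_sd` for the spatial regimes
#'   (covariate-field correlation about 0.5) and `usrf_sd` for the noise
#'   regime.
#' @param mix_p,logE_mean,logE_sd,gamma_shape,gamma_rate expected-count
#'   mixture: with probability `mix_p` draw `logE` from
#'   `N(logE_mean, logE_sd^2)`, otherwise `logE_mean + Gamma(shape, rate)`
#'   for a right tail of larger values.
#' @param obs_sd sd of the extra log-scale observation noise.
#' @param beta_gen covariate effect used when forming the observed counts;
#'   defaults to 0.3 for the spatial regimes and 1.5 for the noise regime,
#'   where the covariate effect dominates both random effects.
#' @param cluster_rho,cluster_level,cluster_quantile,cluster_noise_sd
#'   clusters regime: autocorrelation of the patch-texture field, mean
#'   level of the high patches, quantile of the large-scale field used to
#'   threshold high/low regions, and sd of the small-scale background
#'   noise.
#' @param discretise `"poisson"` (default, counts drawn Poisson around the
#'   mean) or `"round"` (deterministic rounding of the mean).
#' @param seed integer master seed for the generator.
#' @return A `generator_config` list.
#' @export
generator_config <- function(rows = 12L, cols = 12L,
                             regime = c("noise", "smooth", "clusters"),
                             rho = 0.99, smooth_passes = 3L,
                             usrf_sd = NULL,
                             cov_a = 1, cov_sd = NULL,
                             mix_p = 0.95, logE_mean = 2, logE_sd = 0.15,
                             gamma_shape = 2, gamma_rate = 3,
                             obs_sd = 0.1, beta_gen = NULL,
                             cluster_rho = 0.95, cluster_level = 1.6,
                             cluster_quantile = 0.75, cluster_noise_sd = 0.15,
                             discretise = c("poisson", "round"),
                             seed = 1L) {
  regime <- match.arg(regime)
  discretise <- match.arg(discretise)
  if (is.null(usrf_sd))
    usrf_sd <- switch(regime, noise = 0.2, smooth = 0.8, clusters = 0.8)
  # moderate covariate-field correlation (~0.5) for the spatial regimes; a
  # tighter, dominant covariate in the pure-noise regime
  if (is.null(cov_sd))
    cov_sd <- if (regime == "noise") usrf_sd else usrf_sd * sqrt(3)
  if (is.null(beta_gen))
    beta_gen <- if (regime == "noise") 1.5 else 0.3
  stopifnot(rho > 0, rho < 1, usrf_sd >= 0, cov_sd >= 0,
            mix_p >= 0, mix_p <= 1, obs_sd >= 0, smooth_passes >= 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols), regime = regime,
         rho = rho, smooth_passes = as.integer(smooth_passes),
         usrf_sd = usrf_sd, cov_a = cov_a, cov_sd = cov_sd,
         mix_p = mix_p, logE_mean = logE_mean, logE_sd = logE_sd,
         gamma_shape = gamma_shape, gamma_rate = gamma_rate,
         obs_sd = obs_sd, beta_gen = beta_gen,
         cluster_rho = cluster_rho, cluster_level = cluster_level,
         cluster_quantile = cluster_quantile,
         cluster_noise_sd = cluster_noise_sd,
         discretise = discretise, seed = as.integer(seed)),
    class = "generator_config")
}

#' Sample a proper-CAR Gaussian Markov random field
#'
#' Draws one realisation of a zero-mean Gaussian field with precision
#' proportional to `D - rho * A`, where `A` is the binary first-order
#' (queen) adjacency matrix of the geometry and `D` its row-sum diagonal.
#' The draw is centred and rescaled so its empirical standard deviation
#' equals `marginal_sd`. With `rho` near one this approximates a draw from
#' an intrinsic autoregression, i.e. a strongly autocorrelated surface.
#'
#' @param geom an [areal_geometry].
#' @param rho autocorrelation parameter in (0, 1).
#' @param marginal_sd target empirical sd of the draw (0 gives the zero
#'   field).
#' @param seed integer seed; the draw is a pure function of
#'   (geometry, rho, marginal_sd, seed).
#' @return Numeric vector of length N.
#' @export
sample_gmrf <- function(geom, rho = 0.99, marginal_sd = 1, seed = 1L) {
  stopifnot(rho > 0, rho < 1, marginal_sd >= 0)
  graph <- contiguity(geom, include_vertex = TRUE)
  A <- adjacency_matrix(graph)
  Q <- diag(rowSums(A)) - rho * A
  R <- tryCatch(chol(Q), error = function(e)
    stop("ill-conditioned precision (disconnected graph with rho near 1?): ",
         conditionMessage(e)))
  n <- nrow(Q)
  set.seed(seed)
  z <- stats::rnorm(n)
  x <- backsolve(R, z)
  if (marginal_sd == 0) return(rep(0, n))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x * (marginal_sd / s)
}

# repeated local averaging with the queen neighbourhood: each pass replaces
# f_i by the mean of f_i and its neighbours' average
smooth_field <- function(f, geom, passes = 1L) {
  A <- adjacency_matrix(contiguity(geom, include_vertex = TRUE))
  deg <- rowSums(A)
  deg[deg == 0] <- 1
  for (p in seq_len(passes)) f <- (f + as.numeric(A %*% f) / deg) / 2
  f
}

#' Underlying spatial random field for one regime
#'
#' `noise`: iid Gaussian values, no spatial pattern. `smooth`: one strongly
#' autocorrelated GMRF draw. `clusters`: a large-scale smooth field is
#' thresholded at `cluster_quantile` into high/low regions; the high region
#' is given a positive level modulated by a second, shorter-range GMRF
#' (the convolution texture), and small-scale noise is added everywhere,
#' yielding a handful of contiguous patches of larger correlated values in
#' a noisy background.
#'
#' @param regime `"noise"`, `"smooth"` or `"clusters"`.
#' @param geom an [areal_geometry].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return Numeric USRF vector of length N (log-relative-risk scale).
#' @export
make_usrf <- function(regime, geom, config, seed = config$seed) {
  n <- n_areas(geom)
  switch(regime,
    noise = {
      set.seed(seed)
      stats::rnorm(n, 0, config$usrf_sd)
    },
    smooth = {
      f <- sample_gmrf(geom, rho = config$rho, marginal_sd = 1, seed = seed)
      # convolving with the neighbourhood smoother turns the (locally
      # rough) conditional-autoregressive draw into a genuinely smooth
      # surface before rescaling
      f <- smooth_field(f, geom, passes = config$smooth_passes)
      f <- f - mean(f)
      if (config$usrf_sd == 0 || stats::sd(f) == 0) rep(0, n)
      else f * (config$usrf_sd / stats::sd(f))
    },
    clusters = {
      large <- sample_gmrf(geom, rho = config$rho, marginal_sd = 1,
                           seed = seed)
      # convolve with the neighbourhood smoother so thresholding yields a
      # few contiguous patches rather than scattered cells
      large <- smooth_field(large, geom, passes = 1L)
      texture <- sample_gmrf(geom, rho = config$cluster_rho, marginal_sd = 0.3,
                             seed = seed + 1L)
      high <- large > stats::quantile(large, config$cluster_quantile)
      set.seed(seed + 2L)
      noise <- stats::rnorm(n, 0, config$cluster_noise_sd)
      f <- high * (config$cluster_level + texture) + noise
      # rescale overall spread to the configured usrf level
      f * (config$usrf_sd / stats::sd(f))
    },
    stop("unknown regime: ", regime)
  )
}

#' Covariate correlated with the USRF
#'
#' `x_i = a * usrf_i + N(0, sd^2)`; scaling plus noise gives a moderate
#' correlation between the covariate and the latent field, enough to make
#' covariate-space smoothing meaningful while leaving both terms
#' estimable.
#'
#' @param usrf the latent field vector.
#' @param a loading on the field.
#' @param sd noise standard deviation.
#' @param seed integer seed.
#' @return Covariate vector of the same length.
#' @export
make_covariate <- function(usrf, a = 1, sd = 0.5, seed = 1L) {
  set.seed(seed)
  a * usrf + stats::rnorm(length(usrf), 0, sd)
}

#' Log expected counts from a Gaussian/Gamma mixture
#'
#' With probability `mix_p` the log expected count is Gaussian around
#' `logE_mean` (majority of values about 2); otherwise `logE_mean` plus a
#' Gamma draw, producing the few larger values seen in real registry data.
#'
#' @param n number of areas.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return Numeric vector `logE` of length `n`.
#' @export
make_expected <- function(n, config, seed = config$seed) {
  set.seed(seed)
  gaussian <- stats::runif(n) < config$mix_p
  logE <- numeric(n)
  logE[gaussian] <- stats::rnorm(sum(gaussian), config$logE_mean,
                                 config$logE_sd)
  logE[!gaussian] <- config$logE_mean +
    stats::rgamma(sum(!gaussian), shape = config$gamma_shape,
                  rate = config$gamma_rate)
  logE
}

#' Observed counts from the component sum
#'
#' Forms the per-area mean `mu_i = exp(logE_i + beta_gen * (x_i - mean(x))
#' + usrf_i + N(0, obs_sd^2))` and draws `y_i ~ Poisson(mu_i)` (or rounds
#' `mu_i` when `discretise = "round"`). Centring the covariate keeps the
#' implied intercept at zero.
#'
#' @param components list with `usrf`, `x`, `logE`.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return List with `y` (integer counts), `noise` (the extra log-scale
#'   noise) and `log_mu` (the component sum).
#' @export
make_observed <- function(components, config, seed = config$seed) {
  n <- length(components$usrf)
  stopifnot(length(components$x) == n, length(components$logE) == n)
  set.seed(seed)
  noise <- stats::rnorm(n, 0, config$obs_sd)
  log_mu <- components$logE +
    config$beta_gen * (components$x - mean(components$x)) +
    components$usrf + noise
  mu <- exp(log_mu)
  y <- if (config$discretise == "poisson") stats::rpois(n, mu)
       else as.integer(round(mu))
  list(y = as.integer(y), noise = noise, log_mu = log_mu)
}

#' Generate one synthetic areal data set
#'
#' Assembles the lattice geometry, USRF, covariate, expected counts
#' `E = exp(logE)` and observed counts for the requested regime. Sub-seeds
#' for the component draws are fixed offsets of the configured seed, so the
#' whole data set is a pure function of (config, seed).
#'
#' @param regime `"noise"`, `"smooth"` or `"clusters"` (overrides the
#'   config regime when given).
#' @param config a [generator_config()].
#' @return List with `data` (an `area_dataset` data frame: `area_id`, `y`,
#'   `E`, `x`), `components` (a `SyntheticComponents`-style list holding
#'   the truth: `usrf`, `x`, `logE`, `noise`, `log_mu`, `y`, `regime`,
#'   `seed`) and `geom` (the [areal_geometry]).
#' @examples
#' ds <- generate_dataset("smooth", generator_config(regime = "smooth", seed = 7))
#' head(ds$data)
#' @export
generate_dataset <- function(regime = NULL, config = generator_config()) {
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("noise", "smooth", "clusters"))
    if (regime != config$regime)  # regime-specific defaults, keep grid/seed
      config <- generator_config(rows = config$rows, cols = config$cols,
                                 regime = regime, seed = config$seed)
  } else regime <- config$regime
  geom <- grid_lattice(config$rows, config$cols)
  s <- config$seed
  usrf <- make_usrf(regime, geom, config, seed = s + 11L)
  x <- make_covariate(usrf, a = config$cov_a, sd = config$cov_sd,
                      seed = s + 23L)
  logE <- make_expected(n_areas(geom), config, seed = s + 37L)
  obs <- make_observed(list(usrf = usrf, x = x, logE = logE), config,
                       seed = s + 41L)
  data <- data.frame(area_id = geom$area_ids, y = obs$y, E = exp(logE),
                     x = x, stringsAsFactors = FALSE)
  class(data) <- c("area_dataset", class(data))
  components <- list(usrf = usrf, x = x, logE = logE, noise = obs$noise,
                     log_mu = obs$log_mu, y = obs$y, regime = regime,
                     seed = s)
  list(data = data, components = components, geom = geom)
}

#' Write a synthetic data set to a directory
#'
#' Emits `data.csv` (area_id, y, E, x), `truth.csv` (the generator
#' components), `geometry.geojson` (lattice polygons) and `config.json`.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param config the [generator_config()] used.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$data, file.path(dir, "data.csv"), row.names = FALSE)
  truth <- data.frame(area_id = ds$geom$area_ids, usrf = ds$components$usrf,
                      x = ds$components$x, logE = ds$components$logE,
                      noise = ds$components$noise,
                      log_mu = ds$components$log_mu, y = ds$components$y)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_geojson(ds$geom, file.path(dir, "geometry.geojson"),
                values = ds$data[, c("y", "E", "x")])
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
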