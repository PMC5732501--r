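test_that("GMRF draws are deterministic, centred, scaled, and autocorrelated", {
  g <- grid_lattice(8, 8)
  f1 <- sample_gmrf(g, rho = 0.95, marginal_sd = 0.7, seed = 5)
  f2 <- sample_gmrf(g, rho = 0.95, marginal_sd = 0.7, seed = 5)
  expect_identical(f1, f2)
  expect_equal(sd(f1), 0.7, tolerance = 1e-12)
  expect_equal(mean(f1), 0, tolerance = 1e-12)
  expect_equal(sample_gmrf(g, marginal_sd = 0, seed = 1), rep(0, 64))

  # strongly autocorrelated draws register on Moran's I (most seeds)
  W <- build_weights("A1", grid_lattice(12, 12))
  g12 <- grid_lattice(12, 12)
  hits <- sum(sapply(1:20, function(s) {
    f <- sample_gmrf(g12, rho = 0.99, marginal_sd = 1, seed = s)
    morans_p(f, W, n_perm = 199, seed = s)$p < 0.01
  }))
  expect_gte(hits, 19)
})

test_that("usrf regimes have the advertised spatial character", {
  g <- grid_lattice(12, 12)
  W <- build_weights("A1", g)
  cfg_n <- generator_config(regime = "noise", seed = 1)
  cfg_s <- generator_config(regime = "smooth", seed = 1)
  cfg_c <- generator_config(regime = "clusters", seed = 1)

  # noise: mostly non-significant Moran
  pn <- sapply(1:20, function(s)
    morans_p(make_usrf("noise", g, cfg_n, seed = s), W, n_perm = 199,
             seed = s)$p)
  expect_gte(sum(pn > 0.05), 16)

  # smooth: always strongly significant
  ps <- sapply(1:10, function(s)
    morans_p(make_usrf("smooth", g, cfg_s, seed = s), W, n_perm = 999,
             seed = s)$p)
  expect_true(all(ps <= 0.005))

  # clusters: high region splits into a handful of contiguous patches
  ncomp <- sapply(1:40, function(s) {
    u <- make_usrf("clusters", g, cfg_c, seed = s)
    hi <- which(u > quantile(u, 0.75))
    adj <- as.matrix(dist(g$centroids[hi, , drop = FALSE])) < 1.5  # queen
    diag(adj) <- FALSE
    igraph::count_components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  })
  expect_gte(mean(ncomp >= 2 & ncomp <= 6), 0.75)

  expect_error(make_usrf("banana", g, cfg_n), "unknown regime")
})

test_that("covariate construction controls the correlation with the field", {
  set.seed(2)
  u <- rnorm(144)
  expect_equal(cor(make_covariate(u, a = 2, sd = 0, seed = 1), u), 1)

  # a = 0: no association beyond chance
  r0 <- sapply(1:30, function(s) cor(make_covariate(u, a = 0, sd = 1,
                                                    seed = s), u))
  expect_gte(mean(abs(r0) < 0.3), 0.95)

  # regime defaults give a moderate correlation
  rr <- sapply(1:20, function(s) {
    ds <- generate_dataset(config = generator_config(regime = "smooth",
                                                     seed = s))
    cor(ds$data$x, ds$components$usrf)
  })
  expect_true(all(rr > 0.3 & rr < 0.9))
})

test_that("expected-count mixture centres log counts near 2 with a right tail", {
  cfg <- generator_config(regime = "noise", seed = 1)
  med <- sapply(1:40, function(s) median(make_expected(144, cfg, seed = s)))
  expect_gte(mean(med > 1.7 & med < 2.3), 0.95)

  # single Gaussian component: values stay near 2
  cfg1 <- generator_config(regime = "noise", mix_p = 1, seed = 1)
  logE <- make_expected(500, cfg1, seed = 3)
  expect_true(all(logE < 3))
  expect_true(all(exp(logE) > 0))

  # tail component only produces values above the Gaussian centre
  cfg0 <- generator_config(regime = "noise", mix_p = 0, seed = 1)
  expect_true(all(make_expected(200, cfg0, seed = 4) > 2))
})

test_that("observed counts follow the component identity", {
  g <- grid_lattice(6, 6)
  cfg <- generator_config(rows = 6, cols = 6, regime = "noise", seed = 9)
  comp <- list(usrf = rep(0, 36), x = rep(0, 36),
               logE = rep(log(10), 36))
  cfg0 <- utils::modifyList(cfg, list(beta_gen = 0, obs_sd = 0))
  class(cfg0) <- "generator_config"
  obs <- make_observed(comp, cfg0, seed = 2)
  # offset-only model: counts fluctuate Poisson around exp(logE) = 10
  expect_equal(mean(obs$y), 10, tolerance = 0.7)
  expect_identical(obs$log_mu, comp$logE)

  # log mu is exactly the sum of stored components
  ds <- generate_dataset(config = generator_config(regime = "smooth",
                                                   seed = 4))
  with(ds$components, expect_equal(
    log_mu, logE + 0.3 * (x - mean(x)) + usrf + noise, tolerance = 1e-12))

  # rounding discretisation is deterministic
  cfg_r <- generator_config(regime = "noise", discretise = "round", seed = 5)
  d1 <- generate_dataset(config = cfg_r)
  d2 <- generate_dataset(config = cfg_r)
  expect_identical(d1$data$y, d2$data$y)
  expect_identical(d1$data$y, as.integer(round(exp(d1$components$log_mu))))
})

test_that("generate_dataset is a pure function of config and seed", {
  cfg <- generator_config(regime = "clusters", seed = 77)
  a <- generate_dataset(config = cfg)
  b <- generate_dataset(config = cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$components, b$components)
  expect_true(all(a$data$E > 0))
  expect_true(all(a$data$y >= 0))
  expect_equal(nrow(a$data), 144)
})

test_that("dataset export writes the advertised plain-text artefacts", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(rows = 4, cols = 4, regime = "noise", seed = 3)
  ds <- generate_dataset(config = cfg)
  write_dataset(ds, dir, cfg)
  expect_true(all(file.exists(file.path(dir,
    c("data.csv", "truth.csv", "geometry.geojson", "config.json")))))
  back <- load_area_csv(file.path(dir, "data.csv"))
  expect_equal(back$y, ds$data$y)
  expect_equal(back$E, ds$data$E, tolerance = 1e-12)
})
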