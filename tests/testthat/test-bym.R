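test_that("internal standardisation applies the overall rate", {
  expect_equal(internal_standardisation(c(1, 3), c(100, 300)), c(1, 3))
  expect_equal(internal_standardisation(c(2, 2), c(100, 300)), c(1, 3))
  set.seed(8)
  for (i in 1:5) {
    y <- rpois(20, 5); P <- runif(20, 50, 500)
    expect_equal(sum(internal_standardisation(y, P)), sum(y))
  }
  expect_error(internal_standardisation(c(1, 1), c(0, 10)), "positive")
})

test_that("poisson_loglik matches the closed form", {
  expect_equal(poisson_loglik(0, 1, 0), -1)
  expect_equal(poisson_loglik(1, 1, 0), -1)
  set.seed(1)
  y <- rpois(10, 4); E <- runif(10, 1, 5); eta <- rnorm(10, 0, 0.3)
  expect_equal(poisson_loglik(y, E, eta),
               sum(sapply(seq_along(y), function(i)
                 poisson_loglik(y[i], E[i], eta[i]))))
  expect_error(poisson_loglik(-1, 1, 0), "nonnegative")
})

test_that("ICAR conditional gives the weighted-average mean and scaled variance", {
  W2 <- new_weights_matrix(rbind(c(0, 1), c(1, 0)))
  cond <- icar_conditional(c(0.4, -1.2), W2, sigma2_gamma = 0.5, i = 1)
  expect_equal(cond$mean, -1.2)
  expect_equal(cond$var, 0.5)

  W3 <- new_weights_matrix(rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
  cond <- icar_conditional(c(0, 2, 4), W3, 1, i = 1)
  expect_equal(cond$mean, 3)
  expect_equal(cond$var, 1 / 2)

  island <- new_weights_matrix(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_error(icar_conditional(c(0, 0, 0), island, 1, i = 3), "island")
})

test_that("ICAR conditional agrees with the dense Gaussian-conditional oracle", {
  # oracle: assemble the dense joint precision Q = (D - W)/s2 and read the
  # conditional of coordinate i off the generic Gaussian identities
  # mean = -Q[i,-i] gamma[-i] / Q[i,i], var = 1/Q[i,i]
  dense_conditional <- function(w, s2, gamma, i) {
    Q <- (diag(rowSums(w)) - w) / s2
    list(mean = -as.numeric(Q[i, -i] %*% gamma[-i]) / Q[i, i],
         var = 1 / Q[i, i])
  }
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.8)
    w <- w + t(w)
    if (any(rowSums(w) == 0)) next
    gamma <- rnorm(n); gamma <- gamma - mean(gamma)
    s2 <- runif(1, 0.2, 2)
    for (i in sample(n, 2)) {
      got <- icar_conditional(gamma, new_weights_matrix(w), s2, i)
      want <- dense_conditional(w, s2, gamma, i)
      expect_equal(got$mean, want$mean, tolerance = 1e-10)
      expect_equal(got$var, want$var, tolerance = 1e-10)
    }
  }
})

test_that("fit_bym validates its inputs and is reproducible", {
  g <- grid_lattice(4, 4)
  ds <- generate_dataset(config = generator_config(rows = 4, cols = 4,
                                                   regime = "noise", seed = 2))
  W <- build_weights("A1", g)
  expect_error(fit_bym(ds$data, NULL, test_bym_config()), "requires a weights")
  expect_error(fit_bym(ds$data, W,
                       test_bym_config(include_structured = FALSE)),
               "no weights")
  expect_error(fit_bym(ds$data, row_standardise(W), test_bym_config()),
               "unstandardised")

  cfg <- test_bym_config(seed = 31)
  f1 <- fit_bym(ds$data, W, cfg)
  f2 <- fit_bym(ds$data, W, cfg)
  expect_identical(f1$chains, f2$chains)
  M <- cfg$iter / cfg$thin
  expect_length(f1$chains[[1]]$alpha, M)
  expect_equal(dim(f1$chains[[1]]$gamma), c(M, 16L))
})

test_that("stored structured effects satisfy the sum-to-zero constraint", {
  ds <- generate_dataset(config = generator_config(rows = 5, cols = 5,
                                                   regime = "smooth", seed = 6))
  W <- build_weights("A1", grid_lattice(5, 5))
  fit <- fit_bym(ds$data, W, test_bym_config(seed = 4))
  for (ch in fit$chains)
    expect_true(all(abs(rowSums(ch$gamma)) < 1e-8))
})

test_that("null-data fit of model B centres the intercept at zero", {
  g <- grid_lattice(6, 6)
  E <- rep(7, 36)
  dat <- data.frame(area_id = g$area_ids, y = as.integer(round(E)), E = E,
                    x = rep(0, 36))
  fit <- fit_bym(dat, NULL, test_bym_config(include_structured = FALSE,
                                            seed = 12))
  a <- unlist(lapply(fit$chains, `[[`, "alpha"))
  expect_lt(abs(mean(a)) / sd(a), 3)
})

test_that("excess variation and rebalancing follow their definitions", {
  # hand-built posterior: gamma medians (1,2,3), eps medians (0,0,0)
  fake <- structure(list(
    chains = list(list(alpha = rep(0, 3), beta = rep(0, 3),
                       gamma = rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                       epsilon = matrix(0, 3, 3),
                       sigma2_gamma = rep(1, 3), sigma_eps = rep(1, 3))),
    data = list(area_id = letters[1:3], y = c(1, 1, 1), E = rep(1, 3),
                x = rep(0, 3), N = 3L),
    spec_label = "A1",
    config = bym_config(chains = 1, iter = 3, burnin = 0, thin = 1),
    rebalanced = FALSE), class = "bym_fit")
  ev <- excess_variation(fake)
  expect_equal(ev$psi, 1)
  expect_equal(ev$S_gamma, 1)
  expect_equal(ev$S_epsilon, 0)

  # symmetric split -> psi = 1/2
  fake2 <- fake
  fake2$chains[[1]]$epsilon <- rbind(c(3, 2, 1), c(3, 2, 1), c(3, 2, 1))
  expect_equal(excess_variation(fake2)$psi, 0.5)

  # printed update: gamma=1, eps=2, psi=0.5 -> gamma 0, eps 3
  fake3 <- fake
  fake3$chains[[1]]$gamma <- matrix(1, 3, 3)
  fake3$chains[[1]]$epsilon <- matrix(2, 3, 3)
  rb <- rebalance(fake3, psi = 0.5)
  expect_true(all(rb$chains[[1]]$gamma == 0))
  expect_true(all(rb$chains[[1]]$epsilon == 3))

  # psi = 0 is the identity
  rb0 <- rebalance(fake3, psi = 0)
  expect_identical(rb0$chains[[1]]$gamma, fake3$chains[[1]]$gamma)

  # degenerate posterior errors
  fake4 <- fake
  fake4$chains[[1]]$gamma <- matrix(0, 3, 3)
  expect_error(excess_variation(fake4), "degenerate")
})

test_that("rebalancing conserves gamma + eps and the linear predictor", {
  ds <- generate_dataset(config = generator_config(rows = 5, cols = 5,
                                                   regime = "smooth", seed = 3))
  W <- build_weights("A1", grid_lattice(5, 5))
  fit <- fit_bym(ds$data, W, test_bym_config(seed = 8))
  eta_before <- eta_draws(fit)
  tot_before <- fit$chains[[1]]$gamma + fit$chains[[1]]$epsilon
  reb <- rebalance(fit)
  expect_gte(reb$psi, 0); expect_lte(reb$psi, 1)
  expect_equal(reb$chains[[1]]$gamma + reb$chains[[1]]$epsilon, tot_before)
  expect_equal(eta_draws(reb), eta_before)
})

test_that("prior sampling recovers the Gamma(3,1) variance prior moments", {
  # likelihood disabled: the chain targets the joint prior, so the
  # marginal draws of sigma2_gamma must match Gamma(3, 1)
  g <- grid_lattice(4, 4)
  W <- build_weights("A1", g)
  dat <- data.frame(area_id = g$area_ids, y = rep(1L, 16), E = rep(1, 16),
                    x = rep(0, 16))
  cfg <- bym_config(chains = 1, iter = 50000, burnin = 3000, thin = 1,
                    use_likelihood = FALSE, seed = 42)
  fit <- fit_bym(dat, W, cfg)
  s2 <- fit$chains[[1]]$sigma2_gamma
  # batch-means Monte-Carlo error (the chain is autocorrelated)
  nb <- 50
  bm <- colMeans(matrix(s2, ncol = nb))
  se_mean <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(s2) - 3), 3 * se_mean)
  bv <- colMeans(matrix((s2 - mean(s2))^2, ncol = nb))
  se_var <- sd(bv) / sqrt(nb)
  expect_lt(abs(var(s2) - 3), 3 * se_var)
})

test_that("parameters are recovered on data simulated from the model", {
  # simulate from the BYM model itself: gamma from the constrained ICAR,
  # eps iid, known alpha and beta
  g <- grid_lattice(12, 12)
  W <- build_weights("A1", g)
  w <- W$w
  Q <- diag(rowSums(w)) - w
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > 1e-8
  half <- e$vectors[, keep] %*% diag(1 / sqrt(e$values[keep]), sum(keep))
  sim_icar <- function(s2) as.numeric(half %*% rnorm(sum(keep))) * sqrt(s2)
  alpha_t <- 0.2; beta_t <- 0.7; s2g_t <- 0.3; se_t <- 0.15
  n_rep <- 25
  cover <- logical(n_rep)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    gam <- sim_icar(s2g_t)
    eps <- rnorm(144, 0, se_t)
    x <- rnorm(144)
    E <- exp(rnorm(144, 2, 0.15))
    y <- rpois(144, E * exp(alpha_t + beta_t * x + gam + eps))
    dat <- data.frame(area_id = g$area_ids, y = y, E = E, x = x)
    fit <- fit_bym(dat, W, bym_config(chains = 2, iter = 2500, burnin = 1500,
                                      thin = 5, seed = r))
    b <- unlist(lapply(fit$chains, `[[`, "beta"))
    ci <- quantile(b, c(0.025, 0.975))
    cover[r] <- ci[1] <= beta_t && beta_t <= ci[2]
  }
  expect_gte(mean(cover), 0.8)
})
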