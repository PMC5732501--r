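#' Expected counts by internal standardisation
#'
#' Applies the overall observed rate to each area's population:
#' `E_i = (sum(y) / sum(P)) * P_i`, so that `sum(E) = sum(y)` exactly.
#'
#' @param y observed counts.
#' @param P populations at risk (all positive).
#' @return Vector of expected counts.
#' @export
internal_standardisation <- function(y, P) {
  if (any(P <= 0)) stop("all populations must be positive")
  if (any(y < 0)) stop("counts must be nonnegative")
  sum(y) / sum(P) * P
}

#' Poisson log-likelihood of the BYM observation model
#'
#' `sum_i log Po(y_i | E_i * exp(eta_i))`.
#'
#' @param y nonnegative counts.
#' @param E positive expected counts.
#' @param eta log-relative risks.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(y, E, eta) {
  if (any(y < 0)) stop("counts must be nonnegative")
  if (any(E <= 0)) stop("expected counts must be positive")
  sum(stats::dpois(y, E * exp(eta), log = TRUE))
}

#' ICAR full conditional for one area
#'
#' Under the intrinsic autoregression with symmetric weights `W`, the
#' structured effect of area `i` given the rest is Gaussian with mean the
#' weighted average of its neighbours' values and variance
#' `sigma2_gamma / sum_j w_ij`. The weighted average makes row
#' standardisation implicit; `W` should be the unstandardised symmetric
#' matrix.
#'
#' @param gamma current vector of structured effects.
#' @param W a `weights_matrix` (unstandardised) or plain matrix.
#' @param sigma2_gamma positive conditional variance scale.
#' @param i area index.
#' @return List with `mean` and `var`.
#' @export
icar_conditional <- function(gamma, W, sigma2_gamma, i) {
  w <- if (inherits(W, "weights_matrix")) W$w else as.matrix(W)
  rs <- sum(w[i, ])
  if (rs <= 0) stop("island area ", i, ": zero weight row sum, conditional undefined")
  list(mean = sum(w[i, ] * gamma) / rs, var = sigma2_gamma / rs)
}

#' MCMC configuration for the BYM fit
#'
#' Defaults follow the study protocol: two parallel chains of 25,000
#' kept iterations thinned by 5 after a burn-in of 10,000, weakly
#' informative priors `alpha, beta ~ N(0, 100)` (variance 100),
#' `sigma_eps ~ N(0, 10) I(0, Inf)` (half-normal on the sd, scale
#' variance 10) and `sigma2_gamma ~ Gamma(3, 1)` on the ICAR variance.
#'
#' @param chains number of parallel chains.
#' @param iter post-burn-in iterations per chain.
#' @param burnin burn-in iterations per chain (adaptation happens here).
#' @param thin thinning factor; `iter / thin` draws are stored per chain.
#' @param prior_var_alpha,prior_var_beta prior variances of the fixed
#'   effects.
#' @param sigma_eps_scale2 scale variance of the half-normal prior on
#'   `sigma_eps`.
#' @param sigma_gamma_shape,sigma_gamma_rate Gamma prior on
#'   `sigma2_gamma`.
#' @param include_structured `FALSE` drops the ICAR term entirely (the
#'   no-smoothing benchmark, model B).
#' @param use_likelihood internal switch: `FALSE` samples the joint prior
#'   (for calibration checks).
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @return A `bym_config` list.
#' @export
bym_config <- function(chains = 2L, iter = 25000L, burnin = 10000L,
                       thin = 5L, prior_var_alpha = 100,
                       prior_var_beta = 100, sigma_eps_scale2 = 10,
                       sigma_gamma_shape = 3, sigma_gamma_rate = 1,
                       include_structured = TRUE, use_likelihood = TRUE,
                       seed = 1L) {
  stopifnot(chains >= 1, iter >= thin, burnin >= 0, thin >= 1,
            iter %% thin == 0,
            prior_var_alpha > 0, prior_var_beta > 0, sigma_eps_scale2 > 0,
            sigma_gamma_shape > 0, sigma_gamma_rate > 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 prior_var_alpha = prior_var_alpha,
                 prior_var_beta = prior_var_beta,
                 sigma_eps_scale2 = sigma_eps_scale2,
                 sigma_gamma_shape = sigma_gamma_shape,
                 sigma_gamma_rate = sigma_gamma_rate,
                 include_structured = isTRUE(include_structured),
                 use_likelihood = isTRUE(use_likelihood),
                 seed = as.integer(seed)),
            class = "bym_config")
}

# model-side standardisation: rows scaled to unit sums, then symmetrised as
# (Wt + t(Wt))/2 so the ICAR joint stays a valid Gaussian Markov random
# field. Every non-island row sum is ~1, so the ICAR conditional variance is
# ~sigma2_gamma for every area irrespective of how much raw weight mass a
# row carries; without this, dense kernels (e.g. inverse distance on a
# lattice) would pin the structured effect to a near-global mean.
model_weights <- function(w) {
  rs <- rowSums(w)
  live <- rs > 0
  wt <- w
  wt[live, ] <- w[live, , drop = FALSE] / rs[live]
  (wt + t(wt)) / 2
}

# compressed-row representation of a symmetric weights matrix for the C++ core
weights_crs <- function(w) {
  n <- nrow(w)
  idx <- vector("list", n)
  wt <- vector("list", n)
  for (i in seq_len(n)) {
    nz <- which(w[i, ] > 0)
    idx[[i]] <- nz - 1L
    wt[[i]] <- w[i, nz]
  }
  list(ptr = c(0L, cumsum(lengths(idx))),
       idx = as.integer(unlist(idx, use.names = FALSE)),
       wt = as.numeric(unlist(wt, use.names = FALSE)),
       rowsum = rowSums(w))
}

# connected components of the positive-weight graph restricted to non-islands
weights_components <- function(w) {
  live <- which(rowSums(w) > 0)
  if (length(live) == 0L) return(0L)
  sub <- w[live, live, drop = FALSE] > 0
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  igraph::count_components(g)
}

#' Fit the BYM model (or the no-smoothing benchmark) by MCMC
#'
#' Metropolis-within-Gibbs sampler for
#' `y_i ~ Po(E_i exp(alpha + beta x_i + gamma_i + eps_i))` with the ICAR
#' prior on `gamma` (sum-to-zero enforced by recentring after every sweep,
#' the removed mean absorbed into `alpha`) and iid Gaussian `eps`. With
#' `include_structured = FALSE` the structured term is dropped and `W` must
#' be absent: this is benchmark model B. Proposal scales adapt during
#' burn-in only, so the kept draws come from a fixed transition kernel.
#' Chains are initialised from overdispersed prior draws with
#' chain-indexed sub-seeds; the fit is deterministic given
#' (data, W, config).
#'
#' @param data an `area_dataset` data frame (`area_id`, `y`, `E`, `x`) or
#'   list with those elements; `x` defaults to zero if absent.
#' @param W an unstandardised symmetric `weights_matrix`, or `NULL` for
#'   model B.
#' @param config a [bym_config()].
#' @return A `bym_fit`: list with `chains` (per chain: `alpha`, `beta`,
#'   `gamma` (M x N), `epsilon`, `sigma2_gamma`, `sigma_eps`), `data`,
#'   `spec_label`, `config`, `rebalanced` flag.
#' @export
fit_bym <- function(data, W = NULL, config = bym_config()) {
  y <- as.integer(data$y)
  E <- as.numeric(data$E)
  N <- length(y)
  x <- if (is.null(data$x)) rep(0, N) else as.numeric(data$x)
  if (any(y < 0)) stop("counts must be nonnegative")
  if (any(!is.finite(E)) || any(E <= 0)) stop("expected counts must be positive")
  if (length(E) != N || length(x) != N) stop("y, E, x must have equal length")
  structured <- config$include_structured
  if (structured && is.null(W)) stop("structured model requires a weights matrix")
  if (!structured && !is.null(W)) stop("benchmark model B takes no weights matrix")
  if (structured) {
    stopifnot(inherits(W, "weights_matrix"))
    if (W$standardised)
      stop("fit_bym expects the unstandardised symmetric matrix; ",
           "row standardisation is implicit in the ICAR conditional")
    if (nrow(W$w) != N) stop("weights matrix does not match the data")
    w_model <- model_weights(W$w)
    crs <- weights_crs(w_model)
    if (any(crs$rowsum == 0))
      warning("island area(s) with zero weight row sum: structured effect pinned to 0")
    n_comp <- weights_components(w_model)
  } else {
    crs <- list(ptr = integer(N + 1L), idx = integer(0), wt = numeric(0),
                rowsum = numeric(N))
    n_comp <- 0L
  }
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch)
    # overdispersed initial values from the priors
    alpha0 <- stats::rnorm(1, 0, sqrt(config$prior_var_alpha) / 2)
    beta0 <- stats::rnorm(1, 0, sqrt(config$prior_var_beta) / 2)
    s2g0 <- stats::rgamma(1, config$sigma_gamma_shape, config$sigma_gamma_rate)
    se0 <- abs(stats::rnorm(1, 0, sqrt(config$sigma_eps_scale2)))
    se0 <- max(se0, 0.05)
    eps0 <- stats::rnorm(N, 0, min(se0, 1))
    gamma0 <- if (structured) {
      g <- stats::rnorm(N, 0, 0.1)
      g[crs$rowsum == 0] <- 0
      live <- crs$rowsum > 0
      g[live] <- g[live] - mean(g[live])
      g
    } else numeric(N)
    out <- bym_mcmc_cpp(y, E, x, crs$ptr, crs$idx, crs$wt, crs$rowsum,
                        config$burnin, config$iter, config$thin,
                        config$prior_var_alpha, config$prior_var_beta,
                        config$sigma_gamma_shape, config$sigma_gamma_rate,
                        config$sigma_eps_scale2,
                        structured, config$use_likelihood, n_comp,
                        alpha0, beta0, gamma0, eps0, s2g0, se0)
    chains[[ch]] <- out
  }
  structure(list(chains = chains,
                 data = list(area_id = as.character(data$area_id), y = y,
                             E = E, x = x, N = N),
                 spec_label = if (structured) W$spec$label else "B",
                 config = config, rebalanced = FALSE),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  M <- length(x$chains[[1]]$alpha)
  cat(sprintf("bym_fit [%s]: %d areas, %d chains x %d stored draws%s\n",
              x$spec_label, x$data$N, length(x$chains), M,
              if (x$rebalanced) ", rebalanced" else ""))
  s <- posterior_summary(x)
  print(s, digits = 3)
  invisible(x)
}

#' Posterior summary of the scalar parameters
#'
#' @param fit a `bym_fit`.
#' @param probs quantiles to report.
#' @return Data frame with rows alpha, beta, sigma_gamma (sd scale, when
#'   present) and sigma_eps.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  pars <- list(alpha = pooled_draws(fit, "alpha"),
               beta = pooled_draws(fit, "beta"))
  if (fit$config$include_structured)
    pars$sigma_gamma <- sqrt(pooled_draws(fit, "sigma2_gamma"))
  pars$sigma_eps <- pooled_draws(fit, "sigma_eps")
  out <- t(vapply(pars, function(v) c(mean = mean(v),
                                      stats::quantile(v, probs)),
                  numeric(1 + length(probs))))
  as.data.frame(out)
}

# pooled vector (scalars) or M_total x N matrix (vectors) across chains
pooled_draws <- function(fit, what) {
  parts <- lapply(fit$chains, `[[`, what)
  if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
}

#' Per-draw linear predictor
#'
#' `eta_i = alpha + beta x_i + gamma_i + eps_i` for every stored draw,
#' pooled across chains. Invariant to the identifiability rebalancing.
#'
#' @param fit a `bym_fit`.
#' @return Matrix (total draws) x N.
#' @export
eta_draws <- function(fit) {
  a <- pooled_draws(fit, "alpha")
  b <- pooled_draws(fit, "beta")
  g <- pooled_draws(fit, "gamma")
  e <- pooled_draws(fit, "epsilon")
  a + outer(b, fit$data$x) + g + e
}

#' Excess variation of the structured effect
#'
#' `S(gamma)` is the standard deviation across areas of each area's
#' posterior median of `gamma` (`S(eps)` likewise); the share
#' `psi = S(gamma) / (S(gamma) + S(eps))` measures how much of the
#' across-area variation the structured effect carries and drives the
#' identifiability rebalancing.
#'
#' @param fit a `bym_fit`.
#' @param per_chain compute medians per chain instead of pooling draws.
#' @return List with `psi`, `S_gamma`, `S_epsilon` (per-chain: a list of
#'   such lists).
#' @export
excess_variation <- function(fit, per_chain = FALSE) {
  one <- function(g, e) {
    sg <- stats::sd(apply(g, 2L, stats::median))
    se <- stats::sd(apply(e, 2L, stats::median))
    if (sg + se == 0) stop("degenerate posterior: S(gamma) + S(eps) = 0")
    list(psi = sg / (sg + se), S_gamma = sg, S_epsilon = se)
  }
  if (per_chain) {
    lapply(fit$chains, function(ch) one(ch$gamma, ch$epsilon))
  } else {
    one(pooled_draws(fit, "gamma"), pooled_draws(fit, "epsilon"))
  }
}

#' Rebalance the random effects for identifiability
#'
#' Applies, to every stored draw and area, the update
#' `gamma := gamma - psi * eps`, `eps := eps + psi * eps`, where `psi`
#' defaults to the excess-variation share from [excess_variation()]. The
#' update conserves `gamma + eps` for every draw and area, so
#' log-relative-risk summaries are unchanged.
#'
#' @param fit a `bym_fit`.
#' @param psi rebalance weight in \[0, 1\]; computed from the fit when
#'   missing.
#' @return The modified `bym_fit`, with the `rebalanced` flag set and the
#'   applied `psi` attached.
#' @export
rebalance <- function(fit, psi = NULL) {
  if (is.null(psi)) psi <- excess_variation(fit)$psi
  stopifnot(psi >= 0, psi <= 1)
  for (ch in seq_along(fit$chains)) {
    e <- fit$chains[[ch]]$epsilon
    fit$chains[[ch]]$gamma <- fit$chains[[ch]]$gamma - psi * e
    fit$chains[[ch]]$epsilon <- e + psi * e
  }
  fit$rebalanced <- TRUE
  fit$psi <- psi
  fit
}
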