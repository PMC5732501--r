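log_mean_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(v - m)))
}

#' DIC3 model-fit criterion
#'
#' The deviance information criterion variant that plugs in the posterior
#' mean of the per-observation likelihood rather than the likelihood at
#' the posterior mean:
#' `DIC3 = -4/M sum_m sum_i log f(y_i | theta_m)
#'        + 2 sum_i log( 1/M sum_m f(y_i | theta_m) )`,
#' with `f` the Poisson density at `mu_im = E_i exp(eta_im)`. The density
#' average is computed in log space (log-sum-exp) for numerical safety.
#' A smaller value indicates a better fit; differences within 2 units are
#' read as a similar fit.
#'
#' @param y observed counts.
#' @param E expected counts.
#' @param eta matrix of linear-predictor draws, M x N (or a `bym_fit`, in
#'   which case `y` and `E` are taken from it).
#' @return List with `dic3` and `mean_deviance`
#'   (`-2/M sum_m sum_i log f`).
#' @export
dic3 <- function(y, E = NULL, eta = NULL) {
  if (inherits(y, "bym_fit")) {
    fit <- y
    y <- fit$data$y; E <- fit$data$E; eta <- eta_draws(fit)
  }
  if (any(E <= 0)) stop("expected counts must be positive")
  eta <- as.matrix(eta)
  M <- nrow(eta); N <- ncol(eta)
  stopifnot(length(y) == N, length(E) == N, M >= 1)
  ll <- matrix(stats::dpois(rep(y, each = M),
                            rep(E, each = M) * exp(eta), log = TRUE), M, N)
  mean_dev <- -2 * mean(rowSums(ll))
  lme <- apply(ll, 2L, log_mean_exp)
  if (any(!is.finite(lme)))
    stop("all posterior densities vanish for area(s) ",
         paste(which(!is.finite(lme)), collapse = ", "))
  list(dic3 = -4 * mean(rowSums(ll)) + 2 * sum(lme),
       mean_deviance = mean_dev)
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (N / S0) * sum_ij w_ij (z_i - zbar)(z_j - zbar) /
#'  sum_i (z_i - zbar)^2` with `S0 = sum_ij w_ij`. By default the weights
#' are row-standardised first (set `standardise = FALSE` to use them as
#' given). Under no autocorrelation the expectation is `-1/(N-1)`.
#'
#' @param z per-area values (non-constant).
#' @param W a `weights_matrix` or plain nonnegative matrix.
#' @param standardise row-standardise the weights before computing.
#' @return The statistic (scalar).
#' @export
morans_i <- function(z, W, standardise = TRUE) {
  w <- moran_weights(W, standardise)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom == 0) stop("Moran's I undefined for constant input")
  N <- length(z)
  S0 <- sum(w)
  as.numeric(N / S0 * (zc %*% w %*% zc) / denom)
}

moran_weights <- function(W, standardise = TRUE) {
  w <- if (inherits(W, "weights_matrix")) {
    if (standardise && !W$standardised) row_standardise(W)$w else W$w
  } else {
    w0 <- as.matrix(W)
    if (standardise) {
      rs <- rowSums(w0); rs[rs == 0] <- 1
      w0 / rs
    } else w0
  }
  if (all(w == 0)) stop("weights matrix has no positive entry")
  w
}

#' Permutation p-value for Moran's I
#'
#' Two-sided Monte-Carlo permutation test: `z` is randomly relabelled
#' across areas `n_perm` times and the p-value is
#' `(1 + #{ |I* - E[I]| >= |I_obs - E[I]| }) / (n_perm + 1)` with
#' `E[I] = -1/(N-1)`. Deterministic given `seed`. A normal-approximation
#' alternative under randomisation (`method = "normal"`) is provided for
#' comparison.
#'
#' @param z per-area values.
#' @param W a `weights_matrix` or matrix.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param standardise row-standardise the weights first.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return List with `I`, `p`, `expectation`.
#' @export
morans_p <- function(z, W, n_perm = 9999L, seed = 1L, standardise = TRUE,
                     method = c("permutation", "normal")) {
  method <- match.arg(method)
  w <- moran_weights(W, standardise)
  N <- length(z)
  EI <- -1 / (N - 1)
  I_obs <- morans_i(z, w, standardise = FALSE)
  if (method == "normal") {
    # randomisation variance (Cliff-Ord)
    S0 <- sum(w)
    S1 <- sum((w + t(w))^2) / 2
    S2 <- sum((rowSums(w) + colSums(w))^2)
    zc <- z - mean(z)
    b2 <- N * sum(zc^4) / sum(zc^2)^2
    varI <- (N * ((N^2 - 3 * N + 3) * S1 - N * S2 + 3 * S0^2) -
             b2 * ((N^2 - N) * S1 - 2 * N * S2 + 6 * S0^2)) /
            ((N - 1) * (N - 2) * (N - 3) * S0^2) - EI^2
    p <- 2 * stats::pnorm(abs(I_obs - EI) / sqrt(varI), lower.tail = FALSE)
    return(list(I = I_obs, p = min(1, p), expectation = EI))
  }
  if (n_perm < 0) stop("n_perm must be nonnegative")
  if (n_perm == 0) return(list(I = I_obs, p = 1, expectation = EI))
  set.seed(seed)
  ws <- Matrix::Matrix(w, sparse = TRUE)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  S0 <- sum(w)
  exceed <- 0L
  block <- 2000L
  done <- 0L
  t_obs <- abs(I_obs - EI)
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Z <- vapply(seq_len(b), function(k) zc[sample.int(N)], numeric(N))
    I_star <- N / S0 * colSums(Z * as.matrix(ws %*% Z)) / denom
    exceed <- exceed + sum(abs(I_star - EI) >= t_obs - 1e-14)
    done <- done + b
  }
  list(I = I_obs, p = (1 + exceed) / (n_perm + 1), expectation = EI)
}

#' Observed-data spatial autocorrelation
#'
#' Moran's I permutation test on the log standardised incidence ratio
#' `log((y + 0.5)/E)`. Raw counts confound the spatial signal with the
#' expected-count offset and the skew of the exponential link, so the
#' autocorrelation of the observed data is assessed on the log ratio
#' scale, where the latent field enters additively.
#'
#' @param data an `area_dataset` (needs `y` and `E`).
#' @param W a `weights_matrix`.
#' @param n_perm,seed passed to [morans_p()].
#' @return List with `I`, `p`, `expectation`.
#' @export
observed_moran <- function(data, W, n_perm = 9999L, seed = 1L) {
  morans_p(log((data$y + 0.5) / data$E), W, n_perm = n_perm, seed = seed)
}

#' Spatial autocorrelation of model residuals
#'
#' Moran's I and its permutation p-value computed on the posterior mean of
#' the unstructured effects `eps_i` (the model residuals), always with the
#' binary first-order (A1) weights regardless of which weights the model
#' was fitted with. If the model assumptions hold and smoothing has
#' captured the spatial structure, these residuals should be spatially
#' independent.
#'
#' @param fit a `bym_fit` (residuals are read after any rebalancing).
#' @param W_a1 the A1 `weights_matrix` used for the test.
#' @param n_perm,seed passed to [morans_p()].
#' @return List with `I` and `p`.
#' @export
residual_autocorrelation <- function(fit, W_a1, n_perm = 9999L, seed = 1L) {
  res <- colMeans(pooled_draws(fit, "epsilon"))
  out <- morans_p(res, W_a1, n_perm = n_perm, seed = seed)
  list(I = out$I, p = out$p)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classical split-free formulation from between- and within-chain
#' variances: with `m >= 2` chains of `n` draws,
#' `Rhat = sqrt( ((n-1)/n * W + B/n) / W )`. Values near 1 indicate the
#' chains have mixed.
#'
#' @param chains a list of numeric vectors (one per chain) or a matrix
#'   with one column per chain.
#' @return Scalar `Rhat`.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  m <- length(chains)
  if (m < 2L) stop("Gelman-Rubin requires at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("chains too short for a meaningful diagnostic")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Rhat for the main scalar parameters of a fit
fit_gelman_rubin <- function(fit) {
  pars <- c("alpha", "beta", "sigma_eps",
            if (fit$config$include_structured) "sigma2_gamma")
  vapply(pars, function(p) {
    gelman_rubin(lapply(fit$chains, `[[`, p))
  }, numeric(1))
}

#' Evaluate one fitted model
#'
#' Bundles DIC3, residual Moran's I (A1 weights) and the maximum
#' Gelman-Rubin factor over the scalar parameters.
#'
#' @param fit a (rebalanced) `bym_fit`.
#' @param W_a1 the A1 `weights_matrix` of the study geometry.
#' @param dataset_label label of the data set the model was fitted to.
#' @param n_perm,seed permutation-test settings.
#' @return A one-row `fit_evaluation` data frame: `model`, `dataset`,
#'   `dic3`, `mean_deviance`, `morans_I`, `morans_p`, `max_rhat`.
#' @export
evaluate_fit <- function(fit, W_a1, dataset_label = "dataset",
                         n_perm = 9999L, seed = 1L) {
  d <- dic3(fit)
  res <- residual_autocorrelation(fit, W_a1, n_perm = n_perm, seed = seed)
  rhat <- if (length(fit$chains) >= 2L) max(fit_gelman_rubin(fit)) else NA_real_
  out <- data.frame(model = fit$spec_label, dataset = dataset_label,
                    dic3 = d$dic3, mean_deviance = d$mean_deviance,
                    morans_I = res$I, morans_p = res$p, max_rhat = rhat,
                    stringsAsFactors = FALSE)
  class(out) <- c("fit_evaluation", class(out))
  out
}

#' Compare models fitted to one data set
#'
#' Sorts evaluations by DIC3, adds the difference to the best model and a
#' similar-fit flag (within 2 DIC units of the best).
#'
#' @param evaluations a list of `fit_evaluation` rows or a data frame of
#'   them, all with the same dataset label.
#' @return Data frame sorted by `dic3` with `delta_dic` and `similar_fit`
#'   columns.
#' @export
compare_models <- function(evaluations) {
  df <- if (is.data.frame(evaluations)) evaluations
        else do.call(rbind, evaluations)
  if (nrow(df) < 1L) stop("no evaluations to compare")
  if (length(unique(df$dataset)) != 1L)
    stop("evaluations mix dataset labels: ",
         paste(unique(df$dataset), collapse = ", "))
  df <- df[order(df$dic3), , drop = FALSE]
  df$delta_dic <- df$dic3 - df$dic3[1L]
  df$similar_fit <- df$delta_dic <= 2
  rownames(df) <- NULL
  df
}
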