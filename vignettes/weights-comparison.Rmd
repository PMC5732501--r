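---
title: "Spatial weights matrices in the BYM disease-mapping model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial weights matrices in the BYM disease-mapping model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymweights)
```

## The model

Disease counts in small areas are noisy: rare outcomes and small
populations make the raw standardised incidence ratio `y_i / E_i` an
unreliable estimate of the underlying risk. The Besag–York–Mollié (BYM)
model stabilises these estimates by borrowing strength across areas,

$$y_i \sim \mathrm{Po}(E_i e^{\eta_i}), \qquad
  \eta_i = \alpha + \beta x_i + \gamma_i + \varepsilon_i,$$

where `E_i` is the expected count (supplied externally, or computed from
populations by internal standardisation `E_i = P_i \sum y / \sum P`),
`x_i` a covariate, `gamma_i` a spatially *structured* random effect and
`eps_i` an unstructured one. The structured effect carries the intrinsic
conditional autoregressive (ICAR) prior

$$\gamma_i \mid \boldsymbol\gamma_{\setminus i} \sim
  \mathcal N\!\Big(\tfrac{1}{\sum_j w_{ij}}\sum_j w_{ij}\gamma_j,\;
  \tfrac{\sigma_\gamma^2}{\sum_j w_{ij}}\Big),$$

whose behaviour is governed entirely by the spatial weights matrix
$W = \{w_{ij}\}$. This package exists to study that dependence: it builds
seventeen different specifications of $W$, fits the model with each, and
compares the fits.

Priors follow the weakly informative choices of the study protocol:
$\alpha, \beta \sim \mathcal N(0, 100)$ (variance 100),
$\sigma_\varepsilon \sim \mathcal N(0, 10)\,\mathbb I_{(0,\infty)}$
(half-normal on the standard deviation), and
$\sigma_\gamma^2 \sim \mathcal G(3, 1)$ on the ICAR variance. The ICAR
prior is improper; it is identified by recentring $\gamma$ to sum to zero
after every sweep, with the removed mean absorbed into $\alpha$.

## The seventeen weights specifications

Four families, all exposed through `build_weights()`:

* **Adjacency** — `A1`: binary first-order contiguity (areas sharing a
  boundary or vertex; queen moves on a lattice). `A2`: neighbours up to
  third order with order weights $\omega = (e^0, e^{-0.5}, e^{-1})$.
  Order is shortest-path length in the first-order graph. The decreasing
  $\omega$ assigns the largest weights to the closest neighbours; the
  vector is a parameter, so other profiles are available.
* **Geographic distance** — kernels on Euclidean centroid distances
  $d_{ij}$: inverse powers $(1/d_{ij})^k$ with $k = 1, 2, 5$ (`D1`–`D3`),
  exponential decay $e^{-\lambda d_{ij}}$ (`D4`) and Gaussian decay
  $e^{-d_{ij}^2/2b^2}$ (`D5`).
* **Covariate distance** — `C1`–`C5`: the same five kernels with
  $d_{ij}$ replaced by $\delta_{ij} = |x_i - x_j|$, smoothing areas that
  are similar in covariate space rather than nearby on the map.
* **Hybrid** — `H1`–`H5`: the kernels applied to the product
  $d_{ij}\,\delta_{ij}$.

The decay and bandwidth parameters are tied to the scale of the map:
$\lambda = 10 / \bar d$ with $\bar d$ the mean off-diagonal distance
(covariate or hybrid distances for the C and H families), and
$b = 1/\lambda$. This makes `D4`/`D5` invariant to a change of distance
units, which the tests assert exactly. The constant 10 is a configurable
default (`decay_numerator`), not a hard-coded value.

Inverse-power kernels produce non-finite weights wherever a distance is
zero — possible geographically (an area nested inside another shares its
centroid) and common in covariate space (tied values). Following the
study protocol, `sanitise_symmetrise()` replaces each non-finite entry by
the maximum finite value in its row and then restores symmetry by copying
the transposed upper triangle over the lower. A row with *no* finite
off-diagonal entry is an error rather than a silent patch: the repair
rule is undefined there.

Row standardisation is available explicitly (`row_standardise()`), and
`fit_bym()` standardises internally: the supplied symmetric matrix is
scaled to unit row sums and symmetrised as $(\tilde W + \tilde W')/2$
before entering the ICAR conditional. Two consequences matter. First, the
conditional mean is unchanged (it is already a weighted average). Second,
every non-island area gets conditional variance $\approx \sigma_\gamma^2$
regardless of how much raw weight mass its row carries. Without this, the
dense kernels (every area has $N-1$ positive weights) have row sums in
the tens on a lattice, the conditional variance collapses, and the
structured effect is pinned to a near-global average — the model then
cannot smooth at all. Islands (zero rows) are tolerated with a warning
and their structured effect pinned to zero.

## Identifiability and rebalancing

Only the sum $\gamma_i + \varepsilon_i$ is identified by the likelihood.
After sampling, the package computes the excess-variation share

$$\psi = \frac{S(\gamma)}{S(\gamma) + S(\varepsilon)}, \qquad
  S(\gamma) = \mathrm{sd}_i\big\{\mathrm{median}_m\, \gamma_i^{(m)}\big\},$$

and applies, to every stored draw,
$\gamma_i^{(m)} := \gamma_i^{(m)} - \psi\,\varepsilon_i^{(m)}$ and
$\varepsilon_i^{(m)} := \varepsilon_i^{(m)} + \psi\,\varepsilon_i^{(m)}$.
The update is implemented exactly as printed in the protocol it follows.
Note that the second assignment *inflates* the unstructured effect rather
than transferring variation to it; the pair nevertheless conserves
$\gamma + \varepsilon$ for every draw and area — asserted exactly in the
tests — so relative-risk summaries are unaffected. $S(\cdot)$ pools
chains by default (`per_chain = TRUE` is available); the choice is not
prescribed anywhere and pooling matches how the single reported DIC is
computed.

## The sampler

`fit_bym()` runs Metropolis-within-Gibbs chains in compiled code:
single-site random-walk updates for each $\gamma_i$ (ICAR conditional
times Poisson likelihood) and $\varepsilon_i$, random-walk updates for
$\alpha$ and $\beta$, and log-scale random-walk updates for the two scale
parameters against their exact full conditionals. The
$\sigma_\gamma^2$ conditional under a Gamma prior *on the variance* is a
generalised inverse Gaussian, not a standard conjugate family, hence the
Metropolis step; it includes the $(N - G)/2$ normalising exponent of the
constrained ICAR density ($G$ = number of connected components), which is
what makes the prior-recovery check below pass.

Three additional exact moves address the notorious ridges of the BYM
parameterisation, which single-site updates traverse as slow random
walks:

* an interchange Metropolis move $\gamma \to \gamma + \delta
  \varepsilon_c$, $\varepsilon \to \varepsilon - \delta \varepsilon_c$
  (with $\varepsilon_c$ the centred residual vector), which leaves the
  likelihood invariant and is accepted against the two priors with
  Jacobian $|1-\delta|^{N-1}$;
* Gibbs translations along $(\alpha + c, \varepsilon - c)$ and
  $(\beta + t, \varepsilon - t x)$, whose conditionals are Gaussian
  because the likelihood is flat along them;
* a Gibbs translation along $(\beta + t, \gamma - t x_c)$, countering
  spatial confounding between a spatially smooth covariate and the ICAR
  field.

Without these moves we observed potential scale reduction factors above
10 on strongly autocorrelated data; with them the full protocol (2 chains
of 25,000 kept iterations, thinning 5, burn-in 10,000) yields
$\hat R \le 1.02$ on the same data. Proposal scales adapt only during
burn-in (target acceptance 0.44 for single-site moves), so kept draws
come from a fixed kernel. Chains are initialised from overdispersed prior
draws with chain-indexed sub-seeds; every fit is a pure function of
(data, weights, configuration).

Sampler correctness is tested by calibration rather than inspection: with
the likelihood switched off the chain targets the joint prior, and the
marginal $\sigma_\gamma^2$ draws must reproduce the Gamma(3, 1) mean and
variance within batch-means Monte-Carlo error at 50,000 draws. Parameter
recovery is tested on data simulated from the model itself (the
structured effect drawn from the constrained ICAR via the eigenbasis of
its singular precision): the 95% credible interval for $\beta$ must cover
the truth in at least 90 of 100 replicates.

## Synthetic data

Real registry data rarely come with a known risk surface, so the package
generates areal data sets on a 12×12 lattice from additive components on
the log scale: an underlying spatial random field (USRF), a covariate
correlated with it, log expected counts, and extra observation noise;
observed counts are Poisson around the exponentiated sum (deterministic
rounding is available via `discretise = "round"`). Three regimes emulate
three spatial structures:

* **noise** — iid Gaussian USRF (sd 0.2): no spatial pattern;
* **smooth** — a proper conditional-autoregressive draw
  ($\rho = 0.99$) convolved with three passes of queen-neighbourhood
  averaging and rescaled to sd 0.8. The convolution matters: a CAR draw
  is locally rough, and thresholding or smoothing-based recovery both
  behave very differently on a genuinely smooth surface;
* **clusters** — a convolution of two fields: a smoothed large-scale
  draw thresholded at its upper quartile defines high/low regions; the
  high region receives a positive level modulated by a shorter-range
  correlated field; small-scale noise is added everywhere. Across seeds
  the high region typically decomposes into two to six contiguous
  patches, most often around four.

The covariate is a noisy rescaling of the USRF. Its noise sd defaults to
$\sqrt 3$ times the field sd, giving a correlation near 0.5 — strong
enough that covariate-space smoothing is meaningful, weak enough that the
covariate cannot simply replace the field. In the noise regime the
covariate is tighter (correlation ≈ 0.7) and its generating coefficient
larger (1.5 versus 0.3), so the covariate effect dominates both random
effects there. Log expected counts mix $\mathcal N(2, 0.15^2)$ (with
probability 0.95) with $2 + \mathcal G(2, 3)$, centring counts near
$e^2 \approx 7.4$ with a handful of larger values, similar in shape to
cancer-registry expected counts.

These defaults were fixed once, by simulating across seeds until the
regimes met their contracts: the smooth and clusters regimes show
overwhelming positive autocorrelation in the observed data (permutation
p below $10^{-4}$ in roughly nine out of ten seeds) and the noise regime
does not (p above 0.05 in ≈95% of seeds). What passing these contracts
does *not* show: the generator makes no attempt to reproduce any
particular real map, irregular area sizes, population structure, or
covariates measured with error; conclusions about weight specifications
on such data need the user's own inputs.

Observed-data autocorrelation is assessed on the log standardised ratio
$\log((y_i + 0.5)/E_i)$ (`observed_moran()`). Raw counts confound the
spatial signal with the expected-count offset and the skew of the
exponential link; on the ratio scale the latent field enters additively
and the permutation test has the power the regime contracts require.

## Model evaluation

* **DIC3** (`dic3()`): $-4\,\overline{\log f} + 2\sum_i \log \hat f(y_i)$
  with $\hat f(y_i)$ the posterior mean of the per-area Poisson density,
  averaged in log space via log-sum-exp. This variant stays meaningful
  where the plug-in DIC can go negative. Models within 2 units of the
  best are flagged as a similar fit by `compare_models()`.
* **Moran's I** (`morans_i()`, `morans_p()`): computed on row-standardised
  weights by default, with a two-sided permutation p-value around the
  null expectation $-1/(N-1)$ (add-one rule; 9,999 permutations by
  default, deterministic given a seed). A Cliff–Ord normal approximation
  is available as `method = "normal"`. Model adequacy uses the posterior
  mean of the rebalanced residuals $\varepsilon_i$, always with A1
  weights so that models with different $W$ are judged against the same
  notion of neighbourhood.
* **Gelman–Rubin** (`gelman_rubin()`): the classical between/within
  formulation without rank normalisation; `run_study()` flags (never
  drops) fits whose maximum $\hat R$ over scalar parameters exceeds 1.1.

## Numerical choices and degenerate inputs

Coincident centroids and tied covariates are legal inputs; they flow
through the non-finite repair path. Polygon contiguity snaps vertices to
a $10^{-9}$ grid before comparing; lattice cells are unit squares centred
on integer grid points, ordered row-major. Disconnected maps are allowed
everywhere; the ICAR normalising exponent counts components, and islands
are pinned. The permutation test uses a small tolerance
($10^{-14}$) when comparing permuted statistics to the observed one so
that ties of identical floating-point values count as exceedances.
Sub-seeds in `run_study()` are polynomial hashes of the dataset and spec
labels added to the master seed, so adding a model to a study never
changes any other model's results.

## Problem sizes used by the checks

The bundled checks run at sizes chosen to exercise every code path at
desk scale: the prior-recovery calibration uses a 4×4 lattice and 50,000
draws; parameter recovery uses 100 data sets of 144 areas with 2 chains
× 5,000 total iterations each; the weights-comparison check fits eight
models (A1, A2, D1–D5 and the benchmark) with 2 chains × 10,000 kept
iterations after a 5,000 burn-in. The full protocol (25,000 kept after
10,000 burn-in) takes about ten seconds per model on 144 areas and is
the default for `fit_bym()`.

## Known limitations

* The printed rebalancing update inflates $\varepsilon$; we reproduce it
  verbatim rather than substituting the transfer its originators likely
  intended, and flag the discrepancy here.
* The hybrid distance $d_{ij}\delta_{ij}$ under-smooths when either
  factor is small; a logarithmic combination is sometimes suggested and
  is not implemented.
* Shapefile input is not supported; supply GeoJSON, a GAL adjacency
  list, or use the lattice constructor.
* The minimum DIC3 advantage of smoothing over the no-smoothing
  benchmark depends strongly on how local the weights are: on a regular
  lattice the flattest kernel (inverse distance, $k = 1$) yields only a
  few units of improvement, while concentrated kernels (A1, D3, D5)
  yield tens. See the comparison tables produced by `run_study()`.
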