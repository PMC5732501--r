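# bymweights

Tools for studying how the specification of the spatial weights matrix
affects Bayesian disease mapping. Small-area disease counts are modelled
with the Besag–York–Mollié (BYM) Poisson log-linear model,

    y_i ~ Po(E_i exp(eta_i)),    eta_i = alpha + beta x_i + gamma_i + eps_i,

where the structured random effect `gamma` carries an intrinsic
conditional autoregressive (ICAR) prior,

    gamma_i | rest ~ N( sum_j w_ij gamma_j / w_i+ ,  sigma_g^2 / w_i+ ),

whose behaviour is controlled entirely by the spatial weights matrix
`W = {w_ij}`. The package builds seventeen specifications of `W` across
four families — adjacency (`A1`, `A2`), geographic distance (`D1`–`D5`:
inverse powers k = 1, 2, 5, exponential decay, Gaussian decay), covariate
distance (`C1`–`C5`) and hybrid geographic×covariate distance
(`H1`–`H5`) — fits the BYM model with each of them (plus a no-smoothing
benchmark, model `B`) by MCMC with compiled inner loops, restores
identifiability of the two random effects with an excess-variation
rebalancing, and evaluates every fit with the DIC3 information criterion
and permutation tests of Moran's I on the residuals.

It also ships a synthetic-data generator that builds 12×12-lattice areal
data sets from Gaussian Markov random fields in three regimes (no
autocorrelation; a smooth strongly autocorrelated surface; clusters of
elevated risk from a convolution of two fields), so the smoothing
behaviour of each weights specification can be studied against a known
latent surface.

Intended users: spatial epidemiologists and biostatisticians comparing
neighbourhood definitions for areal smoothing, and methodologists who
need a self-contained, reproducible BYM/ICAR reference implementation.

## Worked example

Compare four weight specifications on a generated smooth-surface data
set:

```r
library(bymweights)

cfg <- study_config(
  datasets = list(smooth = generator_config(regime = "smooth", seed = 1)),
  specs    = c("A1", "D5", "C3", "B"),
  bym      = bym_config(chains = 2, iter = 10000, burnin = 5000, thin = 5),
  n_perm   = 9999, seed = 1)
report <- run_study(cfg)
print(report)
#> == dataset: smooth ==
#>   model  dic3 delta_dic similar_fit morans_p
#> 1    D5 714.6      0.00        TRUE   0.7666
#> 2    A1 717.0      2.44       FALSE   0.7961
#> 3    C3 740.1     25.56       FALSE   0.0001
#> 4     B 743.1     28.58       FALSE   0.0001
```

Reading the table: Gaussian-decay distance weights (`D5`) give the best
DIC3, with binary first-order adjacency (`A1`) within ~2.4 units; both
cut about 26–29 DIC units relative to the no-smoothing benchmark `B`.
The `morans_p` column is the permutation p-value of Moran's I on the
posterior-mean residuals with A1 weights: `D5` and `A1` leave no
detectable residual autocorrelation (p ≈ 0.77, 0.80), whereas the
covariate-distance model `C3` and the benchmark leave the spatial signal
in the residuals (p = 1e-4, the smallest value the 9,999-permutation
test can report).

The observed data themselves are strongly autocorrelated under every
tested weights definition:

```r
report$smooth$observed_moran
#>   spec     I     p
#> 1   A1 0.563 1e-04
#> 2   A2 0.435 1e-04
#> 3   D2 0.379 1e-04
#> 4   C3 0.490 1e-04
#> 5   H5 0.531 1e-04
```

Individual pieces are exported too: `grid_lattice()`, `read_geojson()`,
`read_gal()` for geometry; `build_weights()`, `row_standardise()`,
`neighbour_profile()` for weights; `generate_dataset()` for synthetic
data; `fit_bym()`, `rebalance()`, `excess_variation()` for the model;
`dic3()`, `morans_p()`, `gelman_rubin()`, `compare_models()` for
evaluation. A thin command-line wrapper with `simulate`, `weights`,
`fit` and `study` subcommands lives in `inst/scripts/bym-study.R`.

Real data are supplied as a CSV attribute table (`area_id`, `y`, `E` or
`P`, optional `x`; `load_area_csv()` applies internal standardisation
when only populations are given and a covariate scaling divisor if
needed) together with GeoJSON polygons or a GAL adjacency list.

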