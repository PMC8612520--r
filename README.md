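# coopgames

Phylogenetic multinomial regression for cross-cultural analyses of game
goal structures.

Traditional rule-based games differ in whether their players act alone
(solitary), against each other (competitive), or in coordinated groups
(cooperative). `coopgames` asks whether the mix of these goal structures
across ethnolinguistic groups covaries with socio-ecological attributes
of those groups — group hunting on land or water, intra- and inter-group
conflict, social stratification — while accounting for the groups'
shared cultural descent (Galton's problem) through a language phylogeny.
It is aimed at cultural-evolution and phylogenetic comparative
researchers working with per-society count data keyed to a tree.

The package provides the complete pipeline:

- **Ingest**: read game and covariate tables, apply a six-step record
  filter (vocabulary-database linkage, describability, local origin,
  tree membership, covariate availability, temporal overlap within a
  ±50-year window), collapse the six fine-grained goal-structure codes
  into the three analysis categories, and tabulate per-group counts.
- **Phylogeny**: read and prune a Newick language tree (root-to-tip
  distances conserved) and build the Brownian-motion variance-covariance
  matrix, standardized to unit depth.
- **Model + inference**: Bayesian multinomial-logit regression of the
  per-group count triples on binary covariates, with or without
  phylogenetically correlated random effects, sampled with JAGS; WAIC
  model comparison with normalized weights.
- **Synthetic data**: a generator for complete studies (tree,
  covariates, games) with the empirical study's shape — 25 groups, 168
  games, 11 groups with only 1–3 games — used for parameter-recovery and
  coverage experiments.

## The model

For group *j* with *N_j* games, the counts over the three categories
are

```
y_j ~ Multinomial(N_j, softmax(eta_j))
eta_jk = alpha_k + sum_p beta_kp x_jp + phi_jk      (k != reference)
eta_j,ref = 0                                       (reference: competitive)
```

with binary predictors *x* (present = 1, absent = 0; groups missing a
predictor are dropped for that model). `beta_k,p` on the cooperative
equation is therefore the change in log-odds of cooperative relative to
competitive games when covariate *p* is present. Phylogenetic models add
`phi_.k ~ MVN(0, sigma_k^2 C)` where `C` is the Brownian-motion
covariance of the pruned tree (shared root-to-tip path lengths,
standardized to unit depth). Priors are weakly regularizing:
Normal(0, 2.5) on intercepts and slopes, half-Normal(1) on `sigma`.
Models are compared by WAIC; `D` is each model's WAIC difference from
the best, and `W = exp(-D/2)` normalized over the full model set.

## Worked example

The package ships a small synthetic study (8 groups, 60 games, one
planted violation of each filter step) under `inst/extdata`; all files
are generated by `simulate_study()` and labeled synthetic.

```r
library(coopgames)
games <- read_games(system.file("extdata", "synthetic_games.csv", package = "coopgames"))
covs  <- read_covariates(system.file("extdata", "synthetic_covariates.csv", package = "coopgames"))
tree  <- read_newick(system.file("extdata", "synthetic_tree.nwk", package = "coopgames"))

res <- filter_games(games, covs, tree$tip.label, window_years = 50)
res$report
#>             step n_before n_after
#> 1    abvd_linked       66      65
#> 2    describable       65      64
#> 3   local_origin       64      63
#> 4        on_tree       63      62
#> 5 has_covariates       62      61
#> 6   time_overlap       61      60
```

Each filtering step removes exactly one of the planted violations,
leaving the 60 genuine games. Tabulate and fit the univariate
land-hunting model with phylogenetic controls:

```r
counts <- tabulate_counts(res$games)
C <- phylo_covariance(prune_tree(tree, rownames(counts)))
spec <- model_spec("land_hunt", use_phylo = TRUE)
dd <- build_design(covs, counts, spec)
fit <- sample_posterior(spec, dd$design, dd$counts, C,
                        mcmc_config(chains = 2, warmup = 1000, iter = 1000, seed = 1))
summarize_posterior(fit, pars = "^(alpha|beta|sigma)")
#>                     parameter  mean  lower upper
#> 1             alpha[solitary] -0.73 -1.673  0.27
#> 2          alpha[cooperative] -0.36 -1.571  0.62
#> 3    beta[solitary,land_hunt]  0.69 -0.918  2.25
#> 4 beta[cooperative,land_hunt]  0.65 -0.836  2.22
#> 5             sigma[solitary]  0.57  0.037  1.51
#> 6          sigma[cooperative]  0.85  0.176  1.80
```

`beta[cooperative,land_hunt]` is the estimated shift in the log-odds of
cooperative (vs competitive) games where group land hunting is present:
positive here (posterior mean 0.65), but with a 90% interval spanning
zero at this small synthetic sample size. Comparing against the same
model without phylogenetic controls:

```r
fit0 <- sample_posterior(model_spec("land_hunt"), dd$design, dd$counts,
                         mcmc = mcmc_config(chains = 2, warmup = 1000, iter = 1000, seed = 1))
compare_models(list("land_hunt (phylo)" = waic(fit), "land_hunt" = waic(fit0)))
#>               model waic    D      W
#> 1 land_hunt (phylo) 46.9 0.00 0.9442
#> 2         land_hunt 52.5 5.66 0.0558
```

`fit_battery()` runs the full 18-model set (base, six univariate, two
multivariate models, each with and without phylogenetic controls) and
`effect_table()` lays the results out as one row per model with the
predictor effect, 90% interval, `D` and `W`. The same stages are
available as config-driven runners (`run_filter()`, `run_fit()`,
`run_simulate()`, `run_recover()`) and as a thin command-line wrapper in
`inst/cli/coopgames.R`.

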