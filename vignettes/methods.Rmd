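---
title: "Phylogenetic multinomial regression of game goal structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic multinomial regression of game goal structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coopgames` estimates how the goal structures of traditional rule-based
games — solitary, competitive, cooperative — covary with binary
socio-ecological attributes of the ethnolinguistic groups that play
them, while controlling for the groups' shared cultural descent via a
language phylogeny. This vignette documents the modelling choices in
enough detail to audit or extend them.

## Data model and filtering

The unit of analysis is the ethnolinguistic group. Each game record
carries a six-level goal-structure code (solitary; competitive;
competitive vs solitary; competitive vs cooperative group; cooperative
group vs cooperative group; cooperative), three pre-coded boolean
quality flags, and the time frame of its ethnographic description.
The filter applies six steps in a fixed order: linkage to a
basic-vocabulary language code, describability, local origin, presence
on the analysis tree, availability of covariate data, and temporal
overlap between the game description and the covariate reference year
within a ±50-year window. The first three judgments are human coding
work and enter the pipeline as flags; the pipeline's job is their
auditable application, and `filter_games()` returns a per-step report
(before/after counts) so the chain of sample sizes is always
reconstructible.

Two readings of the temporal rule are possible; the package uses closed
intervals with any-overlap semantics, i.e. a game described over
`[start, end]` is kept when `start <= focus + 50` and
`end >= focus - 50`. A symmetric "±50 years" window naturally includes
its endpoints, and any-overlap is the weakest assumption consistent
with treating the description period as informative about the covariate
period.

The six codes are collapsed to three analysis categories: any game with
a cooperative component (cooperative; cooperative group vs cooperative
group; competitive vs cooperative group) is *cooperative*; games with
competition but no cooperation (competitive; competitive vs solitary)
are *competitive*; *solitary* stands alone. The collapse is a total
map, so category totals always equal the number of filtered games.
Groups whose filtered total is zero are excluded from the count matrix:
a multinomial row with `N = 0` carries no likelihood information, and
keeping such rows would silently dilute group counts reported in
descriptive summaries. "At least half" in the descriptive majority
counts is the inclusive `>= 0.5` of the group total.

## The regression model

For group $j$ with $N_j$ games and count triple $y_j$,

$$y_j \sim \mathrm{Multinomial}(N_j,\ \mathrm{softmax}(\eta_j)), \qquad
\eta_{jk} = \alpha_k + \textstyle\sum_p \beta_{kp} x_{jp} + \phi_{jk},$$

with the reference category's score pinned at zero. The reference is
*competitive*, so $\beta$ on the cooperative equation is the change in
log-odds of cooperative relative to competitive games when a covariate
is present — the contrast of scientific interest. Solitary games get
their own free equation rather than being folded into either other
category; the three-category multinomial uses all the information in
the data without asserting that solitary games behave like either
competitive or cooperative ones.

Predictors are binary (present = 1, absent = 0). Missing covariate
values are handled by complete-case deletion *per model*: a group is
dropped only from models that actually use the missing covariate, and
every drop is recorded in the design object. No imputation is
performed; with 25 groups, imputation models would be poorly informed
and would blur the interpretation of the per-model sample.

Priors are weakly regularizing and exposed as `model_spec()` arguments:
Normal(0, 2.5) on intercepts and slopes (on the log-odds scale, 2.5 is
wide enough to cover any plausible odds ratio while damping the
separation-driven divergence that small multinomial samples invite) and
half-Normal(1) on the random-effect scales $\sigma_k$ (a priori most
mass below 1 log-odds unit of between-group spread, which is already a
large cultural difference).

## Phylogenetic random effects

Groups related by descent are not independent observations. Models
"with phylogenetic controls" add, per non-reference category $k$, a
group-level effect vector

$$\phi_{\cdot k} \sim \mathrm{MVN}(0,\ \sigma_k^2\, C),$$

where $C$ is the Brownian-motion variance-covariance matrix of the
pruned tree: $C_{ab}$ is the shared root-to-tip path length of tips $a$
and $b$. The two categories' effect vectors are independent — the
simplest structure consistent with correlated random effects, avoiding
a cross-category correlation parameter that 25 groups cannot
realistically inform. Non-phylo models contain no group-level random
effect at all, so the comparison isolates exactly the contribution of
phylogenetically structured variation.

Three numerical choices matter here:

- **Standardization.** $C$ is divided by the maximum root-to-tip depth,
  so the diagonal is 1 for ultrametric trees and $\sigma_k$ is
  interpretable as the marginal between-group standard deviation
  regardless of the tree's time units.
- **Stem conservation under pruning.** `ape::keep.tip()` re-roots at
  the most recent common ancestor of the kept tips, discarding the
  common stem. `prune_tree()` restores that stem as a root edge and
  `phylo_covariance()` adds it to all entries, so pruning commutes
  exactly with row/column selection of the covariance (a tested
  invariant). A shared stem only shifts all entries equally — it is
  absorbed by the intercept in the likelihood — but conserving it keeps
  root-to-tip distances and covariances consistent between pruned and
  unpruned analyses.
- **Jitter.** Language trees can contain zero-length branches
  (effectively identical tips), making $C$ singular. A `1e-8` diagonal
  jitter is added before Cholesky factorization; at the unit-depth
  scale this is far below any scientifically meaningful covariance.

A star tree gives diagonal $C$, so the phylo model must collapse to the
non-phylo model plus independent noise; with $\sigma$ fixed at 0 the
two posteriors must agree within Monte Carlo error. Both degenerate
limits are exercised in the test suite.

## Sampling and parameterization

The posterior is sampled with JAGS (via `rjags`). The random effects
use the non-centered parameterization $\phi_{\cdot k} = \sigma_k L z$,
$z \sim \mathrm{N}(0, I)$, with $L$ the lower Cholesky factor of the
jittered $C$; this is equivalent to the MVN prior above and mixes far
better when the data are consistent with small $\sigma$, which is
exactly the regime of interest when comparing against non-phylo models.
Defaults are 4 chains of 1000 warmup plus 1000 kept iterations — sized
for a 25-group, ~50-parameter posterior, where this yields effective
sample sizes in the hundreds to thousands. Each chain receives a
deterministic RNG stream derived from the configured seed, so runs are
exactly reproducible. `sample_posterior()` computes split-half R-hat
and effective sample size per parameter and warns when R-hat exceeds
1.01 or ESS falls below 400.

The per-draw, per-group log-likelihood matrix used by WAIC is
recomputed in R from the monitored draws using the package's own
`linear_predictor()` and `log_likelihood()` (log-sum-exp throughout),
rather than trusting the sampler's internals; a test verifies the
vectorized recomputation against a draw-by-draw loop.

## Model comparison

WAIC is computed with the pointwise unit being the ethnolinguistic
group (the likelihood factorizes by group):
$\mathrm{lppd} = \sum_j \log \frac{1}{S}\sum_s \exp \ell_{sj}$,
$p_\mathrm{WAIC} = \sum_j \mathrm{Var}_s(\ell_{sj})$ with the
$S - 1$ denominator, and $\mathrm{WAIC} = -2(\mathrm{lppd} -
p_\mathrm{WAIC})$. Model weights are
$W_m = \exp(-D_m/2)/\sum_{m'} \exp(-D_{m'}/2)$ with
$D_m = \mathrm{WAIC}_m - \min \mathrm{WAIC}$, normalized over the
*entire* supplied set — phylogenetic and non-phylogenetic models
together — so the weights answer "which model variant, including the
control structure, predicts best".

The default battery is 18 models: base, six univariate models (land
hunting, water hunting, intra-group conflict, intra-cultural conflict,
inter-cultural conflict, social stratification), and two multivariate
models pairing each conflict variable of interest with land hunting,
each with and without phylogenetic controls. Models that fail to
converge are flagged in the effect table rather than dropped.

## The synthetic-data generator

`simulate_study()` generates complete studies with the statistical
structure the analysis assumes, so every stage — including the
fine-grained-to-collapsed recoding — can be exercised without any
external data:

- **Tree**: a pure-birth (Yule) tree conditioned on the tip count
  (`ape::rphylo` with zero extinction), rescaled to unit depth. A Yule
  tree is the minimal standard branching prior; an empirical tree can
  be substituted through the Newick reader at any point.
- **Covariates**: iid Bernoulli(prevalence) per tip by default, or —
  to emulate cultural traits with phylogenetic signal — a Brownian
  trait simulated on the tree and thresholded at its prevalence
  quantile. Missingness is applied iid.
- **Group totals**: defaults reproduce the empirical skew (168 games
  over 25 groups, exactly 11 groups with 1–3 games; the remaining games
  are spread by a gamma-weighted multinomial with a floor of 4). This
  imbalance is deliberately preserved because it stresses the model
  exactly where the real data do.
- **Counts**: drawn from the model itself, with random effects drawn
  from $\mathrm{MVN}(0, \sigma^2 C)$; true intercepts default to the
  pooled analysis-sample proportions (23/85/60). Each collapsed count
  is then split uniformly across that category's member codes to emit a
  six-code game table, and filter flags are set passing — with an
  option to plant exactly one violation of each filter step.

What passing recovery tests show: with data generated *from the model
at the study's scale*, the pipeline recovers generating effects with
near-nominal 90% interval coverage and small bias. What they do not
show: robustness to model misspecification — real covariates are not
Bernoulli draws, real trees are not Yule, real goal-structure codings
carry observer error, and the uniform within-category code split is a
convenience. The generator validates the inferential machinery, not
the ethnographic data model.

One property of the study conditions is worth flagging: with
phylogenetic effect scale 0.5, single synthetic studies show large
between-study variation in the realized covariate–outcome contrast
(the effective number of independent observations on a deep tree is
much smaller than the number of tips). This is not an estimator defect
— fits track each realized data set closely, and recovery experiments
across replicates are well calibrated — but it is a reminder of how
little information 25 phylogenetically related groups contain about a
group-level effect, with or without controls.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations to the
study scale they validate: recovery experiments use 50 replicates of
25-group/168-game studies with generating effects in {−1, 0, 1} and
effect scale 0.5, fitted with 2 chains of 500 + 500 iterations;
positive-semidefiniteness of the covariance construction is checked
over 1000 random Yule trees; the likelihood is verified against
exhaustive enumeration for every count triple with total at most 5 on
100 random probability vectors; and the degenerate-limit agreement
check runs two 2-chain fits of 1000 kept iterations each. These reduced
MCMC settings trade effective sample size for replicate count; the
quantities asserted (coverage across replicates, posterior-mean
differences within Monte Carlo error) are the ones robust to that
trade.

## Known limitations

- The covariance is a Brownian-motion kernel on a single fixed tree;
  no Ornstein–Uhlenbeck kernel, tree-posterior averaging, or
  measurement model for the covariates is provided.
- At most two predictors per model, no interactions, no continuous
  predictors — matching the scale of data the method is designed for.
- WAIC is the only comparison criterion (no cross-validation); with 25
  pointwise units its standard error is substantial, and weights
  should be read accordingly.
- Counts weight each game equally; time spent playing, player ages,
  and within-group variation in game practice are outside the data
  model.
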