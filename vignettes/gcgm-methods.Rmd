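---
title: "Bayesian Gaussian copula graphical models for mixed cohort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Gaussian copula graphical models for mixed cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcgm)
```

## The model

`bgcgm` estimates which pairs of variables in a cohort are *conditionally*
dependent — related after the linear effect of every other variable has been
removed — together with the strength of each dependence (the partial
correlation) and, crucially, the posterior uncertainty of both. The intended
application is multi-domain cohort data of the kind collected in Alzheimer's
disease studies: demographics, cognitive composite scores, genetics, an
ordinal amyloid stage, and region-specific gray-matter volume and glucose
uptake.

The backbone is a Gaussian graphical model. Latent variables
$Z_1,\dots,Z_p$ follow a multivariate normal with mean zero and precision
matrix $K = \Sigma^{-1}$. A zero entry $k_{ij} = 0$ is equivalent to
conditional independence of $Z_i$ and $Z_j$ given the rest, so the support
of $K$ *is* the conditional-dependence graph $G$, and

$$\rho_{ij} = -\,k_{ij}\big/\sqrt{k_{ii}\,k_{jj}}$$

is the partial correlation. Inference targets the joint posterior
$P(G, K \mid Z) \propto P(Z \mid K)\, P(K, G)$ with

* an independent Bernoulli prior over edges with inclusion probability 0.2
  (a weakly sparse default: each pair is conditionally dependent with prior
  probability 20%), and
* a G-Wishart prior $K \mid G \sim \mathrm{GW}(\delta, D)$ with $\delta = 3$
  and $D = I$ — the conventional weakly-informative choice; both are
  config-exposed in `prior_spec()` because nothing in the scientific setup
  pins them down.

Observed cohort variables are not Gaussian: sex and APOE4 carrier status are
binary, the amyloid stage is a five-level ordinal score, education is in
whole years, and the imaging variables are skewed positive ratios. The
Gaussian *copula* links each observed variable to its latent column through
a monotone margin:

* **Continuous variables** (imaging variables, the two cognitive composites,
  and age — recorded in years but treated as continuous) are transformed
  once, before the chain starts, by the rank-based semiparametric map
  $\hat z_i = \Phi^{-1}\!\big(r_i/(n+1)\big)$ with average ranks for ties.
  Partial correlations are invariant to monotone margins, so ranks carry all
  the relevant information. The $n+1$ denominator keeps the transform
  finite; the classical Winsorized variant (truncation of the empirical CDF
  at $\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$) is available via
  `nonparanormal(, method = "winsorized")`. Transformed columns are
  standardized to unit variance once — partial correlations are
  scale-invariant and the standardization only stabilizes the sampler.
* **Discrete variables** (sex, APOE4, education, amyloid stage) are
  re-imputed at every MCMC iteration under the extended rank likelihood:
  the latent cell $z_{ij}$ is drawn from its exact univariate conditional
  $N\!\big(-\tfrac{1}{k_{jj}}\sum_{l \ne j} k_{jl} z_{il},\; 1/k_{jj}\big)$
  truncated to the interval allowed by the observed ordering — above every
  latent value of rows with a smaller observation and below every latent
  value of rows with a larger one. Ties impose no mutual constraint.

## The sampler

Each iteration performs three steps.

1. **Copula sweep.** A systematic Gibbs scan over the discrete columns
   (fixed column-major then row-major order, for reproducibility). The scan
   processes observed levels in increasing order, so the lower truncation is
   the running maximum of already-updated lower levels and the upper
   truncation the suffix minimum of not-yet-updated higher levels; this is
   an exact Gibbs sweep at $O(n)$ cost per column.
2. **Single-edge move.** One pair $(i,j)$ is drawn uniformly from all
   $p(p-1)/2$ pairs and its edge is proposed toggled. The acceptance ratio
   marginalizes the two free parameters that the toggle affects ($k_{ij}$
   and the Schur complement of $k_{jj}$), which is available in closed form
   as a Gaussian–Gamma integral. The remaining obstacle — the ratio of
   G-Wishart normalizing constants of the two graphs — is removed by an
   exchange step: one exact auxiliary draw from the G-Wishart *prior* under
   the proposed graph enters the ratio in the reverse direction and the
   intractable constants cancel identically. No normalizing constants are
   ever evaluated or approximated, so the chain targets the stated posterior
   exactly.
3. **Precision refresh.** $K$ is redrawn from its conditional posterior
   $\mathrm{GW}(\delta + n,\, D + Z^{\top}Z)$ restricted to the current
   graph, using the direct sampler: an unconstrained Wishart draw followed
   by iterative block completion of the covariance until the inverse carries
   exact zeros on non-edges.

Edge-inclusion probabilities are the (weight-normalized) frequency of each
edge across stored samples; model-averaged partial correlations average
$\rho_{ij}$ over all stored draws with absent-edge draws contributing exact
zeros. That convention is what produces the spike at zero in the posterior
density of a partial correlation: the spike mass equals one minus the edge
probability.

### Why we trust the implementation

Every graph on at most three nodes is decomposable, so the G-Wishart
normalizing constant factorizes over cliques and separators in closed form
and the graph posterior can be enumerated exactly
(`enumerate_posterior()`). The test suite drives the trans-dimensional
sampler against this oracle on fixtures with $n \in \{0, 20, 50, 200\}$ and
requires agreement within 0.03 per edge; with $n = 0$ the chain must
reproduce the 20% prior within 0.01. The closed-form pieces are themselves
cross-checked: the partial-correlation formula against brute-force
Schur-complement conditioning, the truncated-normal update moments against
covariance-form conditionals (both at $10^{-10}$), and the $p = 2$
enumeration against direct numerical integration of the unnormalized
density.

## Defaults that matter

| Parameter | Default | Meaning |
|---|---|---|
| `edge_prob` | 0.2 | prior probability of conditional dependence per pair |
| `df`, `scale` | 3, $I$ | G-Wishart hyperparameters |
| `iterations`, `burnin` | 120000, 20000 | chain schedule for production runs |
| `thin` | 10 | stored-sample spacing (storage only; probabilities use the stored samples) |
| edge cutoff | 0.5 | median-probability network rule for reported edges |
| Pearson `alpha` | 0.05 | zeroing rule for the naive correlation baseline |
| `strong_cut` | 0.25 | "strong association" tally threshold |

A production-scale run ($p = 19$, $n \approx 1000$, 120k iterations)
completes in roughly ten minutes on one core; the package's tests and the
acceptance script use 40k/10k (single fits) and 20k/5k (stratified refits),
which the enumeration-oracle and recovery checks show to be ample at these
problem sizes.

## The synthetic cohort generator

No public individual-level data accompany the study design this package
targets, so the generator is a first-class module: it draws a latent matrix
from $N(\mu_g, s_g^2 K^{-1})$ per diagnosis group (CN/EMCI/LMCI/AD, default
sizes 345/297/205/175) with a known sparse $K$, then pushes each column
through a monotone margin map:

* sex: indicator above a cut placed so the expected female fraction is 47%
  (group mean shifts reproduce the 53/44/43/42% pattern);
* APOE4: indicator with 45% carrier fraction;
* amyloid stage: five bins at latent quantiles (35/55/75/90%);
* education: `round(16.2 + 2.7 z)` clipped to [0, 25] years;
* age: affine, 73.5 + 7.5 z years;
* cognitive composites: affine maps hard-clipped to $[-3, 3]$ (the design
  states the range, not the mechanism; a hard clip is the simplest monotone
  choice);
* volume / glucose: strictly increasing exponential maps
  $v_0 e^{\lambda z}$ (skews 0.35 / 0.25), so the semiparametric transform
  is genuinely exercised. `gaussian_margins = TRUE` switches these to
  affine for oracle tests.

The default group mean shifts are solved from the published-style baseline
table (cognition ordered CN > EMCI > LMCI > AD, amyloid and atrophy
increasing with stage); the design gives no latent-scale effect sizes, so
these defaults are qualitative emulation, config-exposed and not claimed as
estimates. Per-group variance scales default to 1/0.9/0.85/0.8 — later
stages have compressed within-group variance, which is what drives the
stage-stratified refits to be sparser than the pooled fit (smaller per-group
$n$ plus restricted range pull posteriors toward the 20% prior, below the
0.5 reporting cutoff).

What passing tests on synthetic cohorts do *not* show: real cohorts have
missing data (the package deliberately refuses them rather than impute),
margins that are not exactly monotone transforms of one latent Gaussian,
measurement error correlated across variables, and selection effects. The
generator validates the machinery, not the substantive conclusions one
would draw from any particular cohort.

Parameter-recovery checks run the generator with mean shifts 0 and variance
scales 1: only then is the pooled latent law exactly $N(0, K^{-1})$, which
is the property being measured. With the demographic defaults switched on,
the pooled data are a mixture across shifted groups and the recovered
network reflects that mixture — that configuration is used for the
stratification checks instead.

## Numerical choices and degenerate inputs

* SPD checks use Cholesky; the completion step may add a diagonal jitter of
  $10^{-10}$ (escalating, bounded) only inside the sampler when a solve
  fails.
* Completion iterations stop when the largest elementwise change falls
  below $10^{-8}$ times the matrix scale (at most 100 sweeps inside the
  chain).
* Truncated-normal draws use inverse-CDF sampling with uniform/exponential
  fallbacks when both bounds land in the same extreme tail.
* Constant columns: the semiparametric transform refuses them (the map is
  undefined); the Pearson baseline reports such pairs as zero with a
  warning.
* Empty diagnosis groups are reported with size 0 and `NA` statistics;
  groups under `min_n` (default 30) are skipped in stratified refits with a
  warning.
* Ties in discrete columns share a starting latent value and are mutually
  unconstrained during resampling.
* Candidate edges are drawn uniformly; the move is symmetric, so no
  proposal correction is needed.

## Design decisions that were genuinely open

* **Sampler family.** Birth-death samplers with waiting-time weights are a
  widely used alternative backend for this posterior. We mandate only the
  target distribution and single-edge moves, and chose the
  double-reversible-jump/exchange construction because it is exactly
  correct without normalizing-constant ratios; correctness is gated on the
  enumeration oracle rather than on agreement with any particular package.
  The trace stores per-sample weights so a continuous-time backend could
  plug in behind the same contract.
* **Edge-probability estimator.** Frequency over stored samples (weights
  all one for the discrete-time chain). The alternative — waiting-time
  weighting — only matters for continuous-time backends.
* **Pearson baseline on raw codings.** The naive baseline a practitioner
  would compute; computing it on transformed data would blur the contrast
  the comparison is meant to show.
* **Diagnosis is metadata.** Stage labels never enter the model as a node;
  stage-specific structure is examined by stratified refits instead.
* **Complete cases only.** Silent imputation would change the estimand; a
  missing cell is a validation error that names its row and column.
* **Education latents.** Education is recorded in whole years and the
  generator rounds to integers; the copula layer treats it as a discrete
  (many-level) column, which is robust either way.
* **Latent identifiability.** The latent scale of discrete columns is not
  re-standardized inside the chain; all reported quantities (edge
  probabilities, partial correlations) are scale-free, so the free diagonal
  is harmless.
* **Stratified comparison metrics.** Whether "average absolute partial
  correlation" should include zeroed pairs is ambiguous in this kind of
  report, so `stratified_run()` emits both (`avg_abs_partial` over all
  pairs with sub-cutoff pairs as zero, and `avg_abs_partial_retained`).

## Worked example

```{r example, eval = FALSE}
model <- make_true_model(19, "ad_motif", seed = 1)
cfg <- generator_config(true_model = model, seed = 1)
sim <- generate_cohort(cfg)
summarize_cohort(sim$cohort)

trace <- gcgm_fit(sim$cohort, iterations = 40000, burnin = 10000, seed = 1)
post <- summarize_partials(trace)
net <- threshold_network(post, 0.5)
head(net[order(-net$prob), ])

interval_probability(post, "vol_hippocampus", "adni_mem", 0.1, 0.3)
render_density(post, "vol_hippocampus", "adni_mem")
```

## Known limitations

* Cost grows quickly with $p$ (two G-Wishart draws per iteration) and
  linearly with $n$ through the per-iteration discrete resampling; beyond
  roughly a hundred variables or several thousand rows this sampler is the
  wrong tool.
* Partial correlations measure *linear* latent association; monotone but
  saturating relationships are captured only through their rank structure,
  and non-monotone ones not at all.
* The graph is undirected: nothing here is causal, though a
  well-supported conditional-dependence skeleton is a sensible starting
  point for causal analysis.
* Binary variables carry little rank information, so their edges mix more
  slowly and shrink harder toward the prior than continuous ones at equal
  sample size.
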