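---
title: "Models and methods behind flywaytrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flywaytrends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flywaytrends estimates population trends of migratory shorebird taxa from
replicated non-breeding-season counts, and then asks what explains the
variation in those trends across taxa. The package implements both stages as
a single tested pipeline: a hierarchical N-mixture model for
detection-corrected abundance trends, and a Bayesian phylogenetic regression
with indicator-based variable selection for the cross-taxon comparison.
Because the monitoring data that motivate this design are held under
restricted agreements, the package ships a synthetic-data generator that
reproduces their statistical structure with known ground truth, so every
stage is verifiable end to end.

## Stage 1: the N-mixture count model

Counts are collected at sites $i = 1,\dots,R$ grouped into non-breeding
nodes $k$, over years $t = 1,\dots,K$, with $j$ replicate monthly counts
within each season. The hierarchical model is

$$c_{ijt} \sim \mathrm{Binomial}(N_{it}, P_{ijt}), \qquad
  N_{it} \sim \mathrm{Poisson}(\lambda_{it}),$$

with a log-linear abundance model per node,

$$\log \lambda_{it} = \omega_i + \alpha_k + \beta_k (t - t^*) + \epsilon_{it},$$

or, in the flyway variant, a single $\alpha$ and $\beta$ across all sites.
Here $\omega_i$ is a site random effect, $\epsilon_{it}$ a site-year effect
absorbing extra-Poisson dispersion, and the year covariate is centred on the
mean year $t^*$ so intercepts are mid-series log abundances. Detection is

$$\mathrm{logit}\, P_{ijt} = \gamma_t + \delta_{ijt},$$

with a yearly mean $\gamma_t$ and a per-count effect $\delta_{ijt}$.
Replicates within a season are treated as exchangeable: nothing in the data
model distinguishes a January count from a February one beyond its own
$\delta_{ijt}$. The logit link is used throughout; it is the standard link
for N-mixture detection models and the only choice under which $\gamma_t$
is interpretable as the mean detection probability of year $t$.

Four assumptions come with this model family and are worth restating
because the package cannot check them from data alone: within-season
closure of each site's population; equal detectability of individuals
within a taxon; adequacy of the Poisson/binomial forms (checked by the
posterior predictive machinery below); and negligible double counting.

### Priors

Fixed effects ($\alpha_k$, $\beta_k$, $\gamma_t$) receive vague
$N(0, 10^3)$ priors. Random-effect variances ($\sigma^2_\omega$,
$\sigma^2_\epsilon$) receive inverse-gamma$(10^{-3}, 10^{-3})$ priors,
i.e. precisions are gamma$(10^{-3}, 10^{-3})$. Two points deserve
explanation:

* A literal reading of "precision distributed inverse-gamma" is
  nonstandard; the conventional hierarchical idiom -- and the one every
  mainstream Gibbs implementation of this model uses -- places the
  inverse-gamma on the *variance*. The package adopts the conventional
  parameterization. At these hyperparameter values the prior is so diffuse
  that the distinction is numerically negligible.
* Describing the per-count detection effect as "uniform with range 0-100"
  cannot hold for a mean-zero logit-scale effect. The package reads it as
  the standard hierarchical shorthand it most plausibly abbreviates:
  $\delta_{ijt} \sim N(0, \sigma_\delta^2)$ with $\sigma_\delta \sim
  U(0, 100)$. The literal variant ($\delta_{ijt} \sim U(0, 100)$ on the
  effect itself) remains available behind
  `nmix_spec(delta_literal_uniform = TRUE)` for sensitivity analysis, and
  every run log records which interpretation was in force.
* Fixed effects are *not* given the shared estimated precision that a
  literal reading of the prior sentence would imply for $\alpha_k$ and
  $\beta_k$: with only one to four parameters per class, a
  gamma$(10^{-3},10^{-3})$ precision hyperprior is close to improper and
  couples unrelated parameters. The $N(0, 10^3)$ choice matches the prior
  stated for $\gamma_t$ and is the field's default vague prior.

### The marginalized sampler

The default backend (`nmix_spec(backend = "marginal")`) never samples the
latent abundances during estimation. For one site-year with counts
$c_1,\dots,c_J$, the exact likelihood is the truncated sum

$$f(c \mid \lambda, p) = \sum_{N = \max_j c_j}^{n_{\max}}
  \mathrm{Pois}(N \mid \lambda) \prod_j \mathrm{Bin}(c_j \mid N, p_j),$$

computed by an upward recurrence in double precision (each term follows
from its predecessor with a handful of multiplications, so the sum costs
essentially one pmf evaluation plus the summation window). The exported
[`sityear_marginal_loglik()`] implements the same kernel in plain R with an
explicit truncation rule -- starting at the 0.9999 Poisson quantile and
doubling until the result moves by less than $10^{-8}$ -- and the test
suite pins both implementations to brute-force enumeration at $10^{-10}$
tolerance.

With $N$ marginalized, the remaining posterior is a Gaussian hierarchy
(sites, site-years, detection logits, their variances) behind a
non-Gaussian likelihood. The sampler is Metropolis-within-Gibbs with:

* conjugate draws for $\omega_i$, $\alpha_k$, $\beta_k$, $\gamma_t$ and
  all variances (site effects are hierarchically centred on $\alpha_k$,
  which removes the classic intercept/random-effect random walk);
* adaptive random-walk updates for each site-year log-abundance and each
  detection logit, with Robbins-Monro scale tuning toward 44% acceptance
  during warm-up only (freezing the scales afterwards preserves the
  correct stationary distribution);
* joint "ridge" moves that shift abundance and rescale detection in
  opposite directions -- per site-year, per year, and globally in the
  level and trend directions. These address the well-known N-mixture
  ridge: the data constrain the product $\lambda P$ much more tightly than
  its factors, and samplers that move one coordinate at a time crawl
  along that ridge. The global moves carry $\gamma_t$ along with the mean
  detection-logit shift of its year, a triangular deterministic map whose
  Jacobian is accounted for in the acceptance ratio.

Latent abundances are drawn exactly from their discrete conditional only
when a posterior draw is retained, for use by the abundance and
goodness-of-fit summaries.

The alternative backend (`backend = "jags"`) fits the identical model by
data augmentation in JAGS, sampling $N_{it}$ directly; it is used in the
test suite as an independent cross-check of the marginalized sampler and
runs about an order of magnitude slower per effective draw on the trend
parameter, which is why it is not the default.

### Convergence, checking, and derived quantities

Every monitored parameter gets a Gelman-Rubin $\hat{R}$ across chains
(at least two chains are required). A fit with any $\hat{R}$ above the
gate (1.1 by default) is flagged at fit time and `tidy()` refuses to
summarise it unless explicitly overridden -- a non-converged run should
never silently become a result.

Model adequacy is assessed with a chi-square posterior predictive check:
for each retained draw, the discrepancy
$\sum (c - NP)^2 / (NP + \tfrac12)$ is computed for the observed counts
and for replicate counts simulated from the same draw, and the Bayesian
p-value is the proportion of draws where the observed discrepancy is
larger. Values near 0.50 indicate adequate fit. The small constant in the
denominator guards against zero expected counts; its value does not
matter at the abundances involved.

Two derived summaries mirror the headline quantities of a flyway
analysis: `derive_total_abundance()` sums latent abundance over sites per
year (the detection-corrected population index), and
`node_trend_odds_ratios()` converts node trend contrasts into per-draw
odds ratios $e^{\beta_a}/e^{\beta_b}$ with a mean absolute deviation from
1 in percent, the scale on which "trends differ by mean odds of x%" is
read.

MCMC run lengths: the package defaults
(`mcmc_settings(chains = 2, burn = 1000, draws = 1500, thin = 2)`) are
desk-scale settings adequate for the adaptive marginalized sampler under
the convergence gate. `mcmc_preset("paper", "counts")` exposes the
Gibbs-era run lengths (3 chains of 800,000, burn-in 200,000, thin 18)
for like-for-like reruns; they are unnecessary with this sampler.

## Stage 2: phylogenetic variable selection

The comparative stage explains taxon-level trend estimates $Td_z$
($z = 1,\dots,M$) with five candidate covariates: Yellow Sea reliance
(the proportion of the flyway population staging on Yellow Sea tidal
mudflats), migration distance, breeding range size, generation time and
body size. Residuals carry Brownian-motion phylogenetic covariance: for a
tree, the trait variance of a tip is its root-to-tip length, the
covariance of two tips the depth of their most recent common ancestor
(`vcv_from_tree()`). Each matrix is scaled to unit height -- making it a
correlation-like structure so $\sigma^2$ is a residual variance -- and
inverted (`scale_and_invert()`, `build_vcv_array()`).

Phylogenetic uncertainty enters through a set of $R$ equally plausible
ultrametric trees: the likelihood is
$Td \sim \mathrm{MVN}(\mu, \sigma^2 C_q)$ with tree index $q$ uniform
over the set a priori and resampled from its categorical conditional
every iteration. This is the standard multi-tree idiom; integrating over
the tree set rather than conditioning on a consensus tree propagates
topology and branch-length uncertainty into the coefficient CRIs.

The mean model is

$$\mu_z = \alpha + \sum_c v_c\, \theta_c\, X_{zc} + \epsilon_z, \qquad
  v_c \sim \mathrm{Bernoulli}(0.5),$$

so each covariate's coefficient is gated by a binary indicator; the
indicator's posterior mean measures covariate importance. Classification
follows fixed thresholds: at or above 0.75 important, at or below 0.25
unimportant, in between inconclusive. `two_stage_selection()` then pins
the unimportant indicators to zero and refits, which sharpens the
estimates of the retained predictors.

Design choices worth recording:

* **Standardization.** Covariates and response are z-scored before
  fitting (`bvs_config(standardize = TRUE)`). Selection under a common
  Bernoulli(0.5) prior is only meaningful when coefficients are on a
  common scale, and the reported slope is then a correlation-like
  quantity; raw-scale fitting remains available.
* **The error term $\epsilon$.** The mean model's i.i.d. taxon-level
  error is given its own vague-prior variance
  (inverse-gamma$(10^{-3},10^{-3})$), estimated alongside the
  phylogenetic $\sigma^2$; `bvs_config(include_resid_effect = FALSE)`
  drops it. With of order ten taxa the two variances split the residual
  noise and are individually weakly identified, but simulation shows
  selection and coefficient recovery remain decisive with the term
  included (the package's selection-recovery test runs under the default,
  with the term on).
* **The sampler.** Given $(v, q)$ and the variances, the model is
  linear-Gaussian, so the package uses a collapsed Gibbs sampler written
  for this structure: indicator updates integrate the coefficients out
  analytically and flip $v_c$ by exact Bayes factors; coefficients, the
  error term, the variances and the tree index are drawn from their
  conjugate or categorical conditionals. Naive one-at-a-time indicator
  samplers are notoriously sticky under vague coefficient priors (a
  deactivated coefficient wanders its prior and is essentially never
  re-accepted); the collapsed scheme removes that pathology and is exact
  for the stated model. The closed-form GLS reduction (one tree,
  indicators pinned on) is the test suite's independent check of this
  sampler.
* **Measurement error.** Stage-1 CRIs on the trend estimates are *not*
  propagated into stage 2: the regression treats the posterior-mean
  trends as data, exactly as the two-stage design specifies. This
  understates total uncertainty by the stage-1 measurement error; a
  known-variance extension would add $\mathrm{diag}(SE^2)$ to
  $\sigma^2 C_q$ and is a natural future flag, but it is deliberately not
  the default because the reported quantities are defined without it.
* **Subspecies.** Tree sets without within-species resolution cannot
  separate two subspecies of the same species. The packaged comparative
  summaries therefore exclude the *baueri* bar-tailed godwit and keep
  *menzbieri* (the steeper-declining subspecies); `exclude_taxa`
  makes the alternative run a one-argument change.

## The trend-table summaries

`shorebird_trends()` loads the packaged taxon-level trend table (ten
flyway taxa with Yellow Sea reliance, posterior-mean log-scale trend and
95% CRI). On top of it:

* `classify_trend()` calls a trend credible only when its 95% CRI
  excludes zero; an interval endpoint exactly at zero is *not* credible
  (this resolves the red-necked stint boundary case, whose upper bound is
  0.000).
* `percent_per_year()` converts log-scale slopes with the linear
  transform $100\beta$ by default. The exponential alternative
  $100(e^\beta - 1)$ is provided, but the linear transform is the one
  consistent with the packaged table's group means and per-taxon rates, and at
  $|\beta| < 0.1$ the difference is below half a percentage point.
* `group_mean_trend()` averages percent-per-year trends within reliance
  groups. The high-reliance group is defined as reliance at or above
  0.50 -- including the boundary taxon at exactly 0.50 -- because that is
  the membership under which the high-group mean is reproducible from
  the table; the prose description "more than 50%" is read as inclusive.
  Group means are computed on posterior means from the table (not on
  draws), with a tolerance of about 0.15 percentage points inherited
  from table rounding.

## The synthetic-data generator

`simulate_counts()` draws complete count datasets from the stage-1 model
itself, with every latent recorded as ground truth. The default
configuration describes the monitored system the pipeline targets:

* 4 non-breeding nodes of 4 sites each (16 sites), 20 seasons
  (1993-2012), 1-5 monthly replicate counts per site-year drawn from the
  austral-summer months;
* node intercepts $\log 150$ with site-effect sd 0.6, so site-level mean
  abundances span roughly 45 to 500 birds and the best sites exceed the
  500-bird maxima that make a monitoring site worth retaining;
* overdispersion sd 0.15 (mild extra-Poisson noise in site-year
  abundance);
* detection 0.6 on the logit scale with per-count effect sd 0.3, which
  puts per-count detection probabilities in roughly the 0.52-0.68 band
  reported for this monitoring scheme;
* node trends all $-0.04$ per year: a 4%-per-year decline, the magnitude
  at the centre of the declines this kind of analysis needs to detect.

Missing replicates are removed completely at random (each site-year keeps
at least one count), matching how the likelihood drops them from the
product over replicates.

What the generator does *not* emulate -- and what passing tests therefore
cannot certify about field data: observer- and tide-driven detection
structure (detection effects are exchangeable within a season), movement
among sites within a season (closure is built in, not violated),
double-counting, and any covariate structure on detection. A
closure-violation scenario generator would be the natural stretch
extension.

`simulate_tree_set()` draws random coalescent trees rescaled to unit
height -- ultrametric by construction -- and `simulate_trend_data()` draws
trend vectors from the stage-2 model given one tree sampled from the set,
with standardized covariates and true indicator states recorded.

## Numerical choices and problem sizes

* Truncated latent sums stop when terms fall below $10^{-14}$ of the
  running maximum past the mode, with a hard cap of $10^5$ terms as a
  pathology guard; the exported R kernel uses the doubling rule described
  above.
* Proposal scales adapt only during warm-up (Robbins-Monro, targets 0.44
  univariate / 0.30 for joint moves).
* Chain seeds derive deterministically from the user seed (`seed + chain
  - 1`), so every fit is bit-reproducible at fixed settings.
* Cholesky factorization backs every matrix inversion in stage 2; a
  non-positive-definite scaled VCV is an error, and near-singular
  matrices (reciprocal condition number below $10^{-10}$, e.g. tips that
  effectively coincide) trigger a warning.
* The test suite runs everything at desk scale, chosen so the full suite
  exercises real MCMC while staying fast: the trend-recovery study uses
  50 replicate fits of the default 16-site, 20-year design at 2 chains
  each; the PPC calibration study uses 30 replicate fits of a reduced
  6-site, 8-year design; selection recovery uses 25 replicates at 10
  taxa over 100 trees. These sizes are the package's choices for a
  thorough-but-fast default run; heavier replication only narrows the
  Monte Carlo error of the checks themselves.

## Known limitations

* The N-mixture likelihood is intrinsically ridge-shaped in
  (abundance, detection); with single-replicate seasons or very large
  counts, detection-level quantities ($\gamma_t$, $\sigma_\delta$) carry
  wide posteriors and mix more slowly than the trend parameters. Trend
  inference is robust to this; absolute abundance is the quantity to
  treat cautiously.
* Stage 2 conditions on stage-1 posterior means (see above); CRIs on the
  comparative slope are conditional on the trend table.
* Brownian motion is the only residual model (no Ornstein-Uhlenbeck or
  lambda transforms), matching the design this package implements.
* The pipeline estimates trends; it does not model the mechanisms behind
  them (habitat loss, survival), and a strong reliance-trend association
  remains correlational evidence.
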