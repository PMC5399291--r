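# flywaytrends

Bayesian estimation of migratory shorebird population trends from
replicated count data, and phylogenetic comparative analysis of what
drives those trends.

Millions of shorebirds migrate along the East Asian–Australasian Flyway
(EAAF) between Arctic breeding grounds and non-breeding sites in Australia
and New Zealand, refuelling on tidal mudflats — above all in the Yellow
Sea, an ecosystem shrinking under coastal development. Long-running
citizen-science count programmes record these birds every austral summer,
but raw counts confound true abundance with imperfect detection, and
cross-taxon comparisons must account for shared evolutionary history.
`flywaytrends` is for quantitative ecologists who need to turn such
replicated, detection-biased monitoring counts into defensible trend
estimates and then test which species traits explain trend variation.

## The models

**Stage 1 — hierarchical N-mixture model.** Replicate counts
`c_ijt` at site *i*, month *j*, year *t* are binomial thinnings of a
latent Poisson abundance:

    c_ijt ~ Binomial(N_it, P_ijt)        N_it ~ Poisson(lambda_it)
    log lambda_it = omega_i + alpha_k + beta_k (t - t*) + eps_it
    logit P_ijt   = gamma_t + delta_ijt

with site effects `omega_i`, node-level intercepts and log-linear trends
`alpha_k`, `beta_k` (or a single flyway-wide `alpha`, `beta`), site-year
overdispersion `eps_it`, yearly mean detection `gamma_t` and per-count
detection effects `delta_ijt`. The default sampler marginalizes `N_it`
out of the likelihood exactly and runs an adaptive
Metropolis-within-Gibbs scheme written for this model (conjugate updates
for the Gaussian hierarchy plus joint moves along the
abundance–detection ridge); a JAGS data-augmentation backend provides an
independent cross-check. Model adequacy is assessed with a chi-square
posterior predictive check, and convergence with Gelman–Rubin
diagnostics on every monitored parameter.

**Stage 2 — phylogenetic variable selection.** Taxon-level trends `Td_z`
are regressed on Yellow Sea reliance, migration distance, breeding range
size, generation time and body size, with Brownian-motion phylogenetic
residual covariance integrated over a set of ultrametric trees:

    Td ~ MVN(mu, sigma^2 C_q),   mu_z = alpha + sum_c v_c theta_c X_zc + eps_z
    v_c ~ Bernoulli(0.5)

Each tree's variance–covariance matrix is scaled to unit height and the
tree index `q` is resampled every MCMC iteration. Indicator posterior
means ≥ 0.75 mark important predictors, ≤ 0.25 unimportant ones; a
two-stage refit pins unimportant indicators to zero and sharpens the
retained slopes. The sampler is a collapsed Gibbs scheme (coefficients
integrated out of the indicator updates), exact for this
linear-Gaussian model.

Because the underlying monitoring data are held by member organizations
under restricted agreements, the package includes a synthetic-data
generator (`simulate_counts()`, `simulate_tree_set()`,
`simulate_trend_data()`) reproducing the statistical structure of both
stages with known ground truth, plus the published taxon-level trend
table as an in-package fixture (`shorebird_trends()`).

## Worked example

```r
library(flywaytrends)

# the packaged flyway trend table: ten EAAF taxa
tab <- shorebird_trends()
count_credible_declines(tab)
#> [1] 7
group_mean_trend(tab, 0.50, "high")   # taxa with >= 50% Yellow Sea reliance
#> [1] -5.185714
group_mean_trend(tab, 0.40, "low")    # taxa with <= 40% reliance
#> [1] -0.9333333
reliance_trend_slope(tab, exclude_taxa = "Bar-tailed godwit (baueri)")
#> # A tibble: 1 x 5
#>    slope    lo     hi     n method
#>    <dbl> <dbl>  <dbl> <int> <chr>
#> 1 -0.924 -1.27 -0.581     9 ols
```

Seven of the ten taxa decline credibly (95% CRI below zero). Taxa
relying on the Yellow Sea for at least half their staging decline at
−5.2% per year on average, against −0.9% for low-reliance taxa, and the
standardized reliance–trend slope across the nine comparable taxa is
−0.92: the more a taxon depends on Yellow Sea mudflats, the faster it is
declining.

Fitting the count model to synthetic data with known truth:

```r
sim <- simulate_counts(count_sim_config(seed = 1))   # 16 sites, 20 years, trend -0.04
fit <- fit_flyway_model(sim$counts, nmix_spec(mcmc = mcmc_settings(seed = 2)))
fit
#> <nmix_fit> flyway model (marginal backend) | 16 sites, 20 years | 2 chains x 1500 draws
#>   converged: yes (max Rhat 1.007, gate 1.10)
#>   beta: -0.0399 (95% CRI -0.0469, -0.0335)
posterior_predictive_check(fit)
#> <nmix_ppc> Bayesian p-value: 0.475 (3000 draws)
#>   near 0.50 indicates adequate fit
```

The trend posterior covers the generating value (−0.04) and the
predictive check sits near 0.5, as it should when the fitted model is
the generating model. `derive_total_abundance(fit)` returns the
detection-corrected annual abundance index
(`autoplot()` draws it), and `fit_node_model()` +
`node_trend_odds_ratios()` compare trends among non-breeding nodes.

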