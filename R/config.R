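#' MCMC settings for the samplers
#'
#' Bundles chain count, warm-up, retained draws and thinning. The
#' `"desk"` preset is the package default: modern adaptive samplers reach
#' convergence in a few thousand iterations, checked by a Gelman-Rubin
#' \eqn{\hat{R} < 1.1} gate. The `"paper"` preset mirrors the run lengths
#' used in the original Gibbs-era analyses (counts: 3 chains of 800,000 with
#' 200,000 burn-in, thin 18; regression: 3 chains of 120,000 with 20,000
#' burn-in, thin 3) and is only needed for like-for-like reruns.
#'
#' @param chains number of independent chains (>= 2 so \eqn{\hat{R}} exists)
#' @param burn warm-up iterations discarded per chain (adaptation happens here)
#' @param draws retained draws per chain (after thinning)
#' @param thin thinning interval
#' @param seed integer seed; chain `k` uses `seed + k - 1`
#' @return a list of class `mcmc_settings`
#' @export
mcmc_settings <- function(chains = 2L, burn = 1000L, draws = 1500L, thin = 2L,
                          seed = 1L) {
  check_scalar_number(chains, "chains", lower = 2)
  check_scalar_number(burn, "burn", lower = 0)
  check_scalar_number(draws, "draws", lower = 10)
  check_scalar_number(thin, "thin", lower = 1)
  check_scalar_number(seed, "seed")
  structure(list(chains = as.integer(chains), burn = as.integer(burn),
                 draws = as.integer(draws), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @param stage `"counts"` or `"regression"`
#' @param name `"desk"` (default) or `"paper"`
#' @rdname mcmc_settings
#' @export
mcmc_preset <- function(name = c("desk", "paper"), stage = c("counts", "regression"),
                        seed = 1L) {
  name <- match.arg(name)
  stage <- match.arg(stage)
  if (name == "desk") {
    if (stage == "counts") mcmc_settings(2L, 1000L, 1500L, 2L, seed)
    else mcmc_settings(2L, 2000L, 5000L, 1L, seed)
  } else {
    if (stage == "counts") mcmc_settings(3L, 200000L, 33333L, 18L, seed)
    else mcmc_settings(3L, 20000L, 33333L, 3L, seed)
  }
}

#' Configuration for the replicated-count simulator
#'
#' Defines the generative conditions for synthetic non-breeding-season count
#' data: sites grouped into nodes, a log-linear abundance trend per node with
#' site and site-year (overdispersion) random effects, and imperfect
#' binomial detection with a yearly mean and per-count random effect on the
#' logit scale. Defaults describe a typical monitored flyway population:
#' 4 nodes of 4 sites counted over 20 austral summers with 1-5 monthly
#' replicate counts, site-level abundances of order a few hundred birds, and
#' detection probabilities around 0.6 (per-count spread roughly 0.52-0.68).
#'
#' @param n_sites_per_node sites in each non-breeding node
#' @param n_nodes number of nodes
#' @param n_years number of seasons (years); >= 2
#' @param start_year calendar year of the first season
#' @param replicates_range integer range (min, max) of monthly replicate
#'   counts per site-year; months are drawn from the austral-summer set
#' @param missingness fraction of replicate slots dropped completely at
#'   random (each site-year always keeps at least one count)
#' @param site_effect_sd sd of the site random effect \eqn{\omega_i} (log scale)
#' @param node_intercepts length-`n_nodes` log-scale abundance intercepts
#'   \eqn{\alpha_k} (at the mean year)
#' @param node_trends length-`n_nodes` per-year log-scale trends \eqn{\beta_k}
#' @param overdispersion_sd sd of the site-year effect \eqn{\epsilon_{it}}
#' @param detection_year_mean yearly mean detection on the logit scale
#'   \eqn{\gamma_t}: a scalar (recycled) or length-`n_years` vector
#' @param detection_re_sd sd of the per-count detection effect \eqn{\delta_{ijt}}
#' @param seed integer seed
#' @return a list of class `count_sim_config`
#' @export
count_sim_config <- function(n_sites_per_node = 4L,
                             n_nodes = 4L,
                             n_years = 20L,
                             start_year = 1993L,
                             replicates_range = c(1L, 5L),
                             missingness = 0,
                             site_effect_sd = 0.6,
                             node_intercepts = rep(log(150), n_nodes),
                             node_trends = rep(-0.04, n_nodes),
                             overdispersion_sd = 0.15,
                             detection_year_mean = qlogis(0.6),
                             detection_re_sd = 0.3,
                             seed = 1L) {
  check_scalar_number(n_sites_per_node, "n_sites_per_node", lower = 1)
  check_scalar_number(n_nodes, "n_nodes", lower = 1)
  check_scalar_number(n_years, "n_years", lower = 2)
  check_scalar_number(site_effect_sd, "site_effect_sd", lower = 0)
  check_scalar_number(overdispersion_sd, "overdispersion_sd", lower = 0)
  check_scalar_number(detection_re_sd, "detection_re_sd", lower = 0)
  check_scalar_number(missingness, "missingness", lower = 0, upper = 0.9)
  if (length(replicates_range) != 2L || replicates_range[1] < 1 ||
      replicates_range[2] < replicates_range[1] || replicates_range[2] > 5) {
    abort("`replicates_range` must be (min, max) with 1 <= min <= max <= 5")
  }
  if (length(node_intercepts) != n_nodes) {
    abort(sprintf("`node_intercepts` must have length n_nodes = %d", n_nodes))
  }
  if (length(node_trends) != n_nodes) {
    abort(sprintf("`node_trends` must have length n_nodes = %d", n_nodes))
  }
  if (!length(detection_year_mean) %in% c(1L, n_years)) {
    abort("`detection_year_mean` must be scalar or one value per year")
  }
  structure(list(
    n_sites_per_node = as.integer(n_sites_per_node),
    n_nodes = as.integer(n_nodes),
    n_years = as.integer(n_years),
    start_year = as.integer(start_year),
    replicates_range = as.integer(replicates_range),
    missingness = missingness,
    site_effect_sd = site_effect_sd,
    node_intercepts = node_intercepts,
    node_trends = node_trends,
    overdispersion_sd = overdispersion_sd,
    detection_year_mean = rep_len(detection_year_mean, n_years),
    detection_re_sd = detection_re_sd,
    seed = as.integer(seed)
  ), class = "count_sim_config")
}

#' Configuration for the comparative-data simulator
#'
#' Generative conditions for taxon-level trend estimates with
#' Brownian-motion phylogenetic residual covariance: `n_taxa` tips, a set of
#' `n_trees` random ultrametric trees, standardized covariates, and true
#' regression coefficients gated by binary indicators.
#'
#' @param n_taxa number of taxa (>= 3)
#' @param n_trees number of trees in the set (>= 1)
#' @param intercept true intercept
#' @param coefficients named numeric vector of true coefficients
#'   \eqn{\theta_c}; names become covariate columns
#' @param indicators 0/1 vector, same length: which covariates truly act
#'   (\eqn{v_c})
#' @param residual_variance Brownian residual variance \eqn{\sigma^2} (> 0)
#' @param seed integer seed
#' @return a list of class `comparative_sim_config`
#' @export
comparative_sim_config <- function(n_taxa = 10L,
                                   n_trees = 100L,
                                   intercept = 0,
                                   coefficients = c(reliance = -0.9, distance = 0,
                                                    range_size = 0, generation_time = 0,
                                                    body_size = 0),
                                   indicators = as.numeric(coefficients != 0),
                                   residual_variance = 0.25,
                                   seed = 1L) {
  check_scalar_number(n_taxa, "n_taxa", lower = 3)
  check_scalar_number(n_trees, "n_trees", lower = 1)
  check_scalar_number(residual_variance, "residual_variance")
  if (residual_variance <= 0) abort("`residual_variance` must be > 0")
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("`coefficients` must be a fully named numeric vector")
  }
  if (length(indicators) != length(coefficients) || !all(indicators %in% c(0, 1))) {
    abort("`indicators` must be a 0/1 vector matching `coefficients`")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), n_trees = as.integer(n_trees),
    intercept = intercept, coefficients = coefficients,
    indicators = indicators, residual_variance = residual_variance,
    seed = as.integer(seed)
  ), class = "comparative_sim_config")
}

#' Specification of an N-mixture model fit
#'
#' @param variant `"flyway"` (one intercept and trend across all sites) or
#'   `"node"` (intercept and trend per non-breeding node)
#' @param backend `"marginal"` (default; latent abundance summed out of the
#'   likelihood, sampled with an adaptive Metropolis-within-Gibbs scheme) or
#'   `"jags"` (data augmentation sampling N directly, requires rjags)
#' @param mcmc an [mcmc_settings()] object
#' @param prior_fixed_sd sd of the vague normal prior on intercepts, trends
#'   and yearly detection means (default sqrt(1000))
#' @param re_prior_shape,re_prior_rate shape/rate of the gamma prior on
#'   random-effect precisions (variance ~ inverse-gamma), default 1e-3
#' @param detection_sd_max upper bound of the uniform prior on the
#'   per-count detection effect sd
#' @param delta_literal_uniform if `TRUE`, use the literal
#'   \eqn{\delta_{ijt} \sim U(0, 100)} variant instead of the hierarchical
#'   normal effect (sensitivity analysis only)
#' @param fix_detection optional known detection probability in (0, 1]; when
#'   given, detection is not estimated (used for degenerate-limit checks)
#' @param n_max_cap hard cap on the truncated latent-abundance summation
#' @param rhat_max convergence gate: summaries refuse to report when any
#'   monitored \eqn{\hat{R}} exceeds this (override in [tidy.nmix_fit()])
#' @return a list of class `nmix_spec`
#' @export
nmix_spec <- function(variant = c("flyway", "node"),
                      backend = c("marginal", "jags"),
                      mcmc = mcmc_settings(),
                      prior_fixed_sd = sqrt(1000),
                      re_prior_shape = 1e-3,
                      re_prior_rate = 1e-3,
                      detection_sd_max = 100,
                      delta_literal_uniform = FALSE,
                      fix_detection = NULL,
                      n_max_cap = 100000L,
                      rhat_max = 1.1) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  stopifnot(inherits(mcmc, "mcmc_settings"))
  check_scalar_number(prior_fixed_sd, "prior_fixed_sd", lower = 0)
  check_scalar_number(detection_sd_max, "detection_sd_max", lower = 0)
  if (!is.null(fix_detection)) {
    check_scalar_number(fix_detection, "fix_detection", lower = 1e-12, upper = 1)
  }
  structure(list(variant = variant, backend = backend, mcmc = mcmc,
                 prior_fixed_sd = prior_fixed_sd,
                 re_prior_shape = re_prior_shape, re_prior_rate = re_prior_rate,
                 detection_sd_max = detection_sd_max,
                 delta_literal_uniform = isTRUE(delta_literal_uniform),
                 fix_detection = fix_detection,
                 n_max_cap = as.integer(n_max_cap),
                 rhat_max = rhat_max),
            class = "nmix_spec")
}

#' Configuration for the Bayesian variable-selection regression
#'
#' @param mcmc an [mcmc_settings()] object (regression-scale defaults)
#' @param standardize z-score covariates and response before fitting
#'   (default `TRUE`; reported coefficients are on the standardized scale)
#' @param include_resid_effect include the i.i.d. taxon-level error term with
#'   its own vague-prior variance alongside the phylogenetic residual
#' @param prior_coef_sd sd of the normal prior on intercept and coefficients
#' @param indicator_prior Bernoulli prior probability for each indicator
#' @param fixed_indicators optional named 0/1 vector pinning indicators
#'   (used by the two-stage refit and for GLS reductions)
#' @param important,unimportant indicator posterior-mean thresholds for the
#'   `"important"` / `"unimportant"` classifications
#' @param cri_level credible-interval level
#' @return a list of class `bvs_config`
#' @export
bvs_config <- function(mcmc = mcmc_preset("desk", "regression"),
                       standardize = TRUE,
                       include_resid_effect = TRUE,
                       prior_coef_sd = sqrt(1000),
                       indicator_prior = 0.5,
                       fixed_indicators = NULL,
                       important = 0.75,
                       unimportant = 0.25,
                       cri_level = 0.95) {
  stopifnot(inherits(mcmc, "mcmc_settings"))
  check_scalar_number(indicator_prior, "indicator_prior", lower = 0, upper = 1)
  check_scalar_number(important, "important", lower = 0, upper = 1)
  check_scalar_number(unimportant, "unimportant", lower = 0, upper = 1)
  check_scalar_number(cri_level, "cri_level", lower = 0, upper = 1)
  if (unimportant > important) abort("`unimportant` threshold must be <= `important`")
  structure(list(mcmc = mcmc, standardize = isTRUE(standardize),
                 include_resid_effect = isTRUE(include_resid_effect),
                 prior_coef_sd = prior_coef_sd, indicator_prior = indicator_prior,
                 fixed_indicators = fixed_indicators,
                 important = important, unimportant = unimportant,
                 cri_level = cri_level),
            class = "bvs_config")
}
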