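test_that("indicator classification follows the thresholds with closed boundaries", {
  expect_identical(classify_indicator(0.75), "important")
  expect_identical(classify_indicator(0.25), "unimportant")
  expect_identical(classify_indicator(0.50), "inconclusive")
  expect_identical(classify_indicator(c(0.9, 0.1, 0.3)),
                   c("important", "unimportant", "inconclusive"))
  expect_error(classify_indicator(1.2), "\\[0, 1\\]")
  expect_error(classify_indicator(-0.1), "\\[0, 1\\]")
})

test_that("with one tree and indicators pinned on, the fit reduces to GLS", {
  set.seed(51)
  M <- 12
  tr <- ape::rcoal(M)
  tr$edge.length <- tr$edge.length / max(diag(vcv_from_tree(tr)))
  om <- build_vcv_array(tr)
  Cmat <- om$scaled[, , 1]
  X <- matrix(rnorm(M * 2), M, dimnames = list(om$taxa, c("x1", "x2")))
  y <- drop(0.3 - 0.8 * X[, 1] + 0.4 * X[, 2] + rmvn(1, rep(0, M), 0.2 * Cmat))
  dat <- tibble::tibble(taxon = om$taxa, trend = y, x1 = X[, 1], x2 = X[, 2])
  cfg <- bvs_config(mcmc = mcmc_settings(chains = 2, burn = 1000, draws = 4000, seed = 52),
                    standardize = FALSE, include_resid_effect = FALSE,
                    fixed_indicators = c(x1 = 1, x2 = 1))
  fit <- fit_bvs_regression(dat, om, cfg)
  # closed-form GLS with the known correlation structure
  W <- cbind(1, X)
  Ci <- om$omega[, , 1]
  gls <- solve(crossprod(W, Ci %*% W), crossprod(W, Ci %*% y))
  td <- tidy(fit)
  draws <- fit$summary_draws
  for (i in 1:3) {
    tm <- c("alpha", "beta[x1]", "beta[x2]")[i]
    mcse <- sd(draws[, tm]) / sqrt(400)
    expect_lt(abs(td$mean[td$term == tm] - gls[i]), max(3 * mcse, 0.02))
  }
})

test_that("results with R identical trees match the single-tree fit", {
  set.seed(53)
  cfg_sim <- comparative_sim_config(n_taxa = 9, n_trees = 1, seed = 54)
  trees <- simulate_tree_set(cfg_sim)
  td <- simulate_trend_data(trees, cfg_sim)
  om1 <- build_vcv_array(trees, taxa = td$data$taxon)
  rep_trees <- structure(rep(trees, 8), class = "multiPhylo")
  om8 <- build_vcv_array(rep_trees, taxa = td$data$taxon)
  mk <- function(seed) mcmc_settings(chains = 2, burn = 800, draws = 2500, seed = seed)
  f1 <- fit_bvs_regression(td$data, om1, bvs_config(mcmc = mk(55)))
  f8 <- fit_bvs_regression(td$data, om8, bvs_config(mcmc = mk(56)))
  b1 <- f1$summary_draws[, "beta[reliance]"]
  b8 <- f8$summary_draws[, "beta[reliance]"]
  expect_lt(abs(mean(b1) - mean(b8)),
            3 * sqrt(var(b1) / 200 + var(b8) / 200) + 0.02)
  expect_lt(max(abs(f1$indicators$posterior_mean - f8$indicators$posterior_mean)), 0.12)
})

test_that("a strong predictor is selected and the two-stage refit narrows its CRI", {
  cfg_sim <- comparative_sim_config(n_taxa = 12, n_trees = 20,
                                    coefficients = c(reliance = -1.0, distance = 0,
                                                     body_size = 0),
                                    residual_variance = 0.15, seed = 57)
  trees <- simulate_tree_set(cfg_sim)
  td <- simulate_trend_data(trees, cfg_sim)
  om <- build_vcv_array(trees, taxa = td$data$taxon)
  res <- two_stage_selection(td$data, om,
           bvs_config(mcmc = mcmc_settings(chains = 2, burn = 800, draws = 2500, seed = 58)))
  ind <- res$stage1$indicators
  expect_gte(ind$posterior_mean[ind$covariate == "reliance"], 0.75)
  expect_true(all(c("distance", "body_size") %in% res$dropped |
                  ind$posterior_mean[ind$covariate %in% c("distance", "body_size")] < 0.75))
  # the retained slope is recovered and its stage-2 CRI is no wider
  t1 <- tidy(res$stage1); t2 <- tidy(res$stage2)
  w1 <- with(t1[t1$term == "beta[reliance]", ], hi - lo)
  w2 <- with(t2[t2$term == "beta[reliance]", ], hi - lo)
  # no wider than stage 1 up to Monte Carlo noise in the interval endpoints
  expect_lte(w2, w1 * 1.3)
  expect_s3_class(res$stage2, "bvs_fit")
  expect_true(all(res$stage2$indicators$fixed[res$stage2$indicators$covariate %in% res$dropped]))
})

test_that("with a single always-active covariate stage 2 changes nothing", {
  cfg_sim <- comparative_sim_config(n_taxa = 10, n_trees = 5,
                                    coefficients = c(reliance = -1.2),
                                    residual_variance = 0.1, seed = 59)
  trees <- simulate_tree_set(cfg_sim)
  td <- simulate_trend_data(trees, cfg_sim)
  om <- build_vcv_array(trees, taxa = td$data$taxon)
  res <- two_stage_selection(td$data, om,
           bvs_config(mcmc = mcmc_settings(chains = 2, burn = 600, draws = 2000, seed = 60)))
  expect_length(res$dropped, 0)
  expect_false(any(res$stage2$indicators$fixed))
})

test_that("null-covariate indicators return to the Bernoulli(0.5) prior as information vanishes", {
  # raw-scale fits at two noise levels: when the residual variance dwarfs
  # anything a coefficient could explain, the marginal-likelihood ratio for
  # v_c tends to 1 and the indicator mean tends to its prior
  vbar_at <- function(sigma2, seed) {
    base <- comparative_sim_config(n_taxa = 10, n_trees = 10,
                                   coefficients = c(x1 = 0, x2 = 0),
                                   indicators = c(0, 0),
                                   residual_variance = sigma2, seed = 61)
    trees <- simulate_tree_set(base)
    td <- simulate_trend_data(trees, base)
    om <- build_vcv_array(trees, taxa = td$data$taxon)
    fit <- fit_bvs_regression(td$data, om,
             bvs_config(standardize = FALSE,
                        mcmc = mcmc_settings(chains = 2, burn = 800, draws = 2500, seed = seed)))
    fit$indicators$posterior_mean
  }
  low_noise <- vbar_at(0.25, 62)
  high_noise <- vbar_at(2500, 63)
  # with informative data the null covariates are called unimportant
  expect_true(all(low_noise <= 0.25))
  # with vanishing information the indicators drift off the floor toward the
  # prior instead of staying anti-decisive
  expect_true(all(high_noise > 0.05 & high_noise < 0.95))
  expect_lt(mean(abs(high_noise - 0.5)), mean(abs(low_noise - 0.5)))
})

test_that("input validation refuses mismatched orders and degenerate covariates", {
  cfg_sim <- comparative_sim_config(n_taxa = 6, n_trees = 2, seed = 63)
  trees <- simulate_tree_set(cfg_sim)
  td <- simulate_trend_data(trees, cfg_sim)
  om <- build_vcv_array(trees, taxa = td$data$taxon)
  shuffled <- td$data[rev(seq_len(nrow(td$data))), ]
  expect_error(fit_bvs_regression(shuffled, om, bvs_config()), "order")
  const <- td$data
  const$reliance <- 1
  expect_error(fit_bvs_regression(const, om, bvs_config()), "zero-variance")
  expect_error(fit_bvs_regression(td$data, om,
                                  bvs_config(fixed_indicators = c(nope = 0))), "unknown covariate")
  expect_warning(fit_bvs_regression(
    dplyr::slice(td$data, 1:4),
    build_vcv_array(lapply(trees, function(tr) ape::keep.tip(tr, td$data$taxon[1:4])),
                    taxa = td$data$taxon[1:4]),
    bvs_config(mcmc = mcmc_settings(chains = 2, burn = 100, draws = 200, seed = 64))),
    "taxa for")
})
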