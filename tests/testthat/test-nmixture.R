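test_that("identical data, seed and chain count give identical posteriors", {
  sim <- simulate_counts(tiny_count_config(seed = 1))
  spec <- nmix_spec(mcmc = tiny_mcmc(seed = 4, burn = 200L, draws = 200L))
  f1 <- fit_flyway_model(sim$counts, spec)
  f2 <- fit_flyway_model(sim$counts, spec)
  expect_identical(f1$summary_draws, f2$summary_draws)
  expect_identical(f1$diagnostics, f2$diagnostics)
  # a different seed moves the draws
  spec2 <- nmix_spec(mcmc = tiny_mcmc(seed = 5, burn = 200L, draws = 200L))
  f3 <- fit_flyway_model(sim$counts, spec2)
  expect_false(identical(f1$summary_draws, f3$summary_draws))
})

test_that("latent abundance never falls below the largest replicate count", {
  tf <- tiny_flyway_fit(sim_seed = 2, fit_seed = 3)
  packed <- tf$fit$packed
  cmax <- tapply(packed$count, packed$syi, max)
  for (ch in tf$fit$draws) {
    mins <- apply(ch$N, 2L, min)
    expect_true(all(mins[as.integer(names(cmax))] >= cmax))
  }
})

test_that("with detection fixed at 1 the fit reduces to a Poisson mixed model", {
  skip_if_not_installed("lme4")
  cfg <- tiny_count_config(seed = 6, n_sites_per_node = 4L, n_years = 15L,
                           detection_year_mean = Inf, detection_re_sd = 0,
                           replicates_range = c(1L, 1L))
  sim <- simulate_counts(cfg)
  spec <- nmix_spec(fix_detection = 1, mcmc = tiny_mcmc(seed = 7, burn = 600L, draws = 800L))
  fit <- fit_flyway_model(sim$counts, spec)
  # independent route: frequentist Poisson GLMM on the same data
  d <- sim$counts
  d$yearc <- d$year - mean(unique(d$year))
  d$sy <- paste(d$site_id, d$year)
  glmm <- lme4::glmer(count ~ yearc + (1 | site_id) + (1 | sy), data = d,
                      family = stats::poisson)
  beta_glmm <- lme4::fixef(glmm)[["yearc"]]
  bdraws <- fit$summary_draws[, "beta"]
  mcse <- sd(bdraws) / sqrt(50)  # conservative effective sample size
  expect_lt(abs(mean(bdraws) - beta_glmm), max(2 * mcse, 0.01))
  # with P = 1 the annual totals equal the observed yearly sums exactly
  tot <- derive_total_abundance(fit)
  obs <- dplyr::summarise(dplyr::group_by(d, year), s = sum(count))
  expect_equal(tot$mean, as.numeric(obs$s), tolerance = 1e-9)
})

test_that("the flyway trend is recovered on a moderate synthetic dataset", {
  cfg <- tiny_count_config(seed = 9, n_sites_per_node = 4L, n_nodes = 2L,
                           n_years = 15L, node_intercepts = rep(log(100), 2),
                           node_trends = rep(-0.05, 2))
  sim <- simulate_counts(cfg)
  fit <- fit_flyway_model(sim$counts, nmix_spec(mcmc = tiny_mcmc(seed = 10, burn = 700L, draws = 900L)))
  b <- fit$summary_draws[, "beta"]
  expect_lt(abs(mean(b) - (-0.05)), 0.03)
  ci <- quantile(b, c(0.01, 0.99))
  expect_true(ci[1] < -0.05 + 0.03 && ci[2] > -0.05 - 0.03)
})

test_that("node trends are estimated per node and errors name degenerate nodes", {
  cfg <- tiny_count_config(seed = 12, n_sites_per_node = 3L, n_nodes = 2L,
                           n_years = 12L, node_trends = c(-0.06, 0),
                           node_intercepts = rep(log(80), 2))
  sim <- simulate_counts(cfg)
  fit <- fit_node_model(sim$counts, nmix_spec(variant = "node",
                                              mcmc = tiny_mcmc(seed = 13, burn = 600L, draws = 700L)))
  td <- tidy(fit, check_convergence = FALSE)
  b1 <- td$mean[td$parameter == "beta[node_1]"]
  b2 <- td$mean[td$parameter == "beta[node_2]"]
  expect_lt(abs(b1 - (-0.06)), 0.035)
  expect_lt(abs(b2 - 0), 0.035)
  expect_lt(b1, b2)

  # a node reduced to a single site-year is refused by name
  broken <- dplyr::filter(sim$counts,
                          node_id != "node_2" | (site_id == "site_04" & year == min(year)))
  expect_error(fit_node_model(broken, nmix_spec(variant = "node", mcmc = tiny_mcmc())),
               "node_2")
})

test_that("a single-site dataset still fits, with a warning about identifiability", {
  cfg <- tiny_count_config(seed = 15, n_sites_per_node = 1L, n_nodes = 1L,
                           node_intercepts = log(60), node_trends = -0.04)
  sim <- simulate_counts(cfg)
  expect_warning(
    fit <- fit_flyway_model(sim$counts, nmix_spec(mcmc = tiny_mcmc(seed = 16, burn = 300L, draws = 300L))),
    "weakly identified"
  )
  expect_s3_class(fit, "nmix_fit")
})

test_that("non-converged fits are flagged and summaries refuse without an override", {
  tf <- tiny_flyway_fit(sim_seed = 17, fit_seed = 18)
  fit <- tf$fit
  fit$converged <- FALSE
  fit$diagnostics$rhat[1] <- 1.5
  expect_error(tidy(fit), "not converged")
  expect_s3_class(tidy(fit, check_convergence = FALSE), "tbl_df")
})

test_that("the data-augmentation backend agrees with the marginalized sampler", {
  skip_if_not_installed("rjags")
  cfg <- tiny_count_config(seed = 19, n_years = 12L)
  sim <- simulate_counts(cfg)
  fm <- fit_flyway_model(sim$counts, nmix_spec(mcmc = tiny_mcmc(seed = 20, burn = 800L, draws = 1000L)))
  fj <- fit_flyway_model(sim$counts,
                         nmix_spec(backend = "jags",
                                   mcmc = tiny_mcmc(seed = 21, burn = 2000L, draws = 2000L)))
  bm <- fm$summary_draws[, "beta"]
  bj <- fj$summary_draws[, "beta"]
  # agreement within combined Monte Carlo error (conservative ESS)
  tol <- 2 * sqrt(var(bm) / 100 + var(bj) / 50) + 0.005
  expect_lt(abs(mean(bm) - mean(bj)), tol)
  am <- fm$summary_draws[, "alpha"]
  aj <- fj$summary_draws[, "alpha"]
  expect_lt(abs(mean(am) - mean(aj)), 4 * sqrt(var(am) / 50 + var(aj) / 25) + 0.1)
})
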