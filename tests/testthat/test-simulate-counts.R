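test_that("perfect detection with no extra noise yields Poisson counts equal to latent N", {
  cfg <- tiny_count_config(seed = 11, detection_year_mean = Inf, detection_re_sd = 0,
                           overdispersion_sd = 0, site_effect_sd = 0,
                           node_trends = rep(0, 2), n_years = 30L,
                           replicates_range = c(1L, 1L))
  sim <- simulate_counts(cfg)
  # every count equals its site-year's latent N
  joined <- dplyr::inner_join(sim$counts, sim$truth$site_years,
                              by = c("site_id", "year"))
  expect_identical(as.integer(joined$count), as.integer(joined$N))
  # counts are then marginally Poisson(exp(alpha)): mean and variance agree
  lam <- exp(cfg$node_intercepts[1])
  expect_lt(abs(mean(sim$counts$count) - lam) / lam, 0.1)
  expect_lt(abs(var(sim$counts$count) / mean(sim$counts$count) - 1), 0.35)
})

test_that("mean simulated count matches the Monte Carlo binomial-Poisson oracle", {
  p <- 0.6
  alpha <- log(80)
  cfg <- tiny_count_config(seed = 21, n_sites_per_node = 10L, n_nodes = 2L,
                           n_years = 25L, node_intercepts = rep(alpha, 2),
                           node_trends = rep(0, 2), site_effect_sd = 0,
                           overdispersion_sd = 0, detection_re_sd = 0,
                           detection_year_mean = qlogis(p),
                           replicates_range = c(2L, 2L))
  sim <- simulate_counts(cfg)
  set.seed(99)
  oracle <- mean(rbinom(1e4, rpois(1e4, exp(alpha)), p))
  mc_se <- sd(sim$counts$count) / sqrt(nrow(sim$counts))
  expect_lt(abs(mean(sim$counts$count) - oracle), 4 * mc_se + 1)
  expect_equal(oracle / exp(alpha), p, tolerance = 0.02)
})

test_that("simulated count moments match closed-form thinned-Poisson moments", {
  # thinning a Poisson(lambda) by p gives Poisson(lambda p): mean = var = lambda p
  p <- 0.55
  cfg <- tiny_count_config(seed = 31, n_sites_per_node = 12L, n_nodes = 2L,
                           n_years = 25L, node_intercepts = rep(log(40), 2),
                           node_trends = rep(0, 2), site_effect_sd = 0,
                           overdispersion_sd = 0, detection_re_sd = 0,
                           detection_year_mean = qlogis(p),
                           replicates_range = c(1L, 1L))
  sim <- simulate_counts(cfg)
  m <- mean(sim$counts$count)
  expect_equal(m, 40 * p, tolerance = 0.1)
  expect_equal(var(sim$counts$count) / m, 1, tolerance = 0.25)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  s1 <- simulate_counts(tiny_count_config(seed = 5, missingness = 0.2))
  s2 <- simulate_counts(tiny_count_config(seed = 5, missingness = 0.2))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$site_years, s2$truth$site_years)
  s3 <- simulate_counts(tiny_count_config(seed = 6, missingness = 0.2))
  expect_false(identical(s1$counts$count, s3$counts$count))
})

test_that("every site-year keeps at least one replicate under missingness", {
  sim <- simulate_counts(tiny_count_config(seed = 8, missingness = 0.6,
                                           replicates_range = c(1L, 5L)))
  reps <- dplyr::count(sim$counts, site_id, year)
  expect_true(all(reps$n >= 1L))
  expect_identical(nrow(reps), nrow(sim$truth$site_years))
})

test_that("invalid generator configurations are rejected with the field named", {
  expect_error(count_sim_config(n_years = 1), "n_years")
  expect_error(count_sim_config(site_effect_sd = -0.1), "site_effect_sd")
  expect_error(count_sim_config(node_trends = c(0, 0, 0)), "node_trends")
  expect_error(count_sim_config(node_intercepts = 1), "node_intercepts")
  expect_error(count_sim_config(replicates_range = c(0, 3)), "replicates_range")
  expect_error(count_sim_config(detection_year_mean = c(0, 1)), "detection_year_mean")
})

test_that("count datasets round-trip losslessly through the CSV writer", {
  sim <- simulate_counts(tiny_count_config(seed = 3, missingness = 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(sim$counts, path)
  back <- read_counts(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$counts))
})
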