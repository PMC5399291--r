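# shared builders for small, fast fixtures used across test files

# compact count scenario: moderate abundance so fits stay quick
tiny_count_config <- function(seed = 1, ...) {
  defaults <- list(
    n_sites_per_node = 2L, n_nodes = 2L, n_years = 10L,
    replicates_range = c(2L, 3L),
    node_intercepts = rep(log(60), 2), node_trends = rep(-0.04, 2),
    site_effect_sd = 0.4, overdispersion_sd = 0.1,
    detection_year_mean = qlogis(0.6), detection_re_sd = 0.25,
    seed = seed
  )
  do.call(count_sim_config, modifyList(defaults, list(...)))
}

tiny_mcmc <- function(seed = 1, chains = 2L, burn = 500L, draws = 600L, thin = 1L) {
  mcmc_settings(chains = chains, burn = burn, draws = draws, thin = thin, seed = seed)
}

tiny_flyway_fit <- function(sim_seed = 1, fit_seed = 2, ...) {
  sim <- simulate_counts(tiny_count_config(seed = sim_seed, ...))
  fit <- fit_flyway_model(sim$counts, nmix_spec(mcmc = tiny_mcmc(seed = fit_seed)))
  list(sim = sim, fit = fit)
}

# brute-force probability-space oracle for the marginalized likelihood
brute_marginal_loglik <- function(counts, lambda, p, n_max) {
  p <- rep_len(p, length(counts))
  total <- 0
  for (N in max(counts):n_max) {
    term <- dpois(N, lambda)
    for (j in seq_along(counts)) term <- term * dbinom(counts[j], N, p[j])
    total <- total + term
  }
  log(total)
}

# brute-force Brownian VCV via per-tip root paths (independent of the
# package's edge-accumulation implementation)
brute_vcv <- function(tree) {
  M <- length(tree$tip.label)
  root <- M + 1L
  anc <- function(node) {
    path <- node
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      node <- tree$edge[e, 1]
      path <- c(path, node)
    }
    rev(path)
  }
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      d <- d + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    d
  }
  V <- matrix(0, M, M, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(M), anc)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    common <- intersect(paths[[a]], paths[[b]])
    if (a == b) {
      V[a, a] <- depth_of(a)
    } else {
      V[a, b] <- depth_of(common[length(common)])
    }
  }
  V
}
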