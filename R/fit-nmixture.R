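#' Fit a hierarchical binomial-Poisson N-mixture model
#'
#' Estimates detection-corrected abundance and log-linear population trends
#' from replicated counts. `fit_node_model()` fits an intercept
#' \eqn{\alpha_k} and trend \eqn{\beta_k} per non-breeding node;
#' `fit_flyway_model()` fits a single intercept and trend across all sites,
#' giving the flyway-level trend. Both share the site random effect
#' \eqn{\omega_i}, the site-year overdispersion effect \eqn{\epsilon_{it}},
#' and the detection model \eqn{\mathrm{logit}\, P_{ijt} = \gamma_t +
#' \delta_{ijt}}.
#'
#' Priors: intercepts, trends and yearly detection means get vague
#' \eqn{N(0, 10^3)} priors; random-effect variances get inverse-gamma
#' \eqn{(10^{-3}, 10^{-3})} priors (precision ~ gamma); the per-count
#' detection-effect sd gets a Uniform(0, 100) prior. The default
#' `"marginal"` backend sums the latent abundance out of the likelihood per
#' site-year and samples the remaining hierarchy with an adaptive
#' Metropolis-within-Gibbs scheme (conjugate draws for every Gaussian
#' level, plus joint moves along the abundance-detection ridge). The
#' `"jags"` backend samples the latent abundances directly by data
#' augmentation.
#'
#' Convergence is assessed with the Gelman-Rubin potential scale reduction
#' factor on every monitored parameter; a fit with any \eqn{\hat{R}} above
#' `spec$rhat_max` is flagged and [tidy.nmix_fit()] refuses to summarise it
#' unless overridden.
#'
#' @param data a `count_data` tibble (see [as_count_data()])
#' @param spec an [nmix_spec()]; the `variant` field is forced to match the
#'   calling function
#' @return an object of class `nmix_fit` with elements `draws` (per-chain
#'   posterior draws of all parameters and latent states), `summary_draws`
#'   (combined core-parameter matrix), `diagnostics` (tibble of
#'   \eqn{\hat{R}} per parameter), `converged`, `packed` (indexing
#'   structure), `spec`, and `provenance`
#' @export
fit_node_model <- function(data, spec = nmix_spec(variant = "node")) {
  spec$variant <- "node"
  fit_nmix(data, spec)
}

#' @rdname fit_node_model
#' @export
fit_flyway_model <- function(data, spec = nmix_spec(variant = "flyway")) {
  spec$variant <- "flyway"
  fit_nmix(data, spec)
}

fit_nmix <- function(data, spec) {
  stopifnot(inherits(spec, "nmix_spec"))
  packed <- pack_count_data(data, spec$variant)
  if (packed$nyears < 2L) abort("at least two years of counts are required")
  if (spec$variant == "node" && packed$nsites < 2L) {
    abort("the node model needs at least two sites")
  }
  if (packed$nsites < 2L) {
    warn("single-site dataset: the site random-effect variance is weakly identified")
  }
  chains <- if (spec$backend == "marginal") {
    run_marginal_chains(packed, spec)
  } else {
    run_jags_chains(packed, spec)
  }

  core <- lapply(chains, core_matrix, packed = packed, spec = spec)
  rh <- rhat(core)
  diagnostics <- tibble::tibble(parameter = colnames(core[[1]]), rhat = rh)
  converged <- all(is.finite(rh) & rh <= spec$rhat_max)
  if (!converged) {
    worst <- diagnostics$parameter[which.max(diagnostics$rhat)]
    warn(sprintf(
      "chains not converged: max Rhat %.3f (%s) exceeds %.2f; rerun longer or inspect trace",
      max(diagnostics$rhat), worst, spec$rhat_max))
  }
  structure(list(
    draws = chains,
    summary_draws = do.call(rbind, core),
    diagnostics = diagnostics,
    converged = converged,
    packed = packed,
    spec = spec,
    provenance = list(seed = spec$mcmc$seed, config_hash = config_hash(spec),
                      package_version = as.character(packageVersion("flywaytrends")))
  ), class = "nmix_fit")
}

run_marginal_chains <- function(packed, spec) {
  mc <- spec$mcmc
  cfg <- list(burn = mc$burn, keep = mc$draws, thin = mc$thin,
              prior_var_fixed = spec$prior_fixed_sd^2,
              ig_shape = spec$re_prior_shape, ig_rate = spec$re_prior_rate,
              sd_delta_max = spec$detection_sd_max,
              fix_detection = !is.null(spec$fix_detection),
              p_value = spec$fix_detection %||% 1,
              delta_literal_uniform = spec$delta_literal_uniform,
              n_cap = spec$n_max_cap, keep_latent = TRUE)
  lapply(seq_len(mc$chains), function(ch) {
    set.seed(mc$seed + ch - 1L)
    nmix_chain(packed, cfg)
  })
}

# combined matrix of the monitored (non-latent) parameters for one chain;
# site effects are reported mean-zero (the sampler centres them on alpha)
core_matrix <- function(ch, packed, spec) {
  Kn <- packed$nnodes
  node_names <- if (Kn == 1L) "" else paste0("[", packed$node_levels, "]")
  omega0 <- ch$omega - ch$alpha[, packed$node, drop = FALSE]
  cols <- list(
    setNames(as.data.frame(ch$alpha), paste0("alpha", node_names)),
    setNames(as.data.frame(ch$beta), paste0("beta", node_names)),
    setNames(as.data.frame(omega0), paste0("omega[", packed$site_levels, "]")),
    data.frame(sd_site = sqrt(ch$sig2_om), sd_sityear = sqrt(ch$sig2_eps))
  )
  if (is.null(spec$fix_detection)) {
    cols <- c(cols, list(
      setNames(as.data.frame(ch$gamma), paste0("gamma[", packed$year_seq, "]"))
    ))
    if (!spec$delta_literal_uniform) {
      cols <- c(cols, list(data.frame(sd_detection = ch$sd_delta)))
    }
  }
  as.matrix(do.call(cbind, cols))
}

#' @export
print.nmix_fit <- function(x, ...) {
  mc <- x$spec$mcmc
  cat(sprintf("<nmix_fit> %s model (%s backend) | %d sites, %d years | %d chains x %d draws\n",
              x$spec$variant, x$spec$backend, x$packed$nsites, x$packed$nyears,
              mc$chains, mc$draws))
  cat(sprintf("  converged: %s (max Rhat %.3f, gate %.2f)\n",
              ifelse(x$converged, "yes", "NO"), max(x$diagnostics$rhat), x$spec$rhat_max))
  bn <- grep("^beta", x$diagnostics$parameter, value = TRUE)
  sm <- x$summary_draws[, bn, drop = FALSE]
  for (b in bn) {
    ci <- cri(sm[, b])
    cat(sprintf("  %s: %.4f (95%% CRI %.4f, %.4f)\n", b, mean(sm[, b]), ci[1], ci[2]))
  }
  invisible(x)
}

#' Tidy posterior summaries of an N-mixture fit
#'
#' @param x an `nmix_fit`
#' @param check_convergence refuse to summarise a fit whose Gelman-Rubin
#'   diagnostics exceed the spec gate (default `TRUE`); set `FALSE` to
#'   override deliberately
#' @param cri_level credible-interval level
#' @param ... unused
#' @return a tibble: `parameter`, `mean`, `sd`, `lo`, `median`, `hi`, `rhat`
#' @export
tidy.nmix_fit <- function(x, check_convergence = TRUE, cri_level = 0.95, ...) {
  if (check_convergence && !x$converged) {
    abort(paste0("fit has not converged (max Rhat ",
                 sprintf("%.3f", max(x$diagnostics$rhat)),
                 "); pass check_convergence = FALSE to summarise anyway"))
  }
  m <- x$summary_draws
  a <- (1 - cri_level) / 2
  tibble::tibble(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2L, sd),
    lo = apply(m, 2L, quantile, a),
    median = apply(m, 2L, median),
    hi = apply(m, 2L, quantile, 1 - a),
    rhat = x$diagnostics$rhat[match(colnames(m), x$diagnostics$parameter)]
  )
}

#' One-row model overview of an N-mixture fit
#'
#' @param x an `nmix_fit`
#' @param ... unused
#' @return a one-row tibble: variant, backend, chain geometry, number of
#'   sites/years/counts, max \eqn{\hat{R}}, convergence flag
#' @export
glance.nmix_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    backend = x$spec$backend,
    chains = x$spec$mcmc$chains,
    draws = x$spec$mcmc$draws,
    n_sites = x$packed$nsites,
    n_years = x$packed$nyears,
    n_counts = length(x$packed$count),
    max_rhat = max(x$diagnostics$rhat),
    converged = x$converged
  )
}
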