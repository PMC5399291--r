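# data-augmentation backend: the latent abundances N are sampled directly in
# JAGS (the original software idiom for this model class); used as a
# cross-check for the default marginalized sampler

jags_model_string <- function(spec) {
  det_block <- if (!is.null(spec$fix_detection)) {
    "  for (n in 1:Nobs) {
    count[n] ~ dbin(p_fixed, N[syi[n]])
  }"
  } else if (spec$delta_literal_uniform) {
    "  for (n in 1:Nobs) {
    count[n] ~ dbin(P[n], N[syi[n]])
    logit(P[n]) <- gamma[yr[n]] + delta[n]
    delta[n] ~ dunif(0, 100)
  }
  for (t in 1:nyears) { gamma[t] ~ dnorm(0, prec_fixed) }"
  } else {
    "  for (n in 1:Nobs) {
    count[n] ~ dbin(P[n], N[syi[n]])
    logit(P[n]) <- lp[n]
    lp[n] ~ dnorm(gamma[yr[n]], tau_d)
  }
  for (t in 1:nyears) { gamma[t] ~ dnorm(0, prec_fixed) }
  sd_d ~ dunif(0, sd_max)
  tau_d <- pow(sd_d, -2)"
  }
  paste0("model {
  for (s in 1:S) {
    N[s] ~ dpois(lambda[s])
    log(lambda[s]) <- loglam[s]
    loglam[s] ~ dnorm(omega[site[s]] + beta[nodeof[site[s]]] * yearc[s], tau_eps)
  }
", det_block, "
  for (i in 1:nsites) { omega[i] ~ dnorm(alpha[nodeof[i]], tau_o) }
  for (k in 1:nnodes) {
    alpha[k] ~ dnorm(0, prec_fixed)
    beta[k] ~ dnorm(0, prec_fixed)
  }
  tau_eps ~ dgamma(ig_shape, ig_rate)
  tau_o ~ dgamma(ig_shape, ig_rate)
}
")
}

run_jags_chains <- function(packed, spec) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    abort("backend = \"jags\" requires the rjags package")
  }
  mc <- spec$mcmc
  fixed_p <- !is.null(spec$fix_detection)
  jd <- list(S = packed$S, Nobs = length(packed$count), count = packed$count,
             syi = packed$syi, yr = packed$yr, site = packed$site,
             nodeof = packed$node, yearc = packed$yearc,
             nsites = packed$nsites, nyears = packed$nyears, nnodes = packed$nnodes,
             prec_fixed = 1 / spec$prior_fixed_sd^2,
             ig_shape = spec$re_prior_shape, ig_rate = spec$re_prior_rate)
  if (fixed_p) {
    jd$p_fixed <- spec$fix_detection
    jd$nyears <- NULL
  } else if (!spec$delta_literal_uniform) {
    jd$sd_max <- spec$detection_sd_max
  }
  cmax <- integer(packed$S)
  agg <- tapply(packed$count, packed$syi, max)
  cmax[as.integer(names(agg))] <- as.integer(agg)
  p0 <- spec$fix_detection %||% 0.6
  monitors <- c("alpha", "beta", "omega", "lambda", "N", "tau_eps", "tau_o",
                if (!fixed_p) c("gamma", "P"),
                if (!fixed_p && !spec$delta_literal_uniform) "sd_d")
  lapply(seq_len(mc$chains), function(ch) {
    inits <- list(N = cmax + 1L,
                  loglam = log(cmax / p0 + 1),
                  .RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = mc$seed + ch - 1L)
    jm <- rjags::jags.model(textConnection(jags_model_string(spec)), data = jd,
                            inits = inits, n.chains = 1L, n.adapt = max(500L, mc$burn %/% 2L),
                            quiet = TRUE)
    update(jm, mc$burn)
    sm <- rjags::coda.samples(jm, monitors, n.iter = mc$draws * mc$thin, thin = mc$thin)[[1]]
    cn <- colnames(sm)
    grab <- function(stub, n) {
      if (n == 1L && stub %in% cn) return(matrix(sm[, stub], ncol = 1L))
      as.matrix(sm[, paste0(stub, "[", seq_len(n), "]"), drop = FALSE])
    }
    out <- list(
      alpha = grab("alpha", packed$nnodes),
      beta = grab("beta", packed$nnodes),
      omega = grab("omega", packed$nsites),
      loglam = log(grab("lambda", packed$S)),
      N = grab("N", packed$S),
      sig2_eps = 1 / sm[, "tau_eps"],
      sig2_om = 1 / sm[, "tau_o"]
    )
    if (!fixed_p) {
      out$gamma <- grab("gamma", packed$nyears)
      out$lp <- qlogis(grab("P", length(packed$count)))
      out$sd_delta <- if (spec$delta_literal_uniform) rep(NA_real_, nrow(sm)) else sm[, "sd_d"]
    } else {
      out$gamma <- matrix(qlogis(spec$fix_detection), nrow(sm), packed$nyears)
      out$lp <- matrix(qlogis(spec$fix_detection), nrow(sm), length(packed$count))
      out$sd_delta <- rep(0, nrow(sm))
    }
    out
  })
}
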