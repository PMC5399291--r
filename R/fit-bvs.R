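#' Bayesian variable selection over a phylogenetic tree set
#'
#' Fits the comparative regression \eqn{Td \sim \mathrm{MVN}(\mu, \sigma^2
#' C_q)} with \eqn{\mu_z = \alpha + \sum_c v_c \theta_c X_{zc} + \epsilon_z},
#' where \eqn{C_q} is the unit-height Brownian VCV of tree `q` (a uniform
#' mixture over the tree set, with `q` updated every iteration),
#' \eqn{v_c \sim \mathrm{Bernoulli}(0.5)} are selection indicators and
#' \eqn{\epsilon} is an optional i.i.d. taxon-level error. Priors:
#' \eqn{\alpha, \theta_c \sim N(0, 10^3)}, variances inverse-gamma
#' \eqn{(10^{-3}, 10^{-3})}.
#'
#' The sampler is a collapsed Gibbs scheme exact for this linear-Gaussian
#' model: indicator updates integrate the regression coefficients out
#' analytically (avoiding the stuck-indicator pathology of naive
#' one-at-a-time samplers under vague coefficient priors), coefficients,
#' the error term and variances are drawn from their conjugate
#' conditionals, and the tree index from its categorical conditional.
#'
#' By default covariates and response are z-scored before fitting, so
#' coefficients are comparable across covariates and the reported slope is
#' on the standardized (correlation-like) scale.
#'
#' @param data tibble with columns `taxon`, `trend`, and covariate columns;
#'   the taxon order must match `omega$taxa` exactly (no silent reordering)
#' @param omega a [build_vcv_array()] result
#' @param config a [bvs_config()]
#' @param covariates covariate column names (default: every numeric column
#'   except `trend`, `trend_lo`, `trend_hi`)
#' @return an object of class `bvs_fit`: per-chain draws of \eqn{\alpha},
#'   \eqn{\theta_c}, \eqn{v_c}, \eqn{\beta_c = v_c\theta_c}, variances and
#'   tree index; indicator posterior means with classifications;
#'   standardization metadata; diagnostics
#' @export
fit_bvs_regression <- function(data, omega, config = bvs_config(), covariates = NULL) {
  stopifnot(inherits(omega, "vcv_array"), inherits(config, "bvs_config"))
  data <- tibble::as_tibble(data)
  if (!all(c("taxon", "trend") %in% names(data))) {
    abort("`data` needs `taxon` and `trend` columns")
  }
  if (!identical(data$taxon, omega$taxa)) {
    abort("taxon order in `data` does not match the VCV array tip order; reorder explicitly")
  }
  covariates <- covariates %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c("trend", "trend_lo", "trend_hi"))
  if (!length(covariates)) abort("no covariate columns found")
  X <- as.matrix(data[covariates])
  if (anyNA(X) || anyNA(data$trend)) abort("covariates and trends must be complete")
  y <- data$trend
  M <- length(y)
  C <- length(covariates)
  if (M <= C) warn(sprintf("only %d taxa for %d candidate covariates", M, C))

  std <- list(standardize = config$standardize,
              x_center = rep(0, C), x_scale = rep(1, C),
              y_center = 0, y_scale = 1)
  if (config$standardize) {
    std$x_center <- colMeans(X); std$x_scale <- apply(X, 2L, sd)
    if (any(std$x_scale == 0)) {
      abort(paste0("zero-variance covariate(s): ",
                   paste(covariates[std$x_scale == 0], collapse = ", ")))
    }
    X <- scale(X, std$x_center, std$x_scale)
    std$y_center <- mean(y); std$y_scale <- sd(y)
    y <- (y - std$y_center) / std$y_scale
  }

  fixed <- rep(NA_real_, C)
  names(fixed) <- covariates
  if (!is.null(config$fixed_indicators)) {
    bad <- setdiff(names(config$fixed_indicators), covariates)
    if (length(bad)) abort(paste0("unknown covariate in fixed_indicators: ",
                                  paste(bad, collapse = ", ")))
    fixed[names(config$fixed_indicators)] <- config$fixed_indicators
  }

  mc <- config$mcmc
  chains <- lapply(seq_len(mc$chains), function(ch) {
    set.seed(mc$seed + ch - 1L)
    bvs_chain(y, X, omega, config, fixed, mc)
  })

  vcols <- paste0("v[", covariates, "]")
  core <- lapply(chains, function(ch) {
    df <- cbind(alpha = ch$alpha,
                setNames(as.data.frame(ch$beta), paste0("beta[", covariates, "]")),
                sigma2 = ch$sigma2)
    if (config$include_resid_effect) df$sigma2_eps <- ch$sigma2_eps
    as.matrix(df)
  })
  rh <- rhat(core)
  vbar <- colMeans(do.call(rbind, lapply(chains, `[[`, "v")))
  indicators <- tibble::tibble(
    covariate = covariates,
    posterior_mean = vbar,
    classification = classify_indicator(vbar, config$important, config$unimportant),
    fixed = !is.na(fixed)
  )
  structure(list(
    draws = chains,
    summary_draws = do.call(rbind, core),
    indicators = indicators,
    diagnostics = tibble::tibble(parameter = colnames(core[[1]]), rhat = rh),
    covariates = covariates,
    standardization = std,
    config = config,
    provenance = list(seed = mc$seed, config_hash = config_hash(config),
                      package_version = as.character(packageVersion("flywaytrends")))
  ), class = "bvs_fit")
}

# collapsed Gibbs for one chain
bvs_chain <- function(y, X, omega, config, fixed, mc) {
  M <- length(y)
  C <- ncol(X)
  Rq <- dim(omega$omega)[3]
  Om <- omega$omega
  logdet_om <- vapply(seq_len(Rq), function(q) {
    as.numeric(determinant(Om[, , q], logarithm = TRUE)$modulus)
  }, numeric(1))
  s2b <- config$prior_coef_sd^2
  a0 <- 1e-3; b0 <- 1e-3
  pv <- config$indicator_prior

  v <- ifelse(is.na(fixed), 1, fixed)
  theta <- rep(0, C)
  alpha <- mean(y)
  eps <- rep(0, M)
  sigma2 <- max(var(y), 1e-4)
  sigma2_eps <- if (config$include_resid_effect) max(var(y) / 10, 1e-6) else 0
  q <- sample.int(Rq, 1L)

  # log marginal likelihood of ystar under active set act (b integrated out)
  lml <- function(ystar, act, q, sigma2) {
    W <- cbind(1, X[, act, drop = FALSE])
    S <- sigma2 * omega$scaled[, , q] + s2b * tcrossprod(W)
    ch <- chol(S)
    -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, ystar, transpose = TRUE)^2))
  }

  n_iter <- mc$burn + mc$draws * mc$thin
  keep <- mc$draws
  out <- list(alpha = numeric(keep), theta = matrix(0, keep, C), v = matrix(0, keep, C),
              beta = matrix(0, keep, C), sigma2 = numeric(keep),
              sigma2_eps = numeric(keep), q = integer(keep))
  free <- which(is.na(fixed))
  for (it in seq_len(n_iter)) {
    ystar <- y - eps
    # (1) indicators, coefficients collapsed
    for (c_ in sample(free)) {
      v1 <- v; v1[c_] <- 1
      v0 <- v; v0[c_] <- 0
      l1 <- lml(ystar, which(v1 == 1), q, sigma2)
      l0 <- lml(ystar, which(v0 == 1), q, sigma2)
      p1 <- plogis((l1 - l0) + qlogis(pv))
      v[c_] <- as.numeric(runif(1) < p1)
    }
    # (2) coefficients for the active set (conjugate)
    act <- which(v == 1)
    W <- cbind(1, X[, act, drop = FALSE])
    A <- crossprod(W, Om[, , q] %*% W) / sigma2 + diag(ncol(W)) / s2b
    Ainv_ch <- chol(A)
    m <- backsolve(Ainv_ch, backsolve(Ainv_ch, crossprod(W, Om[, , q] %*% ystar) / sigma2,
                                      transpose = TRUE))
    bdraw <- drop(m + backsolve(Ainv_ch, rnorm(ncol(W))))
    alpha <- bdraw[1]
    theta[] <- 0
    theta[act] <- bdraw[-1]
    # inactive coefficients keep their prior (drawn for completeness)
    inact <- setdiff(seq_len(C), act)
    theta[inact] <- rnorm(length(inact), 0, config$prior_coef_sd)
    mu_fit <- drop(W %*% bdraw)
    # (3) taxon-level error
    if (config$include_resid_effect) {
      r <- y - mu_fit
      Ae <- Om[, , q] / sigma2 + diag(M) / sigma2_eps
      Ae_ch <- chol(Ae)
      me <- backsolve(Ae_ch, backsolve(Ae_ch, Om[, , q] %*% r / sigma2, transpose = TRUE))
      eps <- drop(me + backsolve(Ae_ch, rnorm(M)))
      sigma2_eps <- 1 / rgamma(1, a0 + M / 2, b0 + sum(eps^2) / 2)
    }
    # (4) phylogenetic residual variance
    resid <- y - mu_fit - eps
    qf <- drop(crossprod(resid, Om[, , q] %*% resid))
    sigma2 <- 1 / rgamma(1, a0 + M / 2, b0 + qf / 2)
    # (5) tree index (uniform mixture conditional)
    if (Rq > 1L) {
      lq <- vapply(seq_len(Rq), function(qq) {
        0.5 * logdet_om[qq] - drop(crossprod(resid, Om[, , qq] %*% resid)) / (2 * sigma2)
      }, numeric(1))
      lq <- lq - max(lq)
      q <- sample.int(Rq, 1L, prob = exp(lq))
    }
    kidx <- it - mc$burn
    if (kidx > 0 && kidx %% mc$thin == 0) {
      k <- kidx %/% mc$thin
      if (k <= keep) {
        out$alpha[k] <- alpha
        out$theta[k, ] <- theta
        out$v[k, ] <- v
        out$beta[k, ] <- v * theta
        out$sigma2[k] <- sigma2
        out$sigma2_eps[k] <- sigma2_eps
        out$q[k] <- q
      }
    }
  }
  out
}

#' Classify an indicator posterior mean
#'
#' Thresholds an indicator's posterior mean into evidence categories:
#' `>= 0.75` important, `<= 0.25` unimportant, otherwise inconclusive
#' (boundary values take the non-strict category).
#'
#' @param posterior_mean value(s) in \[0, 1\]
#' @param important,unimportant the thresholds
#' @return character vector of classifications
#' @export
#' @examples
#' classify_indicator(c(0.75, 0.5, 0.25))
classify_indicator <- function(posterior_mean, important = 0.75, unimportant = 0.25) {
  if (any(posterior_mean < 0 | posterior_mean > 1)) {
    abort("indicator posterior means must lie in [0, 1]")
  }
  dplyr::case_when(
    posterior_mean >= important ~ "important",
    posterior_mean <= unimportant ~ "unimportant",
    .default = "inconclusive"
  )
}

#' @export
print.bvs_fit <- function(x, ...) {
  cat(sprintf("<bvs_fit> %d covariates | %d chains x %d draws | max Rhat %.3f\n",
              length(x$covariates), x$config$mcmc$chains, x$config$mcmc$draws,
              max(x$diagnostics$rhat)))
  print(x$indicators)
  invisible(x)
}

#' Tidy coefficient and indicator summaries of a variable-selection fit
#'
#' @param x a `bvs_fit`
#' @param ... unused
#' @return a tibble with one row per model term: posterior mean, sd, CRI of
#'   \eqn{\beta_c = v_c \theta_c} (and the intercept), the indicator
#'   posterior mean and its classification
#' @export
tidy.bvs_fit <- function(x, ...) {
  draws <- x$summary_draws
  lev <- x$config$cri_level
  terms <- c("alpha", paste0("beta[", x$covariates, "]"))
  out <- purrr::map_dfr(terms, function(tm) {
    d <- draws[, tm]
    ci <- cri(d, lev)
    tibble::tibble(term = tm, mean = mean(d), sd = sd(d), lo = ci[1], hi = ci[2])
  })
  out$indicator_mean <- c(NA, x$indicators$posterior_mean)
  out$classification <- c(NA, x$indicators$classification)
  out
}

#' One-row overview of a variable-selection fit
#'
#' @param x a `bvs_fit`
#' @param ... unused
#' @return a one-row tibble: taxa, covariates, trees, important covariates,
#'   residual variance posterior mean, max \eqn{\hat{R}}
#' @export
glance.bvs_fit <- function(x, ...) {
  tibble::tibble(
    n_covariates = length(x$covariates),
    n_important = sum(x$indicators$classification == "important"),
    n_unimportant = sum(x$indicators$classification == "unimportant"),
    sigma2_mean = mean(x$summary_draws[, "sigma2"]),
    max_rhat = max(x$diagnostics$rhat),
    standardized = x$standardization$standardize
  )
}

#' Two-stage variable selection with refit
#'
#' Stage 1 runs the full indicator regression; covariates classified
#' unimportant (indicator posterior mean at or below the lower threshold)
#' then have their indicators pinned to 0 and the model is refitted,
#' sharpening the estimates of retained predictors. If every covariate is
#' unimportant the refit is intercept-only (with a warning).
#'
#' @inheritParams fit_bvs_regression
#' @return an object of class `bvs_two_stage`: `stage1` and `stage2` fits
#'   plus a combined `report` tibble
#' @export
two_stage_selection <- function(data, omega, config = bvs_config(), covariates = NULL) {
  stage1 <- fit_bvs_regression(data, omega, config, covariates)
  drop_c <- stage1$indicators$covariate[stage1$indicators$classification == "unimportant"]
  if (length(drop_c) == length(stage1$covariates)) {
    warn("all covariates classified unimportant; stage 2 is intercept-only")
  }
  cfg2 <- config
  fixed <- setNames(rep(0, length(drop_c)), drop_c)
  cfg2$fixed_indicators <- c(config$fixed_indicators, fixed)
  cfg2$mcmc$seed <- config$mcmc$seed + 1000L
  stage2 <- fit_bvs_regression(data, omega, cfg2, covariates)
  report <- dplyr::bind_rows(
    dplyr::mutate(tidy(stage1), stage = 1L, .before = 1L),
    dplyr::mutate(tidy(stage2), stage = 2L, .before = 1L)
  )
  structure(list(stage1 = stage1, stage2 = stage2, report = report,
                 dropped = drop_c),
            class = "bvs_two_stage")
}

#' @export
print.bvs_two_stage <- function(x, ...) {
  cat("<bvs_two_stage>\n  stage 1 classifications:\n")
  print(x$stage1$indicators)
  cat(sprintf("  dropped in stage 2: %s\n",
              if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "none"))
  retained <- setdiff(x$stage2$covariates, x$dropped)
  t2 <- tidy(x$stage2)
  for (cv in retained) {
    row <- t2[t2$term == paste0("beta[", cv, "]"), ]
    cat(sprintf("  stage-2 %s: %.3f (95%% CRI %.3f, %.3f)\n",
                cv, row$mean, row$lo, row$hi))
  }
  invisible(x)
}
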