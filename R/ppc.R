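#' Chi-square posterior predictive check
#'
#' For each retained posterior draw, computes the chi-square discrepancy
#' \eqn{\sum_n (c_n - E[c_n])^2 / (E[c_n] + \varepsilon)} (with
#' \eqn{E[c_n] = N_{it} P_{ijt}} from that draw) for the observed counts and
#' for replicate counts simulated from the same draw, and returns the
#' proportion of draws in which the observed discrepancy exceeds the
#' replicate discrepancy. Values near 0.50 indicate adequate fit; values
#' near 0 or 1 indicate systematic lack of fit.
#'
#' @param fit an `nmix_fit` with retained latent draws
#' @param eps stabilising constant added to the expected count
#' @return an object of class `nmix_ppc`: list with `p_value`, and the
#'   per-draw discrepancies `chisq_obs`, `chisq_rep`
#' @export
posterior_predictive_check <- function(fit, eps = 0.5) {
  stopifnot(inherits(fit, "nmix_fit"))
  ch1 <- fit$draws[[1]]
  if (is.null(ch1$N) || is.null(ch1$lp)) {
    abort("posterior does not retain latent draws (N, detection logits)")
  }
  counts <- fit$packed$count
  syi <- fit$packed$syi
  obs_d <- rep_d <- numeric(0)
  for (ch in fit$draws) {
    ndr <- nrow(ch$N)
    P <- plogis(ch$lp)                  # draws x Nobs
    Nm <- ch$N[, syi, drop = FALSE]     # draws x Nobs
    E <- Nm * P
    o <- rowSums((matrix(counts, ndr, length(counts), byrow = TRUE) - E)^2 / (E + eps))
    crep <- matrix(rbinom(length(Nm), as.vector(Nm), as.vector(P)), ndr)
    r <- rowSums((crep - E)^2 / (E + eps))
    obs_d <- c(obs_d, o)
    rep_d <- c(rep_d, r)
  }
  structure(list(p_value = mean(obs_d > rep_d),
                 chisq_obs = obs_d, chisq_rep = rep_d),
            class = "nmix_ppc")
}

#' @export
print.nmix_ppc <- function(x, ...) {
  cat(sprintf("<nmix_ppc> Bayesian p-value: %.3f (%d draws)\n",
              x$p_value, length(x$chisq_obs)))
  cat("  near 0.50 indicates adequate fit\n")
  invisible(x)
}
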