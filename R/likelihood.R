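#' Marginalized site-year N-mixture log-likelihood
#'
#' Computes \eqn{\log \sum_{N=\max(c)}^{n_{\max}} \mathrm{Pois}(N \mid
#' \lambda)\prod_j \mathrm{Bin}(c_j \mid N, p_j)} in log space: the exact
#' likelihood of one site-year's replicate counts with the latent abundance
#' summed out. This is the kernel behind the `"marginal"` sampler backend;
#' exposing it directly makes the fit verifiable against brute-force
#' enumeration.
#'
#' When `n_max` is `NULL` the truncation point starts at
#' `max(counts, qpois(0.9999, lambda))` and doubles until the result changes
#' by less than `tol`, so the truncation error is negligible at any
#' \eqn{\lambda}.
#'
#' @param counts integer replicate counts for one site-year
#' @param lambda Poisson mean of the latent abundance (> 0)
#' @param p detection probability per replicate, each in (0, 1]; scalar or
#'   one per count
#' @param n_max upper summation bound (>= `max(counts)`), or `NULL` for the
#'   adaptive rule
#' @param tol convergence tolerance of the adaptive rule
#' @return the log marginal likelihood (scalar)
#' @export
#' @examples
#' sityear_marginal_loglik(3L, lambda = 2, p = 1)   # log dpois(3, 2)
#' sityear_marginal_loglik(c(2L, 1L), lambda = 4, p = c(0.6, 0.5))
sityear_marginal_loglik <- function(counts, lambda, p, n_max = NULL, tol = 1e-8) {
  if (length(counts) < 1L || any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be nonnegative integers")
  }
  check_scalar_number(lambda, "lambda", lower = .Machine$double.xmin)
  p <- rep_len(p, length(counts))
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  if (any(p == 0 & counts > 0)) {
    warn("p = 0 with a positive count has zero likelihood")
    return(-Inf)
  }
  cmax <- max(counts)
  eval_sum <- function(nm) {
    N <- cmax:nm
    lt <- dpois(N, lambda, log = TRUE)
    for (j in seq_along(counts)) lt <- lt + dbinom(counts[j], N, p[j], log = TRUE)
    logsumexp(lt)
  }
  if (!is.null(n_max)) {
    if (n_max < cmax) {
      abort(sprintf("`n_max` (%d) is below the largest count (%d)", n_max, cmax))
    }
    return(eval_sum(as.integer(n_max)))
  }
  nm <- max(cmax, qpois(0.9999, lambda))
  val <- eval_sum(nm)
  repeat {
    nm2 <- nm * 2L + 10L
    val2 <- eval_sum(nm2)
    if (is.infinite(val) && is.infinite(val2)) return(val2)
    if (abs(val2 - val) < tol) return(val2)
    nm <- nm2
    val <- val2
  }
}

#' Detection probability from the yearly mean and a per-count effect
#'
#' The detection model is \eqn{\mathrm{logit}\, P_{ijt} = \gamma_t +
#' \delta_{ijt}}: the inverse logit of the yearly mean detection (logit
#' scale) plus a per-count random effect.
#'
#' @param gamma_t yearly mean detection on the logit scale
#' @param delta per-count random effect (default 0)
#' @return detection probability in (0, 1)
#' @export
#' @examples
#' detection_model(0, 0)          # 0.5
#' detection_model(qlogis(0.6))   # 0.6
detection_model <- function(gamma_t, delta = 0) {
  stopifnot(is.numeric(gamma_t), is.numeric(delta))
  plogis(gamma_t + delta)
}
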