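# internal helpers shared across modules

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# n draws from MVN(mu, Sigma) via Cholesky; returns n x p matrix
rmvn <- function(n, mu, Sigma) {
  z <- matrix(rnorm(n * length(mu)), n) %*% chol(Sigma)
  sweep(z, 2L, mu, "+")
}

# Gelman-Rubin potential scale reduction factor, vectorised over columns of
# per-chain draw matrices (list of matrices with identical dims)
rhat <- function(chains) {
  stopifnot(length(chains) >= 2L)
  n <- nrow(chains[[1]])
  cm <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  cv <- vapply(chains, function(m) apply(m, 2L, var), numeric(ncol(chains[[1]])))
  if (is.null(dim(cm))) { cm <- matrix(cm, nrow = 1L); cv <- matrix(cv, nrow = 1L) }
  W <- rowMeans(cv)
  B <- n * apply(cm, 1L, var)
  out <- sqrt((n - 1) / n + B / (n * W))
  out[W < .Machine$double.eps] <- 1
  out
}

# central credible interval bounds from draws
cri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE))
}

# deterministic short hash of an R object (provenance stamping)
config_hash <- function(x) rlang::hash(x)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}
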