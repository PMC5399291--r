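#' Simulate a set of random ultrametric trees
#'
#' Draws `n_trees` random coalescent trees on `n_taxa` labelled tips and
#' rescales each to unit root-to-tip height, emulating a posterior sample
#' of equally plausible ultrametric phylogenies.
#'
#' @param config a [comparative_sim_config()]
#' @param taxa optional tip labels (default `taxon_01`, ...)
#' @return a `multiPhylo` of ultrametric trees
#' @export
simulate_tree_set <- function(config = comparative_sim_config(), taxa = NULL) {
  stopifnot(inherits(config, "comparative_sim_config"))
  if (config$n_taxa < 3L) abort("at least 3 taxa are required")
  set.seed(config$seed)
  taxa <- taxa %||% sprintf("taxon_%02d", seq_len(config$n_taxa))
  trees <- lapply(seq_len(config$n_trees), function(q) {
    tr <- ape::rcoal(config$n_taxa, tip.label = taxa)
    h <- max(diag(vcv_from_tree(tr)))
    tr$edge.length <- tr$edge.length / h
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate taxon-level trend estimates with phylogenetic residuals
#'
#' Draws the comparative dataset the variable-selection regression assumes:
#' standardized covariates per taxon, a linear predictor
#' \eqn{\mu_z = \alpha + \sum_c v_c \theta_c X_{zc}} using the true
#' indicators, and trends \eqn{Td_z \sim \mathrm{MVN}(\mu, \sigma^2 C)}
#' where C is the unit-height Brownian VCV of one tree sampled from the
#' set.
#'
#' @param trees a `multiPhylo` whose tips are the taxa
#' @param config a [comparative_sim_config()]
#' @return an object of class `comparative_sim`: list with `data` (tibble:
#'   `taxon`, `trend`, `trend_lo`, `trend_hi`, covariate columns), `truth`
#'   (intercept, coefficients, indicators, residual variance, the sampled
#'   tree index), and `config`
#' @export
simulate_trend_data <- function(trees, config = comparative_sim_config()) {
  stopifnot(inherits(config, "comparative_sim_config"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  taxa <- trees[[1]]$tip.label
  M <- length(taxa)
  if (M != config$n_taxa) {
    abort(sprintf("tree has %d tips but config$n_taxa is %d", M, config$n_taxa))
  }
  covs <- names(config$coefficients)
  set.seed(config$seed + 1L)
  X <- matrix(rnorm(M * length(covs)), M, dimnames = list(taxa, covs))
  X <- scale(X)  # standardized covariates, as fitted
  q <- sample.int(length(trees), 1L)
  C <- scale_and_invert(vcv_from_tree(trees[[q]])[taxa, taxa])$scaled
  b <- config$coefficients * config$indicators
  mu <- config$intercept + drop(X %*% b)
  td <- drop(rmvn(1L, mu, config$residual_variance * C))
  data <- tibble::as_tibble(as.data.frame(X)) |>
    dplyr::mutate(taxon = taxa, trend = td, trend_lo = td, trend_hi = td,
                  .before = 1L)
  structure(list(
    data = data,
    truth = list(intercept = config$intercept, coefficients = config$coefficients,
                 indicators = config$indicators,
                 residual_variance = config$residual_variance,
                 tree_index = q, mu = setNames(mu, taxa)),
    config = config
  ), class = "comparative_sim")
}

#' @export
print.comparative_sim <- function(x, ...) {
  active <- names(x$truth$coefficients)[x$truth$indicators == 1]
  cat(sprintf("<comparative_sim> %d taxa | active covariate(s): %s | sigma2 %.3g\n",
              nrow(x$data), if (length(active)) paste(active, collapse = ", ") else "none",
              x$truth$residual_variance))
  invisible(x)
}
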