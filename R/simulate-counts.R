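#' Simulate replicated shorebird counts with known ground truth
#'
#' Draws a complete synthetic count dataset from the same hierarchical
#' binomial-Poisson process the N-mixture models assume: site-year
#' abundance \eqn{N_{it} \sim \mathrm{Pois}(\lambda_{it})} with
#' \eqn{\log \lambda_{it} = \omega_i + \alpha_k + \beta_k (t - t^*) +
#' \epsilon_{it}} (year centred on the mean year \eqn{t^*}), and replicate
#' counts \eqn{c_{ijt} \sim \mathrm{Bin}(N_{it}, P_{ijt})} with
#' \eqn{\mathrm{logit}\, P_{ijt} = \gamma_t + \delta_{ijt}}. Replicate
#' months are drawn from the austral-summer months (Jan, Feb, Mar, Nov,
#' Dec); replicates within a season are exchangeable. Missing replicates are
#' removed completely at random, always leaving at least one count per
#' site-year.
#'
#' @param config a [count_sim_config()]
#' @return an object of class `count_sim`: a list with `counts` (a
#'   `count_data` tibble), `truth` (all latent draws: per-site effects,
#'   per-site-year \eqn{\epsilon}, \eqn{\lambda}, `N`, and per-count
#'   \eqn{\delta} and `P`), and `config`
#' @export
simulate_counts <- function(config = count_sim_config()) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  cf <- config
  n_sites <- cf$n_sites_per_node * cf$n_nodes
  node_of_site <- rep(seq_len(cf$n_nodes), each = cf$n_sites_per_node)
  site_ids <- sprintf("site_%02d", seq_len(n_sites))
  node_ids <- sprintf("node_%d", seq_len(cf$n_nodes))
  years <- cf$start_year + seq_len(cf$n_years) - 1L
  yearc <- seq_len(cf$n_years) - mean(seq_len(cf$n_years))

  omega <- rnorm(n_sites, 0, cf$site_effect_sd)
  sites <- tibble::tibble(site_id = site_ids,
                          node_id = node_ids[node_of_site],
                          omega = omega)

  sy <- tidyr::expand_grid(site = seq_len(n_sites), t = seq_len(cf$n_years))
  k <- node_of_site[sy$site]
  eps <- rnorm(nrow(sy), 0, cf$overdispersion_sd)
  loglam <- omega[sy$site] + cf$node_intercepts[k] + cf$node_trends[k] * yearc[sy$t] + eps
  lambda <- exp(loglam)
  N <- rpois(nrow(sy), lambda)

  site_years <- tibble::tibble(site_id = site_ids[sy$site],
                               node_id = node_ids[k],
                               year = years[sy$t],
                               eps = eps, lambda = lambda, N = N)

  months_pool <- c(1L, 2L, 3L, 11L, 12L)
  rep_vals <- seq(cf$replicates_range[1], cf$replicates_range[2])
  reps <- rep_vals[sample.int(length(rep_vals), nrow(sy), replace = TRUE)]
  if (cf$missingness > 0) {
    extra <- reps - 1L
    dropped <- rbinom(nrow(sy), extra, cf$missingness)
    reps <- reps - dropped
  }
  obs <- tibble::tibble(
    row = rep(seq_len(nrow(sy)), reps),
    month = unlist(lapply(reps, function(J) sort(sample(months_pool, J))))
  )
  gamma_t <- cf$detection_year_mean
  tt <- sy$t[obs$row]
  delta <- rnorm(nrow(obs), 0, cf$detection_re_sd)
  P <- plogis(gamma_t[tt] + delta)
  count <- rbinom(nrow(obs), N[obs$row], P)

  counts <- tibble::tibble(
    site_id = site_ids[sy$site[obs$row]],
    node_id = node_ids[node_of_site[sy$site[obs$row]]],
    year = years[tt],
    month = obs$month,
    count = count
  )
  obs_truth <- dplyr::bind_cols(counts, tibble::tibble(delta = delta, P = P))

  structure(list(
    counts = as_count_data(counts),
    truth = list(sites = sites, site_years = site_years, obs = obs_truth,
                 gamma = tibble::tibble(year = years, gamma = gamma_t,
                                        mean_detection = plogis(gamma_t)),
                 node_intercepts = setNames(cf$node_intercepts, node_ids),
                 node_trends = setNames(cf$node_trends, node_ids)),
    config = cf
  ), class = "count_sim")
}

#' @export
print.count_sim <- function(x, ...) {
  cat(sprintf("<count_sim> %d counts | %d sites in %d nodes | %d years | seed %d\n",
              nrow(x$counts), nrow(x$truth$sites), x$config$n_nodes,
              x$config$n_years, x$config$seed))
  invisible(x)
}
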