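#' Flyway trend table for ten EAAF shorebird taxa
#'
#' The packaged taxon-level summary of flyway population trends for the ten
#' East Asian-Australasian Flyway shorebird taxa: Yellow Sea reliance (the
#' proportion of the flyway population staging on Yellow Sea tidal
#' mudflats), the posterior mean log-scale trend with its 95% CRI, and an
#' EAAF-endemism flag. Used as the reference input for the comparative
#' summaries.
#'
#' @param path optional path to a CSV with the same columns
#' @return a `trend_table` tibble: `taxon`, `reliance`, `trend`, `lo`,
#'   `hi`, `endemic`, plus the derived `credible` classification
#' @export
shorebird_trends <- function(path = NULL) {
  path <- path %||% system.file("extdata", "eaaf_trend_table.csv",
                                package = "flywaytrends", mustWork = TRUE)
  x <- readr::read_csv(path, col_types = readr::cols(
    taxon = readr::col_character(), reliance = readr::col_double(),
    trend = readr::col_double(), lo = readr::col_double(),
    hi = readr::col_double(), endemic = readr::col_logical()
  ))
  if (any(x$lo > x$trend | x$trend > x$hi)) {
    abort("trend table violates lo <= trend <= hi")
  }
  if (any(x$reliance < 0 | x$reliance > 1)) abort("reliance must lie in [0, 1]")
  x$credible <- classify_trend(x$lo, x$hi)
  class(x) <- c("trend_table", class(x))
  x
}

#' Classify a trend by its credible interval
#'
#' A trend is a credible decline when the whole 95% CRI is below zero and a
#' credible increase when it is wholly above zero; an interval touching
#' zero at either end is not credible.
#'
#' @param lo,hi credible-interval bounds (vectorised)
#' @return character: `"credible decline"`, `"credible increase"`, or
#'   `"not credible"`
#' @export
#' @examples
#' classify_trend(-0.095, -0.055)   # credible decline
#' classify_trend(-0.031, 0.000)    # not credible (touches zero)
classify_trend <- function(lo, hi) {
  if (any(lo > hi)) abort("`lo` must not exceed `hi`")
  dplyr::case_when(
    hi < 0 ~ "credible decline",
    lo > 0 ~ "credible increase",
    .default = "not credible"
  )
}

#' Count credibly declining taxa
#'
#' @param table a trend table with `lo` and `hi` columns
#' @return integer count of rows classified as credible declines
#' @export
count_credible_declines <- function(table) {
  sum(classify_trend(table$lo, table$hi) == "credible decline")
}

#' Mean trend of a reliance group, in percent per year
#'
#' Averages the per-year log-scale trends (transformed with
#' [percent_per_year()]) over the taxa whose Yellow Sea reliance falls on
#' one side of a threshold. The default grouping follows the reported
#' split: the low group is reliance <= 0.40 and the high group reliance >=
#' 0.50.
#'
#' @param table a trend table (`reliance`, `trend` columns)
#' @param threshold reliance cut-off
#' @param side `"high"` (reliance >= threshold) or `"low"` (<= threshold)
#' @param method transform passed to [percent_per_year()]
#' @return mean percent-per-year trend of the group (scalar)
#' @export
group_mean_trend <- function(table, threshold, side = c("high", "low"),
                             method = c("linear", "exponential")) {
  side <- match.arg(side)
  sel <- if (side == "high") table$reliance >= threshold else table$reliance <= threshold
  if (!any(sel)) abort(sprintf("no taxa with reliance %s %.2f",
                               ifelse(side == "high", ">=", "<="), threshold))
  mean(percent_per_year(table$trend[sel], method))
}

#' Standardized reliance-trend slope
#'
#' Z-scores Yellow Sea reliance and the trend across taxa and regresses
#' trend on reliance. Run tree-free (the default closed form) the
#' standardized slope equals the Pearson correlation; run through the
#' phylogenetic regression it is the posterior-mean standardized slope.
#'
#' @param table a trend table (`taxon`, `reliance`, `trend`)
#' @param exclude_taxa taxa dropped before fitting (e.g. a subspecies the
#'   tree set cannot separate)
#' @param fit optional `bvs_fit` whose reliance slope should be reported
#'   instead of the closed form
#' @return a one-row tibble: `slope`, `lo`, `hi`, `n`, `method`
#' @export
reliance_trend_slope <- function(table, exclude_taxa = NULL, fit = NULL) {
  tab <- dplyr::filter(table, !.data$taxon %in% exclude_taxa)
  if (nrow(tab) < 3L) abort("need at least 3 taxa")
  if (sd(tab$reliance) == 0) abort("reliance has zero variance")
  if (!is.null(fit)) {
    td <- tidy(fit)
    row <- td[grepl("reliance", td$term), ]
    return(tibble::tibble(slope = row$mean, lo = row$lo, hi = row$hi,
                          n = nrow(tab), method = "phylogenetic"))
  }
  z <- function(v) (v - mean(v)) / sd(v)
  m <- lm(z(tab$trend) ~ z(tab$reliance))
  ci <- stats::confint(m)[2, ]
  tibble::tibble(slope = unname(coef(m)[2]), lo = ci[[1]], hi = ci[[2]],
                 n = nrow(tab), method = "ols")
}

#' Convert a log-scale trend to percent per year
#'
#' The default linear transform is \eqn{100\beta}; the exponential
#' alternative \eqn{100(e^{\beta} - 1)} is available for strict
#' multiplicative interpretation. At the trend magnitudes involved
#' (|beta| < 0.1) the two differ by well under half a percentage point.
#'
#' @param beta per-year log-scale slope(s)
#' @param method `"linear"` (default) or `"exponential"`
#' @return percent change per year
#' @export
#' @examples
#' percent_per_year(-0.075)            # -7.5
#' percent_per_year(-0.075, "exponential")
percent_per_year <- function(beta, method = c("linear", "exponential")) {
  method <- match.arg(method)
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  switch(method,
         linear = 100 * beta,
         exponential = 100 * (exp(beta) - 1))
}
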