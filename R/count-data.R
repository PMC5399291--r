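#' Validate a replicated-count table
#'
#' A count dataset is a long-format tibble with one row per replicate count:
#' columns `site_id`, `node_id`, `year`, `month`, `count`. A missing
#' replicate is simply an absent row (or an `NA` count, which is dropped
#' with a message). Each site must belong to exactly one node, and every
#' site-year entering the likelihood must retain at least one count.
#'
#' @param x a data frame with columns `site_id`, `node_id`, `year`, `month`,
#'   `count`
#' @return a validated `count_data` tibble
#' @export
as_count_data <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("site_id", "node_id", "year", "month", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("count data lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(x$count))) {
    inform(sprintf("dropping %d NA-count rows (missing replicates)", sum(is.na(x$count))))
    x <- dplyr::filter(x, !is.na(.data$count))
  }
  bad <- which(x$count < 0 | x$count != floor(x$count))
  if (length(bad)) {
    abort(sprintf("counts must be nonnegative integers; offending row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  multi <- x |>
    dplyr::distinct(.data$site_id, .data$node_id) |>
    dplyr::count(.data$site_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(paste0("site(s) mapped to more than one node: ",
                 paste(multi$site_id, collapse = ", ")))
  }
  dup <- x |>
    dplyr::count(.data$site_id, .data$year, .data$month) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate (site, year, month) rows, e.g. %s / %d / %d",
                  dup$site_id[1], dup$year[1], dup$month[1]))
  }
  x <- dplyr::arrange(x, .data$site_id, .data$year, .data$month)
  x$count <- as.integer(x$count)
  x$year <- as.integer(x$year)
  class(x) <- c("count_data", class(x))
  x
}

#' Read or write a replicated-count CSV
#'
#' The on-disk format is the long format of [as_count_data()]:
#' `site_id,node_id,year,month,count`, with a blank count marking a missing
#' replicate. Schema violations are reported with row numbers.
#'
#' @param path file path
#' @return `read_counts()` returns a validated `count_data` tibble
#' @export
read_counts <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    node_id = readr::col_character(),
    year = readr::col_integer(),
    month = readr::col_integer(),
    count = readr::col_integer()
  ))
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(sprintf("malformed counts CSV at row(s): %s",
                  paste(head(unique(prob$row), 5L), collapse = ", ")))
  }
  bad <- which(!is.na(raw$count) & raw$count < 0)
  if (length(bad)) {
    abort(sprintf("negative count at data row(s): %s", paste(head(bad, 5L), collapse = ", ")))
  }
  as_count_data(raw)
}

#' @param x a `count_data` tibble
#' @rdname read_counts
#' @return `write_counts()` returns `path` invisibly
#' @export
write_counts <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @export
print.count_data <- function(x, ...) {
  nsites <- dplyr::n_distinct(x$site_id)
  nnodes <- dplyr::n_distinct(x$node_id)
  yrs <- range(x$year)
  cat(sprintf("<count_data> %d counts | %d sites in %d nodes | years %d-%d\n",
              nrow(x), nsites, nnodes, yrs[1], yrs[2]))
  NextMethod()
}

# pack a validated count table into the flat integer-indexed structure the
# samplers consume; year centring on the mean year happens here
pack_count_data <- function(data, variant = "flyway") {
  data <- as_count_data(data)
  site_levels <- sort(unique(data$site_id))
  node_of_site <- data |>
    dplyr::distinct(.data$site_id, .data$node_id) |>
    dplyr::arrange(.data$site_id)
  node_levels <- sort(unique(node_of_site$node_id))
  years <- sort(unique(data$year))
  year_seq <- seq(min(years), max(years))
  yearc_all <- year_seq - mean(year_seq)

  sy <- data |>
    dplyr::distinct(.data$site_id, .data$year) |>
    dplyr::arrange(.data$site_id, .data$year)
  sy$syi <- seq_len(nrow(sy))

  obs <- data |>
    dplyr::inner_join(sy, by = c("site_id", "year")) |>
    dplyr::arrange(.data$syi, .data$month)

  if (variant == "node") {
    per_node <- sy |>
      dplyr::inner_join(node_of_site, by = "site_id") |>
      dplyr::count(.data$node_id)
    lonely <- per_node$node_id[per_node$n < 2L]
    if (length(lonely)) {
      abort(paste0("node(s) with a single site-year cannot support a trend: ",
                   paste(lonely, collapse = ", ")))
    }
  }

  list(
    S = nrow(sy),
    count = as.integer(obs$count),
    syi = as.integer(obs$syi),
    yr = as.integer(match(obs$year, year_seq)),
    site = as.integer(match(sy$site_id, site_levels)),
    node = if (variant == "node") as.integer(match(node_of_site$node_id, node_levels))
           else rep(1L, length(site_levels)),
    yearc = yearc_all[match(sy$year, year_seq)],
    syyear = as.integer(match(sy$year, year_seq)),
    nsites = length(site_levels),
    nyears = length(year_seq),
    nnodes = if (variant == "node") length(node_levels) else 1L,
    site_levels = site_levels,
    node_levels = node_levels,
    year_seq = as.integer(year_seq),
    sy_site = sy$site_id,
    sy_year = as.integer(sy$year)
  )
}
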