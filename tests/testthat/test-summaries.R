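tab <- shorebird_trends()

test_that("the packaged trend table is complete and internally consistent", {
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$lo <= tab$trend & tab$trend <= tab$hi))
  expect_true(all(tab$reliance >= 0 & tab$reliance <= 1))
})

test_that("credible-trend classification matches every row's interval", {
  expect_identical(classify_trend(-0.095, -0.055), "credible decline")
  expect_identical(classify_trend(-0.031, 0.000), "not credible")   # endpoint at zero
  expect_identical(classify_trend(-0.021, 0.041), "not credible")
  expect_identical(classify_trend(0.002, 0.05), "credible increase")
  expect_error(classify_trend(1, 0), "lo")
  # the seven steepest-declining taxa are exactly the credible declines
  declining <- tab$taxon[classify_trend(tab$lo, tab$hi) == "credible decline"]
  expect_length(declining, 7L)
  expect_false("Red-necked stint" %in% declining)   # upper bound exactly 0
  expect_false("Grey-tailed tattler" %in% declining)
  expect_false("Terek sandpiper" %in% declining)
})

test_that("decline counting behaves on boundary tables", {
  expect_identical(count_credible_declines(tab), 7L)
  up <- tibble::tibble(lo = c(0.01, 0.2), hi = c(0.05, 0.4))
  expect_identical(count_credible_declines(up), 0L)
  down <- tibble::tibble(lo = c(-0.2, -0.1), hi = c(-0.1, -0.01))
  expect_identical(count_credible_declines(down), 2L)
})

test_that("reliance-group mean trends reproduce the group contrasts", {
  expect_equal(group_mean_trend(tab, 0.50, "high"), -5.2, tolerance = 0.15)
  expect_equal(group_mean_trend(tab, 0.40, "low"), -1.0, tolerance = 0.15)
  single <- tab[tab$taxon == "Curlew sandpiper", ]
  expect_equal(group_mean_trend(single, 0.5, "high"), 100 * single$trend)
  expect_error(group_mean_trend(tab, 1.5, "high"), "no taxa")
  # the high (>= 0.5) and low (<= 0.4) groups partition all ten taxa
  n_high <- sum(tab$reliance >= 0.50)
  n_low <- sum(tab$reliance <= 0.40)
  expect_identical(n_high + n_low, 10L)
  expect_identical(sum(tab$reliance > 0.40 & tab$reliance < 0.50), 0L)
})

test_that("the standardized reliance-trend slope behaves like a correlation", {
  sl <- reliance_trend_slope(tab, exclude_taxa = "Bar-tailed godwit (baueri)")
  expect_identical(sl$n, 9L)
  r <- with(tab[tab$taxon != "Bar-tailed godwit (baueri)", ], cor(reliance, trend))
  expect_equal(sl$slope, r, tolerance = 1e-10)
  # collinear input gives exactly +/- 1
  fake <- tibble::tibble(taxon = letters[1:5], reliance = seq(0.1, 0.9, length.out = 5),
                         trend = -0.1 * seq(0.1, 0.9, length.out = 5))
  expect_equal(reliance_trend_slope(fake)$slope, -1, tolerance = 1e-10)
  # affine rescaling of either variable leaves the slope unchanged
  resc <- dplyr::mutate(tab, trend = 100 * trend + 3)
  expect_equal(reliance_trend_slope(resc, "Bar-tailed godwit (baueri)")$slope,
               sl$slope, tolerance = 1e-10)
  expect_error(reliance_trend_slope(dplyr::mutate(tab, reliance = 0.5)), "zero variance")
  expect_error(reliance_trend_slope(tab[1:2, ]), "at least 3")
})

test_that("randomly shuffling reliance destroys the relationship on average", {
  set.seed(71)
  slopes <- replicate(200, {
    shuf <- tab
    shuf$reliance <- sample(shuf$reliance)
    reliance_trend_slope(shuf)$slope
  })
  expect_lt(abs(mean(slopes)), 0.1)
  expect_gt(sd(slopes), 0.1)   # individual shuffles scatter widely around zero
})

test_that("percent-per-year transforms are exact and consistent at small slopes", {
  expect_identical(percent_per_year(0), 0)
  expect_identical(percent_per_year(0, "exponential"), 0)
  expect_equal(percent_per_year(-0.075), -7.5)
  expect_equal(percent_per_year(-0.075, "exponential"), 100 * (exp(-0.075) - 1))
  expect_equal(percent_per_year(-0.052), -5.2)
  expect_lt(abs(percent_per_year(-0.06) - percent_per_year(-0.06, "exponential")), 0.2)
  expect_error(percent_per_year(NA_real_))
})
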