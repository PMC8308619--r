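test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), sqrt(8) / 10) # 0.2828...
  expect_equal(coefficient_of_variation(c(4, 6, 8, 10, 12)), sqrt(10) / 8)
  expect_error(coefficient_of_variation(5), "insufficient-series")
  expect_error(coefficient_of_variation(c(0, 0, 0)), "degenerate-series")
  expect_error(coefficient_of_variation(c(-1, 2)), "negative")
})

test_that("historical variation scales by CV, caps at the baseline, defaults to 10%", {
  hv <- historical_variation(100, 0.25)
  expect_equal(hv$hv, 25)
  expect_equal(hv$provenance, "series_cv")

  capped <- historical_variation(100, 1.5)
  expect_equal(capped$hv, 100)

  dflt <- historical_variation(50, NULL)
  expect_equal(dflt$hv, 5)
  expect_equal(dflt$cv, 0.10)
  expect_equal(dflt$provenance, "default_10pct")

  expect_error(historical_variation(-1, 0.2), "negative baseline")
})

test_that("hv never exceeds the baseline rate over random inputs", {
  set.seed(11)
  for (i in 1:200) {
    b <- runif(1, 0, 1000)
    cv <- runif(1, 0, 3)
    expect_lte(historical_variation(b, cv)$hv, b + 1e-12)
  }
})

test_that("tidal baseline applies mapped-rate precedence and the Puget Sound constant", {
  ps <- tidal_baseline(1000, NULL, in_puget_sound = TRUE)
  expect_equal(ps$rate, 2.15)
  expect_equal(ps$max_resource, 1000)

  mapped <- tidal_baseline(1000, 5.0, in_puget_sound = TRUE)
  expect_equal(mapped$rate, 5.0)

  expect_equal(tidal_baseline(0, NULL, TRUE)$rate, 0)
  expect_equal(tidal_baseline(1000, NULL, FALSE)$rate, 0)
  expect_error(tidal_baseline(-1), "lost_ha")
})

test_that("grassland allocation is proportional and conserves the statewide rate", {
  expect_equal(grassland_county_baseline(100, c(0.25, 0.75))[1], 25)
  out <- grassland_county_baseline(40, c(0.5, 0.3, 0.2))
  expect_equal(out, c(20, 12, 8))
  expect_equal(sum(out), 40)
  expect_equal(grassland_county_baseline(0, c(0.6, 0.4)), c(0, 0))
  expect_error(grassland_county_baseline(10, c(0.5, 0.4)), "sum to 1")
})

test_that("nutrient management area is 40% of cropland", {
  expect_equal(nutrient_max_area(1000), 400)
  expect_equal(nutrient_max_area(0), 0)
  expect_equal(nutrient_max_area(2537), 1014.8)
})

test_that("census disaggregation allocates the residual proportionally to the other year", {
  filled <- disaggregate_missing_counties(100, c(A = 60, B = 30), c(A = 50, B = 20, C = 10))
  expect_equal(filled[["C"]], 10)
  expect_equal(sum(filled), 100)

  unchanged <- disaggregate_missing_counties(100, c(A = 100), c(A = 90))
  expect_equal(unchanged, c(A = 100))

  split <- disaggregate_missing_counties(90, c(A = 80), c(A = 70, C = 20, D = 10))
  expect_equal(split[["C"]], 20 / 3, tolerance = 1e-9)
  expect_equal(split[["D"]], 10 / 3, tolerance = 1e-9)
  expect_equal(sum(split), 90)

  expect_message(
    uniform <- disaggregate_missing_counties(12, c(A = 10), c(A = 9, C = 0, D = 0)),
    "uniformly"
  )
  expect_equal(uniform[["C"]], 1)
  expect_equal(uniform[["D"]], 1)

  expect_error(disaggregate_missing_counties(50, c(A = 60), c(A = 1)), "exceed")
})

test_that("derive_baselines recovers series CVs, applies defaults and drops excluded timber", {
  bundle <- make_toy_bundle(timber_series = c(900, 1000, 1100))
  derived <- derive_baselines(bundle, quiet = TRUE)
  timber <- derived[derived$pathway == "timber", ]
  expect_equal(timber$baseline_rate, 1000)
  expect_equal(timber$cv, sd(c(900, 1000, 1100)) / 1000)
  expect_equal(timber$provenance, "series_cv")

  rip <- derived[derived$pathway == "riparian_reforestation", ]
  expect_equal(rip$cv, 0.10)
  expect_equal(rip$hv, 10)
  expect_equal(rip$provenance, "default_10pct")

  # constant series: cv = 0, hv = 0
  const <- make_toy_bundle(timber_series = c(1000, 1000, 1000))
  d2 <- derive_baselines(const, quiet = TRUE)
  expect_equal(d2$hv[d2$pathway == "timber"], 0)

  # wildfire exclusion removes timber rows for the flagged county
  excl <- make_toy_bundle()
  excl$counties$timber_excluded[1] <- TRUE
  expect_message(d3 <- derive_baselines(excl), "wildfire-excluded")
  expect_false("timber" %in% d3$pathway)
})
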