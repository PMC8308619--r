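test_that("rate draws honour the Normal(mean, sd) family and the seed contract", {
  specs <- tibble::tibble(mean_rate = c(-2, -0.5), sd_rate = c(0, 0))
  expect_equal(draw_rates(specs, seed = 3), c(-2, -0.5))

  specs$sd_rate <- c(0.5, 0.1)
  expect_identical(draw_rates(specs, seed = 3), draw_rates(specs, seed = 3))
  expect_false(all(draw_rates(specs, seed = 3) == draw_rates(specs, seed = 4)))

  bad <- tibble::tibble(mean_rate = -1, sd_rate = -0.1)
  expect_error(draw_rates(bad, seed = 1), "sd_rate")

  # distributional oracle at n = 1e5
  one <- tibble::tibble(mean_rate = -2, sd_rate = 0.5)
  set.seed(99)
  draws <- vapply(1:1e5, function(i) draw_rates(one, seed = i), numeric(1))
  se <- 0.5 / sqrt(1e5)
  expect_lt(abs(mean(draws) - (-2)), 3 * se)
  expect_lt(abs(sd(draws) - 0.5) / 0.5, 0.02)
})

test_that("a single-iteration sd = 0 run equals the deterministic pipeline", {
  bundle <- make_toy_bundle()
  cube <- run_simulation(bundle, "limited", n_iter = 1, seed = 1)
  det <- cube$deterministic
  for (r in seq_len(nrow(det))) {
    expect_equal(as.numeric(cube$values[1, r, ]), det$annual_flux[[r]])
  }
  expect_error(run_simulation(bundle, "limited", n_iter = 0), "n_iter")
})

test_that("identical seeds give bitwise-identical cubes and summaries", {
  bundle <- make_toy_bundle(riparian_sd = 1.5)
  a <- run_simulation(bundle, "ambitious", n_iter = 50, seed = 7)
  b <- run_simulation(bundle, "ambitious", n_iter = 50, seed = 7)
  expect_identical(a$values, b$values)
  expect_identical(
    summarize_iterations(a, by = "pathway"),
    summarize_iterations(b, by = "pathway")
  )
  c2 <- run_simulation(bundle, "ambitious", n_iter = 50, seed = 8)
  expect_false(identical(a$values, c2$values))
})

test_that("quantiles interpolate linearly between order statistics", {
  values <- array(0, dim = c(100, 1, 1))
  values[, 1, 1] <- -(1:100) * 1e6 # MT so the MMT conversion gives -1..-100
  cube <- make_cube(values, tibble::tibble(
    county_id = 1L, pathway = "riparian_reforestation",
    sub_activity = "", ownership = "na", scenario = "ambitious"
  ), scenario = "ambitious")
  s <- summarize_iterations(cube)
  expect_equal(s$median, -50.5)
  expect_equal(s$p05, -95.05)
  expect_equal(s$p95, -5.95)
})

test_that("totals aggregate per-iteration sums, not sums of summaries", {
  # two series whose medians of sums differ from sums of medians
  values <- array(0, dim = c(3, 2, 1))
  values[, 1, 1] <- c(0, 0, -10) * 1e6
  values[, 2, 1] <- c(0, -10, 0) * 1e6
  series <- tibble::tibble(
    county_id = c(1L, 1L),
    pathway = c("timber", "agriculture"),
    sub_activity = c("harvest", "cover_crops"),
    ownership = c("private", "na"),
    scenario = "ambitious"
  )
  cube <- make_cube(values, series)
  tot <- summarize_iterations(cube)
  byp <- summarize_iterations(cube, by = "pathway")
  # brute-force quantile of the elementwise iteration sums
  sums <- c(0, -10, -10)
  expect_equal(tot$median, median(sums))
  expect_equal(tot$p05, as.numeric(quantile(sums, 0.05)))
  # strict inequality: median of total != sum of pathway medians
  expect_equal(sum(byp$median), 0)
  expect_equal(tot$median, -10)
  expect_false(isTRUE(all.equal(tot$median, sum(byp$median))))
})

test_that("sd -> 0 collapses every quantile onto the deterministic value", {
  bundle <- make_toy_bundle(riparian_sd = 0)
  cube <- run_simulation(bundle, "moderate", n_iter = 25, seed = 2)
  s <- summarize_iterations(cube, by = c("county_id", "pathway"))
  expect_equal(s$median, s$p05)
  expect_equal(s$median, s$p95)
})

test_that("rate draws are shared within an iteration across counties and years", {
  cfg <- synth_config(n_counties = 4, n_west = 2, n_timber_excluded = 0)
  sb <- synth_bundle(cfg, seed = 3)
  cube <- run_simulation(sb$bundle, "limited", n_iter = 5, seed = 11)
  det <- cube$deterministic
  # same (key, region) in two west counties: sampled flux ratio must equal
  # the deterministic effective-activity ratio in every iteration and year
  idx <- which(det$pathway == "riparian_reforestation")[1:2]
  eff1 <- det$effective[[idx[1]]]
  eff2 <- det$effective[[idx[2]]]
  ratio <- cube$values[, idx[1], ] / cube$values[, idx[2], ]
  expect_equal(
    as.numeric(ratio),
    rep(eff1 / eff2, each = 5),
    tolerance = 1e-9
  )
})
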