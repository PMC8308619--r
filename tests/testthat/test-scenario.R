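test_that("annual increments ramp over the first decade then hold", {
  lim <- param_row()
  expect_equal(annual_increment(lim, 3, hv = 50), 15)
  expect_equal(annual_increment(lim, 10, hv = 50), 50)
  expect_equal(annual_increment(lim, 25, hv = 50), 50)

  timber_lim <- param_row(post_decade_share = 0.5)
  expect_equal(annual_increment(timber_lim, 20, hv = 50), 25)

  expect_error(annual_increment(lim, 0, hv = 1), "out of range")
  expect_error(annual_increment(lim, 32, hv = 1), "out of range")
  expect_error(annual_increment(lim, 5, hv = -1), "negative")
})

test_that("uncapped limited-general enrollment reaches 26.5 x hv by year 31", {
  traj <- build_trajectory(hv = 10, params = param_row(), max_resource = NA)
  expect_equal(traj$enrolled[31], 265)
  expect_true(is.na(traj$capped_at))
  # brute-force cumulative-sum oracle
  inc <- sapply(1:31, function(t) min(t * 0.1, 1) * 10)
  expect_equal(traj$enrolled, cumsum(inc))
})

test_that("zero historical variation yields an all-zero trajectory", {
  traj <- build_trajectory(hv = 0, params = param_row(), max_resource = 1e6)
  expect_equal(traj$enrolled, rep(0, 31))
  expect_equal(traj$increments, rep(0, 31))
})

test_that("resource caps bind enrollment and preserve the additionality identity", {
  traj <- build_trajectory(hv = 10, params = param_row(), max_resource = 100)
  expect_true(all(traj$enrolled <= 100 + 1e-12))
  expect_equal(max(traj$enrolled), 100)
  # brute-force: first year the uncapped cumulative exceeds the cap
  inc <- sapply(1:31, function(t) min(t * 0.1, 1) * 10)
  expect_equal(traj$capped_at, which(cumsum(inc) > 100)[1])
  # enrolled[t] = enrolled[t-1] + increments[t] exactly, even in the cap year
  expect_equal(cumsum(traj$increments), traj$enrolled)
  expect_true(all(traj$increments >= 0))
})

test_that("trajectories are monotone, capped and linear in hv (property sweep)", {
  set.seed(23)
  for (i in 1:100) {
    p <- param_row(
      ramp_fraction = 0.1,
      growth_share = runif(1),
      post_decade_share = runif(1),
      cap_fraction = runif(1, 0.1, 1)
    )
    hv <- runif(1, 0, 100)
    mr <- runif(1, 10, 2000)
    traj <- build_trajectory(hv, p, mr)
    expect_true(all(diff(traj$enrolled) >= -1e-12))
    expect_true(all(traj$enrolled <= p$cap_fraction * mr + 1e-9))
    expect_equal(cumsum(traj$increments), traj$enrolled)
    # linearity in hv while uncapped
    k <- 3.7
    t_uncapped <- which(is.na(traj$capped_at) | seq_len(31) < traj$capped_at)
    scaled <- build_trajectory(k * hv, p, max_resource = NA)
    base <- build_trajectory(hv, p, max_resource = NA)
    expect_equal(scaled$enrolled, k * base$enrolled, tolerance = 1e-12)
  }
})

test_that("the default registry encodes the timber ownership rules", {
  d <- scenario_defaults()
  pick <- function(scen, path, sub, own) {
    d[d$scenario == scen & d$pathway == path & d$sub_activity == sub & d$ownership == own, ]
  }
  expect_equal(pick("ambitious", "timber", "harvest", "private")$cap_fraction, 0.40)
  expect_equal(pick("ambitious", "timber", "harvest", "state")$cap_fraction, 0.32)
  expect_equal(pick("ambitious", "timber", "harvest", "federal")$cap_fraction, 1.0)
  expect_equal(pick("moderate", "timber", "harvest", "private")$growth_share, 0.30)
  expect_equal(pick("moderate", "timber", "harvest", "state")$growth_share, 0.15)
  expect_equal(pick("moderate", "timber", "harvest", "other")$growth_share, 0.75)
  expect_equal(pick("limited", "timber", "harvest", "private")$post_decade_share, 0.5)
  lim_rip <- pick("limited", "riparian_reforestation", "", "na")
  expect_equal(lim_rip$growth_share, 1.0)
  expect_equal(lim_rip$post_decade_share, 1.0)
  # complete registry: every (scenario, activity) pair present exactly once
  expect_equal(nrow(d), 3 * nrow(activity_registry()))
  expect_equal(anyDuplicated(d[, c("scenario", "pathway", "sub_activity", "ownership")]), 0L)
})

test_that("scenario overrides replace defaults and unknown keys are rejected", {
  ov <- tibble::tibble(
    scenario = "limited", pathway = "riparian_reforestation",
    sub_activity = "", ownership = "na",
    ramp_fraction = 0.1, growth_share = 0.42, post_decade_share = 1,
    cap_fraction = 1, flux_mode = "stock"
  )
  merged <- scenario_params_with_overrides(ov)
  got <- merged[merged$scenario == "limited" & merged$pathway == "riparian_reforestation", ]
  expect_equal(got$growth_share, 0.42)
  expect_equal(nrow(merged), nrow(scenario_defaults()))

  bad <- ov
  bad$pathway <- "geoengineering"
  expect_error(scenario_params_with_overrides(bad), "registry")
})
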