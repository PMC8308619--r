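test_that("timber net rate is the signed sum of its five components", {
  zero <- c(
    harvest_volume = 0, belowground_biomass = 0, unused_mill_residue = 0,
    commercial_fuel = 0, shortlived_products = 0
  )
  expect_equal(timber_net_rate(zero), 0)

  comp <- c(
    harvest_volume = -2.0, belowground_biomass = -0.4,
    unused_mill_residue = 0.3, commercial_fuel = 0.2,
    shortlived_products = 0.5
  )
  expect_equal(timber_net_rate(comp), -1.4)

  west <- comp
  east <- comp / 2
  expect_false(timber_net_rate(west) == timber_net_rate(east))

  expect_error(timber_net_rate(comp[-3]), "unused_mill_residue")
})

test_that("stock flux accrues on enrolled stock each year", {
  expect_equal(stock_flux(rep(0, 5), -2)$annual_flux, rep(0, 5))

  fs <- stock_flux(c(10, 20, 30), -2)
  expect_equal(fs$annual_flux, c(-20, -40, -60))
  expect_equal(fs$cumulative, c(-20, -60, -120))

  expect_equal(stock_flux(c(10, 20, 30), -4)$annual_flux, 2 * fs$annual_flux)
})

test_that("cohort flux applies age-dependent rates with terminal extension", {
  prof <- tibble::tibble(age = c(1L, 2L), rate = c(-1, -3))
  ledger <- tibble::tibble(year = 1L, amount = 10)
  fs <- cohort_flux(ledger, prof, n_years = 3)
  expect_equal(fs$annual_flux, c(-10, -30, -30))

  # flat profile reduces exactly to stock flux
  flat <- tibble::tibble(age = 1L, rate = -2)
  inc <- c(5, 3, 0, 2)
  enrolled <- cumsum(inc)
  expect_equal(
    cohort_flux(inc, flat, n_years = 4)$annual_flux,
    stock_flux(enrolled, -2)$annual_flux
  )

  expect_error(cohort_flux(ledger, tibble::tibble(age = integer(), rate = double())), "empty")
})

test_that("multi-cohort flux matches a brute-force per-cohort sum", {
  prof <- tibble::tibble(age = 1:6, rate = -(1:6))
  ledger <- tibble::tibble(year = c(1L, 2L), amount = c(10, 5))
  n <- 6
  brute <- numeric(n)
  for (i in seq_len(nrow(ledger))) {
    for (t in ledger$year[i]:n) {
      age <- t - ledger$year[i] + 1
      brute[t] <- brute[t] + ledger$amount[i] * prof$rate[min(age, nrow(prof))]
    }
  }
  expect_equal(cohort_flux(ledger, prof, n_years = n)$annual_flux, brute)
})

test_that("added sequestration is private-only and follows the delta profile", {
  expect_error(
    delayed_harvest_added_sequestration(c(1, 1), tibble::tibble(age = 1L, rate = -1),
      ownership = "state"
    ),
    "private"
  )

  zero <- tibble::tibble(age = 1L, rate = 0)
  expect_equal(
    delayed_harvest_added_sequestration(c(10, 10), zero, n_years = 4)$annual_flux,
    rep(0, 4)
  )

  # enrollment held at 100 from year 1, constant delta -0.5 -> flux -50/yr
  const <- tibble::tibble(age = 1L, rate = -0.5)
  inc <- c(100, rep(0, 9))
  expect_equal(
    delayed_harvest_added_sequestration(inc, const, n_years = 10)$annual_flux,
    rep(-50, 10)
  )

  # per-cohort flux magnitude shrinks as the delta declines with age
  declining <- tibble::tibble(age = 1:5, rate = c(-1, -0.8, -0.6, -0.4, -0.2))
  single <- delayed_harvest_added_sequestration(c(10, rep(0, 7)), declining, n_years = 8)
  expect_true(all(diff(abs(single$annual_flux)) <= 1e-12))
})

test_that("flux is linear in enrollment and rate (random scaling)", {
  set.seed(5)
  for (i in 1:50) {
    enrolled <- cumsum(runif(31, 0, 10))
    rate <- -runif(1, 0.1, 5)
    k <- runif(1, 0.5, 4)
    expect_equal(
      stock_flux(k * enrolled, rate)$annual_flux,
      k * stock_flux(enrolled, rate)$annual_flux,
      tolerance = 1e-12
    )
    expect_equal(
      stock_flux(enrolled, k * rate)$annual_flux,
      k * stock_flux(enrolled, rate)$annual_flux,
      tolerance = 1e-12
    )
  }
})

test_that("cumulative flux is monotone non-increasing under all-negative rates", {
  set.seed(6)
  prof <- tibble::tibble(age = c(1L, 3L, 8L), rate = c(-0.5, -1.5, -2))
  inc <- runif(31, 0, 5)
  fs <- cohort_flux(inc, prof, n_years = 31)
  expect_true(all(diff(fs$cumulative) <= 1e-12))
})

test_that("effective activity dispatches stock, pulse and cohort modes", {
  inc <- c(4, 4, 0)
  enr <- cumsum(inc)
  expect_equal(effective_activity(inc, enr, "stock"), enr)
  expect_equal(effective_activity(inc, enr, "pulse"), inc)
  mult <- tibble::tibble(age = c(1L, 2L), multiplier = c(0.5, 1))
  expect_equal(
    effective_activity(inc, enr, "stock", mult),
    c(0.5 * 4, 4 + 0.5 * 4, 4 + 4)
  )
})
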