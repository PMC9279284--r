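lambda <- PB210_LAMBDA

test_that("excess activity is total minus supported, with equilibrium clamping", {
  prof <- profile_from_excess(c(30, 0, -2) + 0, supported = 20)
  # raw totals: 50, 20, 18 over ra 20
  expect_equal(prof$pb210_total, c(50, 20, 18))
  exc <- excess_pb210(prof)
  expect_equal(exc$excess[1], 30)
  # at and below equilibrium the raw difference (0 and -2) is clamped to the
  # floor (0.1 % of surface excess) and flagged
  floor_val <- 0.001 * 30
  expect_equal(exc$excess[2:3], rep(floor_val, 2))
  expect_equal(exc$clamped, c(FALSE, TRUE, TRUE))
  # missing activity is rejected with the interval index
  prof$ra226[2] <- NA
  expect_error(excess_pb210(prof), "interval\\(s\\): 2")
})

test_that("interval inventory contributions follow the unit arithmetic", {
  # excess 100 Bq kg^-1 = 0.1 Bq g^-1, rho 1 g cm^-3, 2 cm -> 0.2 Bq cm^-2
  prof <- profile_from_excess(c(100, 50, 25, 12.5, 6.25), rho = 1, supported = 10)
  inv <- cumulative_inventory(prof)
  expect_equal(inv$contribution[1], 0.2)
  expect_equal(inv$contribution, (prof$pb210_total - 10) / 500) # (1/1000)*rho*2cm
  # conservation: total inventory = sum of contributions + tail
  expect_equal(inv$total_inventory, sum(inv$contribution) + inv$tail_inventory)
})

test_that("inventories of an exponential profile match the analytic integral", {
  c0 <- 300; rho <- 0.5; thick <- 2
  for (k in c(0.1, 0.25, 0.5)) {
    n <- 30
    m_top <- (seq_len(n) - 1) * rho * thick
    m_bot <- seq_len(n) * rho * thick
    exc <- slab_average_exponential(c0, k, m_top, m_bot)
    prof <- profile_from_excess(exc, rho = rho, thickness = thick)
    inv <- suppressWarnings(cumulative_inventory(prof))
    dat <- inv$datable
    expected <- analytic_inventory_below(c0, k, m_top[dat])
    expect_equal(inv$inventory_top[dat], expected, tolerance = 0.01)
    # the slab-sum tail reproduces the analytic remainder almost exactly
    expect_equal(inv$total_inventory, analytic_inventory_below(c0, k, 0),
                 tolerance = 1e-6)
  }
})

test_that("incomplete profiles error without tail extrapolation", {
  exc <- slab_average_exponential(300, 0.05, 0:9, 1:10)  # far from equilibrium
  prof <- profile_from_excess(exc, rho = 0.5, thickness = 2)
  expect_error(cumulative_inventory(prof, tail = FALSE), "incomplete inventory")
  expect_silent(cumulative_inventory(prof, tail = TRUE))
})

test_that("CRS recovers ages and accumulation on noiseless constant-flux cores", {
  for (r in c(0.1, 0.14, 0.19, 0.24, 0.3)) {
    sim <- make_core(core_scenario(mar = r, noise_cv = 0, seed = 11))
    dated <- suppressWarnings(suppressMessages(crs_date(sim$profile)))
    ok <- !is.na(dated$age) & dated$age <= 150
    expect_equal(dated$age[ok], sim$truth$age[ok], tolerance = 1e-3)
    expect_lt(max(abs(dated$mar[ok] - r) / r), 0.01)
    # surface boundary age is zero
    expect_equal(dated$age_top[1], 0)
    # burial equals mar x OC fraction x unit factor
    expect_equal(dated$oc_burial[ok],
                 dated$mar[ok] * sim$profile$oc_percent[ok] / 100 * 1e4)
  }
})

test_that("CRS age at the half-inventory depth equals one half-life", {
  sim <- make_core(core_scenario(mar = 0.15, noise_cv = 0, seed = 2))
  dated <- suppressWarnings(suppressMessages(crs_date(sim$profile)))
  total <- attr(dated, "total_inventory")
  # log-inventory is linear in age, so interpolation at total/2 is exact
  age_half <- stats::approx(log(dated$inventory_below), dated$age,
                            xout = log(total / 2))$y
  expect_equal(age_half, log(2) / lambda, tolerance = 1e-6)
  expect_equal(log(2) / lambda, 22.3, tolerance = 1e-12)
})

test_that("CRS ages are invariant under rescaling of all activities", {
  sim <- make_core(core_scenario(mar = 0.12, noise_cv = 0.08, seed = 7))
  prof <- sim$profile
  doubled <- core_profile(transform(as.data.frame(prof),
                                    pb210_total = 2 * pb210_total,
                                    ra226 = 2 * ra226),
                          lake_id = "doubled")
  d1 <- suppressWarnings(suppressMessages(crs_date(prof)))
  d2 <- suppressWarnings(suppressMessages(crs_date(doubled)))
  expect_equal(d1$age, d2$age, tolerance = 1e-10)
})

test_that("ages are non-decreasing with depth for both models", {
  for (seed in 1:5) {
    sim <- make_core(core_scenario(mar = 0.15, noise_cv = 0.1, seed = seed))
    d_crs <- suppressWarnings(suppressMessages(crs_date(sim$profile)))
    d_cic <- suppressWarnings(cic_date(sim$profile))
    expect_true(all(diff(d_crs$age[!is.na(d_crs$age)]) > 0))
    expect_true(all(diff(d_cic$age) >= 0))
  }
})

test_that("CIC recovers constructed ages exactly and handles flat profiles", {
  # excess built as C0 e^(-lambda t) for known ages (surface slab = age 0)
  t_true <- c(0, 8, 20, 35, 55, 80, 110)
  prof <- profile_from_excess(200 * exp(-lambda * t_true))
  dated <- suppressWarnings(cic_date(prof))
  expect_equal(dated$age_top, t_true, tolerance = 1e-10)
  # constant excess: every interval has the surface concentration -> age 0
  flat <- profile_from_excess(rep(120, 5))
  d_flat <- suppressWarnings(cic_date(flat))
  expect_equal(d_flat$age, rep(0, 5))
  # inversions are monotonized with a warning
  inverted <- profile_from_excess(c(200, 120, 160, 80, 40, 20, 10))
  expect_warning(d_inv <- cic_date(inverted), "monotonized")
  expect_true(all(diff(d_inv$pb210_excess) <= 0))
})

test_that("CIC and CRS agree on ideal constant-flux cores", {
  sim <- make_core(core_scenario(mar = 0.2, noise_cv = 0, seed = 4))
  d_crs <- suppressWarnings(suppressMessages(crs_date(sim$profile)))
  d_cic <- suppressWarnings(cic_date(sim$profile))
  w <- which(!is.na(d_crs$age) & d_crs$age > 5 & d_crs$age <= 100)
  expect_lt(max(abs(d_cic$age[w] - d_crs$age[w]) / d_crs$age[w]), 0.02)
})

test_that("profile validation enforces the interval invariants", {
  good <- data.frame(top_depth = c(0, 2, 4), thickness = 2,
                     dry_bulk_density = 0.5, pb210_total = c(100, 60, 40),
                     ra226 = 20, oc_percent = 4)
  expect_s3_class(core_profile(good), "core_profile")
  bad_gap <- good; bad_gap$top_depth <- c(0, 3, 6)
  expect_error(core_profile(bad_gap), "contiguous")
  bad_oc <- good; bad_oc$oc_percent[1] <- 150
  expect_error(core_profile(bad_oc), "oc_percent")
  expect_error(crs_date(core_profile(good[1:2, ])), "at least 3")
})
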