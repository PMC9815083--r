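test_that("initial substrate mass converts concentration and volume linearly", {
  expect_equal(initial_substrate_mass(1), 606)
  expect_equal(initial_substrate_mass(0.5), 303)
  expect_equal(initial_substrate_mass(0), 0)
  g <- reactor_geometry(total_volume = 100)
  expect_equal(initial_substrate_mass(2, g), 200)
  expect_equal(initial_substrate_mass(c(1, 2)), c(606, 1212))
  expect_error(initial_substrate_mass(-1), ">= 0")
  expect_error(reactor_geometry(chamber_height = 0), "chamber_height")
})

test_that("total biomass is area x height x density", {
  expect_equal(total_biomass(100, 1, 0.2), 20)
  expect_equal(total_biomass(0, 1, 0.2), 0)
  expect_equal(total_biomass(2 * 100, 1, 0.2), 2 * total_biomass(100, 1, 0.2))
})

test_that("yield coefficient matches its defining ratio", {
  expect_equal(yield_xs(300, 30, 600), 0.45)
  expect_equal(yield_xs(30, 30, 600), 0)
  expect_warning(y <- yield_xs(20, 30, 600), "negative yield")
  expect_lt(y, 0)
  expect_error(yield_xs(300, 30, 0), "positive")
})

test_that("chamber yields recover the generating yield from batch series", {
  # noiseless series: exact recovery through the generator inverse
  ser0 <- simulate_picoliter_batch(s0_mass = 303, yield_true = 0.45,
                                   x0_mass = 3, density = 0.2,
                                   area_noise_cv = 0)
  final <- total_biomass(utils::tail(ser0$area_um2, 1), 1, 0.2)
  truth <- attr(ser0, "truth")
  expect_equal(final, truth$x0_mass + 0.45 * 303, tolerance = 1e-4)
  y0 <- yield_from_series(ser0, s0_mass = 303, density = 0.2,
                          min_initial_cells = 0)
  expect_equal(y0$y_xs, 0.45, tolerance = 0.001)
  # 2% frame noise: recovery within 2% for S0 at and above 0.05% w/v
  for (s0_conc in c(0.5, 1, 2)) {
    ser <- simulate_picoliter_batch(s0_mass = 606 * s0_conc,
                                    yield_true = 0.45, x0_mass = 3,
                                    density = 0.2, area_noise_cv = 0.02,
                                    seed = round(100 * s0_conc))
    y <- yield_from_series(ser, s0_mass = 606 * s0_conc, density = 0.2,
                           min_initial_cells = 0)
    expect_lt(abs(y$y_xs / 0.45 - 1), 0.02)
  }
})

test_that("implausible chambers are flagged excluded rather than dropped", {
  ser <- data.frame(time_min = c(0, 20, 40), area_um2 = c(10, 200, 210))
  y <- yield_from_series(ser, s0_mass = 20, density = 0.2)  # carbon yield > 1
  expect_true(y$excluded)
  expect_gt(y$y_xs, 24.63 / 30.03)
  y2 <- yield_from_series(ser, s0_mass = 2000, density = 0.2,
                          min_initial_cells = 50)            # too few cells
  expect_true(y2$excluded)
})

test_that("uptake and product rates follow the defining ratios", {
  expect_equal(specific_uptake_rate(0.6, 0.5), 1.2)
  expect_equal(specific_uptake_rate(0, 0.5), 0)
  expect_equal(specific_uptake_rate(0.66, 0.44), 1.5)
  expect_error(specific_uptake_rate(0.6, 0), "positive")
  expect_equal(product_rate_from_yield(0.6, 0.01), 0.006)
  expect_equal(product_rate_from_yield(0.6, 0), 0)
  expect_error(product_rate_from_yield(0.6, -1), ">= 0")
})

test_that("the Cmol closure satisfies carbon conservation identically", {
  st <- carbon_balance_close(mu = 0.61, y_xs = 0.5)
  expect_equal(st$y_ps, 1 - 0.5 * 30.03 / 24.63)
  expect_equal(st$y_ps, 0.390, tolerance = 1e-3)
  expect_equal(st$r_p, product_rate_from_yield(st$mu, st$y_px))
  # conservation identity across admissible inputs
  set.seed(4)
  for (i in 1:25) {
    y <- runif(1, 0.05, 0.8)
    mx <- runif(1, 20, 30); ms <- runif(1, 25, 35)
    if (y > mx / ms) next
    st_i <- carbon_balance_close(runif(1, 0.05, 0.7), y, mx, ms)
    expect_equal(st_i$y_ps + st_i$y_xs * ms / mx, 1, tolerance = 1e-12)
    expect_gte(st_i$y_ps, 0)
  }
  # all carbon to biomass: zero product
  st0 <- carbon_balance_close(0.5, 24.63 / 30.03)
  expect_equal(st0$r_p, 0, tolerance = 1e-12)
  expect_equal(st0$y_ps, 0, tolerance = 1e-12)
  expect_error(carbon_balance_close(0.5, 0.9), "balance violated")
})
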