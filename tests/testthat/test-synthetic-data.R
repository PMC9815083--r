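test_that("noiseless saturating generator reproduces ln2/mu_max doubling times", {
  cfg <- quick_cfg(mu_max = 0.66, ks_mean = 4.86e-4, ks_cv = 0, noise_cv = 0,
                   glucose_levels = 10,            # S >> ks: saturation
                   events_per_level = 10L, frame_interval = 1e-6)
  tr <- simulate_mother_machine_tracks(cfg)
  td <- diff(tr$division_time_min)
  expect_equal(td, rep(log(2) / 0.66 * 60, length(td)), tolerance = 1e-4)
})

test_that("noiseless generator at half-saturation doubles in 2 ln2 / mu_max hours", {
  cfg <- quick_cfg(mu_max = 0.66, ks_mean = 4.86e-4, ks_cv = 0, noise_cv = 0,
                   glucose_levels = 4.86e-4,        # S = ks
                   events_per_level = 5L, frame_interval = 1e-6)
  tr <- simulate_mother_machine_tracks(cfg)
  td_h <- diff(tr$division_time_min) / 60
  expect_equal(td_h, rep(2 * log(2) / 0.66, length(td_h)), tolerance = 1e-6)
  expect_equal(td_h[1], 2.1004, tolerance = 1e-4)
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- quick_cfg(seed = 7L)
  expect_identical(simulate_mother_machine_tracks(cfg),
                   simulate_mother_machine_tracks(cfg))
  cfg2 <- quick_cfg(seed = 8L)
  expect_false(identical(simulate_mother_machine_tracks(cfg)$division_time_min,
                         simulate_mother_machine_tracks(cfg2)$division_time_min))
})

test_that("non-positive glucose levels are rejected with a message", {
  expect_error(quick_cfg(glucose_levels = c(1, 0)), "positive")
  expect_error(quick_cfg(glucose_levels = -1), "positive")
})

test_that("division timestamps are quantized to the frame interval", {
  cfg <- quick_cfg(frame_interval = 5, seed = 3L)
  tr <- simulate_mother_machine_tracks(cfg)
  expect_true(all(abs(tr$division_time_min / 5 -
                        round(tr$division_time_min / 5)) < 1e-9))
  expect_true(all(tapply(tr$division_time_min, tr$lineage_id,
                         function(t) !is.unsorted(t, strictly = TRUE))))
})

test_that("consecutive-division artifacts appear at the configured rate", {
  cfg <- quick_cfg(glucose_levels = 1, events_per_level = 200L,
                   artifact_rate = 0.5, seed = 5L)
  tr <- simulate_mother_machine_tracks(cfg)
  td <- diff(tr$division_time_min)
  expect_gt(sum(td <= cfg$frame_interval), 40)   # plenty of 1-frame intervals
})

test_that("rendered phase image of nothing is zero and rendering is linear in density", {
  img0 <- render_phase_image(NULL, image_shape = c(32, 32), noise_sd = 0)
  expect_true(all(img0$opd == 0))
  cl <- cell_spec(2.5, 0.9, density = 0.2, x = 3, y = 3, orientation = 0.4)
  cl2 <- cl; cl2$density <- 2 * cl$density
  i1 <- render_phase_image(cl, image_shape = c(140, 140), noise_sd = 0)
  i2 <- render_phase_image(cl2, image_shape = c(140, 140), noise_sd = 0)
  expect_equal(i2$opd, 2 * i1$opd, tolerance = 1e-12)
})

test_that("integrated OPD of a rendered sphere matches the analytic volume integral", {
  rho <- 1.053; alpha <- 0.244
  bead <- cell_spec(1, 1, density = rho, refraction_increment = alpha,
                    x = 1.5, y = 1.5)
  img <- render_phase_image(bead, image_shape = c(68, 68), noise_sd = 0)
  integral <- sum(img$opd) * img$pixel_size^2
  expect_equal(integral, rho * alpha * 4 / 3 * pi * 0.5^3, tolerance = 0.01)
})

test_that("objects outside the image bounds are reported by index", {
  cells <- cell_spec(length = c(2, 2), width = c(1, 1), density = 0.2,
                     x = c(3, 5.9), y = c(3, 3))
  expect_error(render_phase_image(cells, image_shape = c(132, 132)),
               "object 2")
})

test_that("picoliter batch with no inoculum stays flat", {
  ser <- simulate_picoliter_batch(s0_mass = 100, x0_mass = 0, t_max = 200,
                                  area_noise_cv = 0)
  expect_true(all(ser$area_um2 == 0))
  expect_true(all(ser$substrate_pg == 100))
})

test_that("picoliter batch run to exhaustion obeys the closed-form mass balance", {
  ser <- simulate_picoliter_batch(s0_mass = 606, yield_true = 0.45,
                                  x0_mass = 6, area_noise_cv = 0)
  final_mass <- utils::tail(ser$area_um2, 1) * 0.2 * 1   # density x height
  expect_equal(final_mass, 6 + 0.45 * 606, tolerance = 1e-4)
  expect_equal(final_mass, 278.7, tolerance = 1e-3)
  expect_lt(utils::tail(ser$substrate_pg, 1), 1e-5 * 606)
})

test_that("picoliter batch rejects non-positive yields and is seed-reproducible", {
  expect_error(simulate_picoliter_batch(100, yield_true = 0), "yield_true")
  a <- simulate_picoliter_batch(303, seed = 9L)
  b <- simulate_picoliter_batch(303, seed = 9L)
  expect_identical(a, b)
})
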