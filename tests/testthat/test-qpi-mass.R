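phase_img <- function(opd, px = 0.045) {
  structure(list(opd = opd, pixel_size = px), class = "phase_image")
}

test_that("background subtraction removes a scalar offset", {
  img <- phase_img(matrix(3.2, 20, 20))
  expect_true(all(subtract_background(img)$opd == 0))
  expect_true(all(subtract_background(img, 50)$opd == 0))
  img0 <- phase_img(matrix(0, 5, 5))
  expect_identical(subtract_background(img0)$opd, img0$opd)
  expect_error(subtract_background(img, 60), "\\[0, 50\\]")
})

test_that("offset rendered image is restored to the generator truth", {
  cl <- cell_spec(2.5, 0.9, density = 0.2, x = 3, y = 3, orientation = 0.4)
  img <- render_phase_image(cl, image_shape = c(140, 140), noise_sd = 0)
  shifted <- phase_img(img$opd + 0.7, img$pixel_size)
  expect_equal(subtract_background(shifted)$opd, img$opd, tolerance = 1e-12)
})

test_that("threshold segmentation counts disjoint objects and filters specks", {
  cells <- cell_spec(length = c(2.5, 3), width = c(0.9, 1), density = 0.2,
                     x = c(3, 8), y = c(3, 8), orientation = c(0.3, 1.5))
  img <- render_phase_image(cells, image_shape = c(250, 250), noise_sd = 0)
  lab <- segment_objects(img, threshold = 0.005, min_area_px = 10)
  expect_identical(max(lab), 2L)
  # a 1-px speck is removed by the minimum-area rule
  speck <- img$opd; speck[200, 200] <- 1
  lab2 <- segment_objects(phase_img(speck), 0.005, min_area_px = 10)
  expect_identical(max(lab2), 2L)
  # threshold above the maximum leaves nothing
  expect_identical(max(segment_objects(img, threshold = 1)), 0L)
})

test_that("dry-mass integration matches hand arithmetic and is linear", {
  img <- phase_img(matrix(0.1, 10, 10))
  expect_equal(integrate_dry_mass(img, refraction_increment = 0.18),
               0.1 * 100 * 0.045^2 / 0.18)
  expect_equal(integrate_dry_mass(img, refraction_increment = 0.18), 0.1125)
  expect_equal(integrate_dry_mass(phase_img(matrix(0, 10, 10))), 0)
  img2 <- phase_img(2 * img$opd)
  expect_equal(integrate_dry_mass(img2), 2 * integrate_dry_mass(img))
  # additive over disjoint masks
  m1 <- matrix(FALSE, 10, 10); m1[1:5, ] <- TRUE
  m2 <- !m1
  expect_equal(integrate_dry_mass(img, m1) + integrate_dry_mass(img, m2),
               integrate_dry_mass(img))
  expect_warning(got <- integrate_dry_mass(img, matrix(FALSE, 10, 10)),
                 "empty mask")
  expect_identical(got, 0)
})

test_that("mass of a rendered spherocylinder equals density times analytic volume", {
  rho <- 0.2
  cl <- cell_spec(3, 1, rho, x = 5, y = 5, orientation = 0.7)
  img <- render_phase_image(cl, image_shape = c(222, 222), noise_sd = 0)
  m <- integrate_dry_mass(img, refraction_increment = 0.18)
  expect_equal(m, rho * spherocylinder_volume(3, 1), tolerance = 0.02)
})

test_that("spherocylinder volume has the closed form and scales cubically", {
  expect_equal(spherocylinder_volume(1, 1), pi / 6)
  expect_equal(spherocylinder_volume(3, 1),
               pi * 0.25 * 2 + 4 / 3 * pi * 0.125)
  expect_equal(spherocylinder_volume(3, 1), 2.0944, tolerance = 1e-4)
  expect_equal(spherocylinder_volume(6, 2), 8 * spherocylinder_volume(3, 1))
  expect_error(spherocylinder_volume(0.5, 1), "length >= width")
})

test_that("dry-mass density is mass over volume with guarded inputs", {
  expect_equal(dry_mass_density(0.3, 1.5), 0.2)
  expect_equal(dry_mass_density(0, 2), 0)
  expect_error(dry_mass_density(1, 0), "positive")
})

test_that("pipeline recovers generator densities across the observed envelope", {
  for (rho in c(0.13, 0.2, 0.28)) {
    cl <- cell_spec(3, 1, rho, x = 5, y = 5, orientation = 0.9)
    img <- render_phase_image(cl, image_shape = c(222, 222),
                              noise_sd = 0.001, seed = round(rho * 1000))
    rec <- measure_cells(img)
    expect_identical(nrow(rec), 1L)
    expect_lt(abs(rec$density_pg_um3 / rho - 1), 0.05)
    expect_lt(abs(rec$length_um - 3), 0.1)
    expect_lt(abs(rec$width_um - 1), 0.05)
  }
})

test_that("density time course flags drifting cells and reports noise-level CV", {
  # constant density
  rec <- data.frame(cell_id = 1, t_min = seq(0, 300, by = 5),
                    density_pg_um3 = 0.2)
  tc <- density_timecourse(rec)
  expect_equal(tc$cv, 0)
  expect_false(tc$flagged)
  # 3% multiplicative measurement noise
  set.seed(1)
  n <- 400
  rec2 <- data.frame(cell_id = rep(1:4, each = n / 4),
                     t_min = rep(seq_len(n / 4), 4),
                     density_pg_um3 = 0.2 * rlnorm(n, 0, sqrt(log(1 + 0.03^2))))
  tc2 <- density_timecourse(rec2)
  expect_equal(mean(tc2$cv), 0.03, tolerance = 0.2)
  expect_true(all(!tc2$flagged))
  expect_error(density_timecourse(rec2[1, ]), ">= 2 time points")
})
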