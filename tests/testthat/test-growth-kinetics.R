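test_that("doubling times drop the first interval and down-weight frame-level events", {
  td <- doubling_times(c(0, 60, 120, 180), frame_interval = 5)
  expect_equal(td$td_min, c(60, 60))
  expect_equal(td$weight, c(1, 1))
  td2 <- doubling_times(c(0, 60, 65, 125), frame_interval = 5)
  expect_equal(td2$td_min, c(5, 60))
  expect_equal(td2$weight, c(0, 1))
  expect_identical(nrow(doubling_times(c(0), 5)), 0L)
  expect_identical(nrow(doubling_times(c(0, 60), 5)), 0L)
  expect_error(doubling_times(c(0, 60, 60), 5), "strictly increasing")
})

test_that("growth classification follows the event- and generation-count rules", {
  one_valid <- make_track(seq(0, by = 60, length.out = 55))
  expect_identical(classify_growth(one_valid), "valid")
  pooled <- rbind(make_track(seq(0, by = 60, length.out = 4), lineage = "A")[1:4, ],
                  make_track(seq(0, by = 60, length.out = 4), lineage = "B")[1:4, ],
                  make_track(seq(0, by = 60, length.out = 4), lineage = "C")[1:4, ])
  pooled$generation <- c(1, 2, 2, 2, 1, 2, 2, 2, 1, 1, 1, 1)  # gens 2 + 2 + 1 = 5
  expect_identical(classify_growth(pooled), "pooled")
  none <- rbind(make_track(c(0, 60), lineage = "A"),
                make_track(c(0, 60), lineage = "B"))
  none$generation <- c(1, 2, 1, 1)   # total generations 3
  expect_identical(classify_growth(none), "no_growth")
  expect_identical(classify_growth(NULL), "no_growth")
  # order-independence over lineages
  expect_identical(classify_growth(pooled[sample(nrow(pooled)), ]), "pooled")
})

test_that("geometric-mean rate matches hand values and honors zero weights", {
  gm <- geometric_mean_mu(c(120, 480))
  expect_equal(gm$td_gm_min, 240)
  expect_equal(gm$mu_gm, log(2) / 4)
  expect_equal(gm$mu_gm, 0.1733, tolerance = 1e-3)
  same <- geometric_mean_mu(rep(log(2) * 60, 5))
  expect_equal(same$mu_gm, 1)
  expect_equal(same$mu_sd, 0)
  # a weight-0 outlier changes nothing vs excluding it
  with_out <- geometric_mean_mu(c(5, 60, 60, 62), c(0, 1, 1, 1))
  without <- geometric_mean_mu(c(60, 60, 62), c(1, 1, 1))
  expect_equal(with_out$mu_gm, without$mu_gm)
  expect_equal(with_out$mu_sd, without$mu_sd)
  expect_error(geometric_mean_mu(c(5, 5), c(0, 0)), "no admissible")
})

test_that("geometric mean never exceeds the arithmetic mean of doubling times", {
  set.seed(11)
  for (i in 1:20) {
    td <- rlnorm(30, log(60), 0.5)
    gm <- geometric_mean_mu(td)
    expect_lte(gm$td_gm_min, mean(td) + 1e-12)
  }
})

test_that("the Monod curve has its textbook landmarks and monotonicity", {
  expect_equal(monod_mu(0, 0.66, 4.86e-4), 0)
  expect_equal(monod_mu(4.86e-4, 0.66, 4.86e-4), 0.33)
  expect_equal(monod_mu(1, 0.66, 4.86e-4), 0.6597, tolerance = 1e-4)
  S <- 10^seq(-6, 2, length.out = 50)
  mu <- monod_mu(S, 0.66, 4.86e-4)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu < 0.66))
  expect_equal(monod_mu(1e6, 0.66, 4.86e-4), 0.66, tolerance = 1e-6)
})

test_that("noiseless Monod points are recovered exactly by the fit", {
  pts <- monod_points(0.66, 4.86e-4)
  fit <- fit_monod(pts)
  expect_equal(unname(coef(fit)["mean", "mu_max"]), 0.66, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["mean", "ks"]), 4.86e-4, tolerance = 1e-5)
  expect_equal(unname(fit$r2["mean"]), 1, tolerance = 1e-9)
  # boundary variants collapse onto the mean when mu_sd = 0
  expect_equal(coef(fit)["upper_boundary", ], coef(fit)["mean", ],
               tolerance = 1e-6)
})

test_that("degenerate fits are rejected and saturation is flagged", {
  flat <- data.frame(glucose_g_per_L = c(1e-4, 1e-3, 1e-2, 1), mu_gm = 0)
  expect_error(fit_monod(flat), "zero")
  expect_error(fit_monod(monod_points(0.66, 4.86e-4)[1:3, ]), "at least 4")
  sat_S <- c(0.5, 1, 2, 5, 10)
  sat <- data.frame(glucose_g_per_L = sat_S,
                    mu_gm = monod_mu(sat_S, 0.66, 1e-6), mu_sd = 0)
  w <- capture_warnings(fit_monod(sat))   # warns once per fitted variant
  expect_match(w, "poorly identified", all = TRUE)
})

test_that("boundary fits bracket the mean fit on heterogeneous data", {
  pts <- monod_points(0.66, 4.86e-4, mu_sd = 0.2)
  fit <- fit_monod(pts)
  co <- coef(fit)
  expect_gt(co["upper_boundary", "mu_max"], co["mean", "mu_max"])
  expect_lt(co["lower_boundary", "mu_max"], co["mean", "mu_max"])
  # predictions and residuals are consistent
  expect_equal(predict(fit), pts$mu_gm, tolerance = 1e-6)
  expect_equal(residuals(fit), rep(0, nrow(pts)), tolerance = 1e-6)
})

test_that("fit bias shrinks as events per level grow", {
  err <- vapply(c(10L, 50L, 200L), function(n) {
    errs <- vapply(1:4, function(s) {
      cfg <- generator_config(events_per_level = n, n_lineages = 1L,
                              artifact_rate = 0, seed = 100L + s)
      pts <- growth_points(simulate_mother_machine_tracks(cfg))
      co <- coef(fit_monod(pts))
      abs(co["mean", "mu_max"] / 0.66 - 1)
    }, 1)
    mean(errs)
  }, 1)
  expect_lt(err[3], err[1])
})

test_that("per-cell affinity inversion has its identities and limits", {
  mu_max <- 0.66
  s <- 2e-4
  # cells growing at exactly mu_max/2 invert to ks = S
  td <- log(2) / (mu_max / 2) * 60
  tr <- make_track(cumsum(rep(td, 12)), glucose = s)
  kd <- ks_distribution(tr, mu_max, frame_interval = 1e-6)
  expect_equal(kd$values, rep(s, length(kd$values)), tolerance = 1e-9)
  expect_equal(kd$mean, s, tolerance = 1e-9)
  # cells at mu_max invert to ks ~ 0 and faster cells are skipped
  td_fast <- log(2) / mu_max * 60
  tr2 <- make_track(cumsum(rep(c(td_fast, td_fast * 0.5), 6)), glucose = s)
  kd2 <- ks_distribution(tr2, mu_max * 1.0000001, frame_interval = 1e-6)
  expect_equal(max(kd2$values), 0, tolerance = 1e-4)
  tr3 <- make_track(cumsum(rep(td_fast * 0.5, 10)), glucose = s)
  expect_error(ks_distribution(tr3, mu_max, frame_interval = 1e-6),
               "fewer than 2")
})

test_that("affinity distribution of generated cells recovers the generating mean", {
  cfg <- generator_config(ks_cv = 234 / 486, noise_cv = 0,
                          glucose_levels = 4.86e-4, events_per_level = 250L,
                          n_lineages = 1L, artifact_rate = 0,
                          frame_interval = 1e-4, seed = 21L)
  tr <- simulate_mother_machine_tracks(cfg)
  kd <- ks_distribution(tr, mu_max = 0.66, frame_interval = 1e-4)
  # truncation at zero shifts the mean up by ~11 ug/L; allow 3 SE on top
  expect_lt(abs(kd$mean - 4.86e-4), 0.6e-4)
  expect_equal(kd$sd, 2.34e-4, tolerance = 0.25)
  expect_identical(sum(kd$histogram$counts), length(kd$values))
})
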