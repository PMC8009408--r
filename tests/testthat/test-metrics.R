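test_that("ring detection handles flat, single-bump and double-bump
           profiles", {
  d <- seq(0, 1, length.out = 501)
  # constant profile: no rings, no core
  ps0 <- detect_rings(d, rep(2, 501))
  expect_identical(ps0$ring_count, 0L)
  expect_false(ps0$has_core)

  # isolated Gaussian bump: one ring, FWHP = 2.355 sd on a zero baseline
  sd <- 0.05
  ps1 <- detect_rings(d, exp(-((d - 0.4)^2) / (2 * sd^2)))
  expect_identical(ps1$ring_count, 1L)
  expect_equal(ps1$rings$peak_d, 0.4, tolerance = 2 * (d[2] - d[1]))
  expect_equal(ps1$rings$width, 2.3548 * sd, tolerance = 0.005)
  expect_false(ps1$has_core)

  # two separated bumps: two rings at the two centers
  prof2 <- exp(-((d - 0.25)^2) / (2 * 0.04^2)) +
    0.6 * exp(-((d - 0.65)^2) / (2 * 0.04^2))
  ps2 <- detect_rings(d, prof2)
  expect_identical(ps2$ring_count, 2L)
  expect_equal(ps2$rings$peak_d, c(0.25, 0.65), tolerance = 0.01)

  # a center-supported plateau is a core, not a ring
  prof3 <- exp(-((d - 1)^2) / (2 * 0.12^2)) +
    0.8 * exp(-((d - 0.2)^2) / (2 * 0.04^2))
  ps3 <- detect_rings(d, prof3)
  expect_true(ps3$has_core)
  expect_identical(ps3$ring_count, 1L)

  expect_error(detect_rings(numeric(0), numeric(0)), "3 points")
})

test_that("ring detection is invariant to amplitude rescaling and stable
           under grid refinement", {
  d1 <- seq(0, 1, length.out = 201)
  d2 <- seq(0, 1, length.out = 401)
  f <- function(d) exp(-((d - 0.3)^2) / (2 * 0.05^2)) +
    0.5 * exp(-((d - 0.7)^2) / (2 * 0.06^2))
  a <- detect_rings(d1, f(d1))
  b <- detect_rings(d1, 1e4 * f(d1))
  expect_identical(a$ring_count, b$ring_count)
  expect_equal(a$rings$peak_d, b$rings$peak_d)
  fine <- detect_rings(d2, f(d2))
  expect_identical(fine$ring_count, a$ring_count)
})

test_that("OLS fits on exact linear sweep data recover slopes with R^2 = 1
           and reject underdetermined input", {
  df <- data.frame(domain_radius = c(1, 1.5, 2, 2.5, 3, 3.5, 4))
  df$final_R <- 0.9 * df$domain_radius
  df$ring_width <- 0.3 * df$domain_radius
  fits <- scale_fits(df, moderate_frac = 1)
  expect_equal(fits$radius_fit$slope, 0.9, tolerance = 1e-12)
  expect_equal(fits$width_fit$slope, 0.3, tolerance = 1e-12)
  expect_equal(fits$radius_fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fits$width_fit$r_squared, 1, tolerance = 1e-12)
  # the default moderate sub-range drops the extremes
  fits60 <- scale_fits(df, moderate_frac = 0.6)
  expect_lt(fits60$radius_fit$n, nrow(df))
  expect_error(scale_fits(df[1, ]), "3 points")
  expect_error(scale_invariance_sweep(run_config(preset = "fig4_low_burden"),
                                      domain_radii = 2),
               "at least 3")
})

test_that("emergence ordering reads constructed kymographs correctly", {
  d <- seq(0, 1, length.out = 101)
  tms <- as.numeric(0:4)
  vals <- matrix(0, length(tms), length(d))
  # ring appears near the edge at t = 1, core at the center from t = 2
  ring <- exp(-((d - 0.08)^2) / (2 * 0.03^2))
  core <- exp(-((d - 1)^2) / (2 * 0.15^2))
  vals[2, ] <- ring
  vals[3, ] <- ring + core
  vals[4, ] <- ring + core
  vals[5, ] <- ring + core
  kym <- list(t = tms, d = d, R = rep(1, length(tms)), values = vals)
  eo <- emergence_order(kym, min_R_frac = 0)
  expect_identical(eo$order, "ring_first")
  expect_identical(eo$ring_time, 1)
  expect_identical(eo$core_time, 2)
  # absent features are reported, not errors
  eo2 <- emergence_order(list(t = tms, d = d, R = rep(1, 5),
                              values = matrix(0, 5, length(d))),
                         min_R_frac = 0)
  expect_identical(eo2$order, "none")
})
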