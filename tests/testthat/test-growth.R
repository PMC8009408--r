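test_that("division rate saturates, vanishes without nutrient, and halves at
           both half-saturation points", {
  p <- growth_params(sigma0 = 2, n_star = 0.5, K_sigma = 0.2, n_sigma = 3)
  # edge position, nutrient-saturated limit: both Hill factors -> 1
  expect_equal(division_rate(1, R = 1, n = 1e9, p), p$sigma0,
               tolerance = 1e-8)
  # no nutrient, no division
  expect_identical(division_rate(0.5, R = 1, n = 0, p), 0)
  # n = n* and R - x = K_sigma: each factor = 1/2
  expect_equal(division_rate(1 - p$K_sigma, R = 1, n = p$n_star, p),
               p$sigma0 / 4, tolerance = 1e-12)
  # domain errors
  expect_error(division_rate(1.5, R = 1, n = 1, p), "\\[0, R\\]")
  expect_error(division_rate(-0.1, R = 1, n = 1, p), "\\[0, R\\]")
  expect_error(division_rate(0.5, R = 1, n = -1, p), "non-negative")
})

test_that("growth integral matches the closed form in the uniform limit and
           a brute-force Riemann sum in the generic case", {
  # K_sigma = Inf: sigma uniform, integral = sigma * r^2 / 2
  p_inf <- growth_params(K_sigma = Inf)
  sig <- p_inf$sigma0 * 1 / (1 + p_inf$n_star)
  expect_equal(growth_integral(0.7, R = 1, n = 1, p_inf), sig * 0.7^2 / 2,
               tolerance = 1e-9)
  expect_identical(growth_integral(0, R = 1, n = 1, p_inf), 0)

  # generic parameters vs midpoint Riemann sum with 1e6 panels
  p <- growth_params(sigma0 = 1.3, n_star = 0.4, K_sigma = 0.25,
                     n_sigma = 5)
  r_up <- 0.83; R <- 1.1; n <- 0.7
  mids <- (seq_len(1e6) - 0.5) * (r_up / 1e6)
  riemann <- sum(mids * division_rate(mids, R, n, p)) * (r_up / 1e6)
  expect_equal(growth_integral(r_up, R, n, p), riemann, tolerance = 1e-6)

  expect_error(growth_integral(2, R = 1, n = 1, p), "\\[0, R\\]")
})

test_that("growth RHS respects arrest, front attachment, and the nutrient-
           radius conservation structure", {
  p <- growth_params(sigma0 = 1.2, n_star = 0.3, K_sigma = 0.3, n_sigma = 4,
                     v = 0.8, sigma_n_tilde = 1.7)
  # nutrient exhausted: every derivative vanishes
  d0 <- growth_rhs(colony_state(R = 1, n = 0, r = c(0, 0.4, 1)), p)
  expect_true(all(unlist(d0) == 0))
  # a marker exactly at R moves with the front; r = 0 marker stays put
  d1 <- growth_rhs(colony_state(R = 0.9, n = 0.6, r = c(0, 0.5, 0.9)), p)
  expect_equal(d1$r_dot[3], d1$R_dot, tolerance = 1e-12)
  expect_identical(d1$r_dot[1], 0)
  # structure: n_dot / R_dot = -(sigma_n_tilde / v) * R at any state
  for (R in c(0.3, 0.8, 1.4)) {
    d <- growth_rhs(colony_state(R = R, n = 0.5, r = c(0.1, 0.2)), p)
    expect_equal(d$n_dot / d$R_dot, -(p$sigma_n_tilde / p$v) * R,
                 tolerance = 1e-9)
  }
})

test_that("uniform-growth no-consumption limit reproduces the exponential
           closed form", {
  p <- growth_params(sigma0 = 1.5, n_star = 0.5, K_sigma = Inf,
                     sigma_n_tilde = 0)
  r0 <- c(0.02, 0.06, 0.1)
  sim <- integrate_growth(colony_state(R = 0.1, n = 1, r = r0), p,
                          t_end = 3, n_out = 31)
  rate <- p$v * p$sigma0 * (1 / (1 + p$n_star)) / 2
  for (j in seq_along(r0)) {
    exact <- r0[j] * exp(rate * sim$times)
    expect_equal(sim$r[, j], exact, tolerance = 1e-7)
  }
  expect_equal(sim$R, 0.1 * exp(rate * sim$times), tolerance = 1e-7)
})

test_that("growth trajectories are monotone, non-crossing, and settle as the
           nutrient declines", {
  p <- growth_params()
  sim <- integrate_growth(colony_state(R = 0.1, n = 1), p, t_end = 60,
                          n_out = 201)
  expect_true(sim$exhausted)
  expect_true(all(diff(sim$R) >= -1e-12))
  expect_true(all(diff(sim$n) <= 1e-12))
  expect_true(all(apply(sim$r, 2, function(x) all(diff(x) >= -1e-12))))
  # non-crossing: ordering of tracked radii is preserved at every time
  expect_true(all(apply(sim$r, 1, function(x) !is.unsorted(x))))
  # saturation: late-time marker velocities vanish with the nutrient
  last <- colony_state(R = sim$R[length(sim$R)], n = sim$n[length(sim$n)],
                       r = sim$r[nrow(sim$r), ],
                       t = sim$times[length(sim$times)])
  d_late <- growth_rhs(last, p)
  expect_lt(max(abs(d_late$r_dot)), 1e-3)
  expect_lt(d_late$R_dot, 1e-3)
})

test_that("marker trajectories do not depend on how many other markers are
           tracked", {
  p <- growth_params()
  shared <- seq(0.01, 0.1, length.out = 10)
  extra <- sort(c(shared, seq(0.011, 0.099, length.out = 90)))
  s10 <- integrate_growth(colony_state(R = 0.12, n = 1, r = shared), p,
                          t_end = 20, n_out = 41)
  s100 <- integrate_growth(colony_state(R = 0.12, n = 1, r = extra), p,
                           t_end = 20, n_out = 41)
  cols <- match(shared, extra)
  rel <- abs(s100$r[, cols] - s10$r) / pmax(abs(s10$r), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("parameter validation rejects non-physical values", {
  expect_error(growth_params(sigma0 = -1), "sigma0")
  expect_error(growth_params(n_sigma = 0.5), "n_sigma")
  expect_error(growth_params(sigma_n_tilde = -0.1), "sigma_n_tilde")
  expect_error(colony_state(R = 1, n = 1, r = c(0.5, 0.2)), "increasing")
  expect_error(colony_state(R = 1, n = 1, r = c(0.5, 1.2)), "\\[0, R\\]")
})
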