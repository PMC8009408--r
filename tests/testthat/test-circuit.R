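test_that("expression capacity is maximal at the edge, halves at K_phi, and
           is lower in the interior under the sharp profile", {
  cp <- circuit_params()
  expect_identical(expression_capacity(0, cp), 1)
  expect_equal(expression_capacity(cp$K_phi, cp), 0.5, tolerance = 1e-12)
  expect_true(all(diff(expression_capacity(seq(0, 1, 0.05), cp)) < 0))
  # sharp (fig3) vs flat (fig4) capacity at a matched interior distance
  sharp <- load_config("fig3_high_burden_sharp")$circuit
  flat <- load_config("fig4_low_burden")$circuit
  d <- 0.3
  expect_lt(expression_capacity(d, sharp), expression_capacity(d, flat))
  expect_error(expression_capacity(-0.1, cp), "non-negative")
})

test_that("burden factor is 1 without burden or load and halves at unit
           scaled load", {
  expect_identical(burden_factor(3, 5, circuit_params(b = 0)), 1)
  expect_identical(burden_factor(0, 0, circuit_params(b = 2)), 1)
  cp1 <- circuit_params(b = 0.25, h_b = 1)
  expect_equal(burden_factor(2, 2, cp1), 0.5, tolerance = 1e-12) # b(T+L)=1
  # strictly decreasing in total load for b > 0
  cp <- circuit_params(b = 0.5)
  loads <- burden_factor(seq(0, 4, 0.5), 0, cp)
  expect_true(all(diff(loads) < 0))
})

test_that("the trivial fixed point is inert and the AHL synthesis term
           scales with the inverse domain area", {
  cp <- circuit_params(A0 = 0)
  p <- growth_params()
  col <- colony_state(R = 0.4, n = 1, r = c(0, 0.2, 0.399))
  z <- circuit_state(T7 = c(0, 0, 0))
  d <- circuit_rhs(z, col, cp, p)
  expect_true(all(abs(unlist(d)) == 0))

  # nonzero T7: doubling R_domain cuts the AHL synthesis rate 4-fold
  st <- circuit_state(T7 = c(1, 2, 3))
  d1 <- circuit_rhs(st, col, cp, p)
  cp2 <- do.call(circuit_params,
                 utils::modifyList(unclass(cp), list(R_domain = 2)))
  d2 <- circuit_rhs(st, col, cp2, p)
  expect_equal(d1$dA / d2$dA, 4, tolerance = 1e-9)
})

test_that("complex inhibition and AHL thresholding act in the stated
           directions", {
  # increasing P at fixed T strictly decreases T7 synthesis (k_off = 0
  # isolates the transcriptional arm from complex unbinding)
  cp <- circuit_params(k_off = 0)
  p <- growth_params()
  col <- colony_state(R = 0.2, n = 1, r = c(0.1, 0.19))
  dP0 <- circuit_rhs(circuit_state(T7 = c(1, 1)), col, cp, p)$dT7
  stP <- circuit_state(T7 = c(1, 1), P = c(2, 2))
  dP2 <- circuit_rhs(stP, col, cp, p)$dT7
  expect_true(all(dP2 < dP0))
  cp <- circuit_params()
  # lysozyme synthesis: negligible below K_A, near-maximal above
  lowA <- circuit_state(T7 = c(0, 0), A = 0.5 * cp$K_A)
  hiA <- circuit_state(T7 = c(0, 0), A = 2 * cp$K_A)
  dl <- circuit_rhs(lowA, col, cp, p)$dL
  dh <- circuit_rhs(hiA, col, cp, p)$dL
  nfac <- 1 / (1 + p$n_star)
  cap <- expression_capacity(col$R - col$r, cp) * cp$alpha_L * nfac
  expect_lt(max(dl / cap), 0.01)
  expect_gt(min(dh / cap), 0.9)
})

test_that("with zero burden the growth layer is exactly decoupled from the
           circuit", {
  cfg <- run_config(preset = "fig4_low_burden")
  cfg <- modify_config(cfg, circuit = list(b = 0))
  sim <- simulate_pattern(cfg)
  # growth-only reference on the same marker start (spawning off for a
  # like-for-like ODE system)
  cfg_off <- cfg
  cfg_off$spawn <- spawn_policy(enabled = FALSE)
  sim_c <- simulate_pattern(cfg_off)
  r0 <- seq(0, cfg$init$R0, length.out = cfg$init$n_markers)
  r0[length(r0)] <- cfg$init$R0 * (1 - cfg$spawn$delta)
  ref <- integrate_growth(colony_state(R = cfg$init$R0, n = cfg$init$n0,
                                       r = r0),
                          cfg$growth, t_end = cfg$solver$t_end,
                          n_out = 201, rtol = 1e-10, atol = 1e-12,
                          n_floor_frac = 0)
  # nutrient consumption in coupled runs is scaled by the domain area; at
  # R_domain = 1 the two models solve the same equations
  tt <- sim_c$times[sim_c$times <= min(max(ref$times), max(sim_c$times))]
  R_ref <- stats::approx(ref$times, ref$R, xout = tt)$y
  R_cpl <- stats::approx(sim_c$times, sim_c$R, xout = tt)$y
  expect_lt(max(abs(R_cpl - R_ref) / R_ref), 2e-4)

  # and burden only ever shrinks the colony
  sim_b <- simulate_pattern(modify_config(cfg, circuit = list(b = 0.3)))
  expect_lte(sim_b$final$R, sim$final$R + 1e-6)
})

test_that("the isolated circuit pulse is unimodal in T7 with monotone
           lysozyme under sustained AHL", {
  tr <- circuit_phase_plane(circuit_params(), A = 1, t_end = 25,
                            T0 = 0.1, L0 = 0)
  pk <- which.max(tr$T7)
  expect_gt(pk, 1)
  expect_lt(pk, nrow(tr))
  expect_true(all(diff(tr$T7[1:pk]) >= -1e-8))
  expect_true(all(diff(tr$T7[pk:nrow(tr)]) <= 1e-6))
  expect_true(all(diff(tr$L) >= -1e-9))
})

test_that("concentrations remain non-negative along a coupled run", {
  sim <- simulate_pattern(run_config(preset = "fig3d_ahl08"))
  expect_gte(min(sim$T7, na.rm = TRUE), 0)
  expect_gte(min(sim$L, na.rm = TRUE), 0)
  expect_gte(min(sim$P, na.rm = TRUE), 0)
  expect_gte(min(sim$A), 0)
  expect_gte(min(sim$n), 0)
})
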