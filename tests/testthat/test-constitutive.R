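test_that("active strain rate follows the linearized Hill relation", {
  p <- material_params(E_s = 500, eta_a = 2000, sigma_max = 6, E_p = 50,
                       eta_p = 1e5, sigma_Y_t = 1, sigma_Y_c = 1)
  expect_equal(active_strain_rate(6, p), 0)           # stall
  expect_equal(active_strain_rate(10, p), 0.002)      # lengthening
  expect_equal(active_strain_rate(0, p), -0.003)      # contractile shortening
  # strictly increasing with slope 1/eta_a
  expect_equal(active_strain_rate(7, p) - active_strain_rate(6, p), 1 / 2000)
  bad <- p; bad$eta_a <- -1
  expect_error(active_strain_rate(6, bad), "eta_a")
})

test_that("plastic strain rate is the continuous Bingham overstress rule", {
  p <- material_params(E_s = 1, eta_a = 1, sigma_max = 0, E_p = 50,
                       eta_p = 600, sigma_Y_t = 2, sigma_Y_c = 2)
  expect_equal(plastic_strain_rate(1, p), 0)          # inside yield range
  expect_equal(plastic_strain_rate(5, p), 0.005)
  expect_equal(plastic_strain_rate(-5, p), -0.005)
  # stress exactly at yield counts as elastic, and the rule is continuous
  expect_equal(plastic_strain_rate(2, p), 0)
  expect_equal(plastic_strain_rate(-2, p), 0)
  eps <- 1e-9
  expect_lt(plastic_strain_rate(2 + eps, p), 1e-11)
  bad <- p; bad$eta_p <- 0
  expect_error(plastic_strain_rate(1, bad), "eta_p")
})

test_that("equilibrium state carries stall stress and stays stationary", {
  # control-like baseline: whole baseline carried by the cell branch
  p <- material_params(E_s = 500, eta_a = 2e4, sigma_max = 6.66, E_p = 50,
                       eta_p = 1e5, sigma_Y_t = 1, sigma_Y_c = 1)
  st <- equilibrium_state(p, baseline_stress = 6.66)
  expect_equal(st$sigma_a, 6.66)
  expect_equal(st$sigma_p, 0)
  expect_equal(st$eps_total, 0)

  # matrix-only baseline (cell-lysed tissue)
  pe <- material_params(E_p = 50, eta_p = 1e5, sigma_Y_t = 2, sigma_Y_c = 2,
                        variant = "ecm_only")
  ste <- equilibrium_state(pe, baseline_stress = 1.56)
  expect_equal(ste$sigma_p, 1.56)
  expect_equal(ste$sigma_a, 0)

  # baseline partition outside the yield range is rejected
  expect_error(equilibrium_state(pe, baseline_stress = 2.5),
               "inconsistent baseline")

  # stationarity: frozen strain leaves the state unchanged
  eps0 <- time_series(seq(0, 300, 1), rep(0, 301))
  sim <- simulate_stress_response(eps0, p, init = st)
  expect_lt(max(abs(sim$stress$value - 6.66)), 1e-12)
  expect_lt(max(abs(sim$trajectory$eps_a - st$eps_a)), 1e-14)

  # degenerate all-zero state
  p0 <- material_params(E_s = 1, eta_a = 1, sigma_max = 0, E_p = 1,
                        eta_p = 1, sigma_Y_t = 0, sigma_Y_c = 0)
  st0 <- equilibrium_state(p0)
  expect_equal(st0$sigma_a + st0$sigma_p, 0)
})

test_that("step-strain response matches the standard-linear-solid closed form", {
  p <- sls_params()  # E_s 500, eta_a 5000, E_p 100, yields never reached
  t <- seq(0, 150, by = 1)
  sim <- simulate_stress_response(time_series(t, rep(0.01, length(t))), p)
  expected <- 0.01 * (100 + 500 * exp(-0.1 * t))
  expect_lt(max(abs(sim$stress$value - expected) / expected), 1e-3)
  # initial jump (E_s + E_p) * step and long-time plateau E_p * step
  expect_equal(sim$stress$value[1], 6, tolerance = 1e-10)
  expect_equal(sim$stress$value[length(t)], 1, tolerance = 1e-3)
})

test_that("supra-yield constant-rate ramp stress approaches sigma_Y + eta_p * rate", {
  p <- material_params(E_p = 50, eta_p = 2e3, sigma_Y_t = 0.5,
                       sigma_Y_c = 0.5, variant = "ecm_only")
  rate <- 2e-3
  t <- seq(0, 400, by = 0.5)
  sim <- simulate_stress_response(time_series(t, rate * t), p)
  asymptote <- 0.5 + 2e3 * rate
  expect_lt(abs(sim$stress$value[length(t)] - asymptote) / asymptote, 5e-3)
})

test_that("strain decomposition and stress additivity hold along trajectories", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      p <- material_params(E_s = 10^runif(1, 1, 3), eta_a = 10^runif(1, 3, 5),
                           sigma_max = runif(1, 0, 10),
                           E_p = 10^runif(1, 1, 2.5),
                           eta_p = 10^runif(1, 3, 5),
                           sigma_Y_t = runif(1, 0.2, 2),
                           sigma_Y_c = runif(1, 0.2, 2))
      strain <- random_strain_protocol()
      sim <- simulate_stress_response(strain, p)
      traj <- sim$trajectory
      # sigma_a = E_s * (eps_total - eps_a)
      expect_lt(max(abs(traj$sigma_a - p$E_s * (traj$eps_total - traj$eps_a))),
                1e-9 * max(1, max(abs(traj$sigma_a))))
      # sigma_p = E_p * (eps_total - eps_pl)
      expect_lt(max(abs(traj$sigma_p - p$E_p * (traj$eps_total - traj$eps_pl))),
                1e-9 * max(1, max(abs(traj$sigma_p))))
      # total = sigma_a + sigma_p
      expect_equal(sim$stress$value, traj$sigma_a + traj$sigma_p)
    }
  })
})

test_that("decomposed branch stresses sum to the total and respect variants", {
  strain <- short_yield_strain()
  p <- default_params()
  sim <- simulate_stress_response(strain, p)
  parts <- decompose_stress(sim)
  expect_equal(parts$sigma_a$value + parts$sigma_p$value, sim$stress$value)
  pc <- material_params(E_s = 500, eta_a = 2e4, sigma_max = 6,
                        variant = "cell_only")
  simc <- simulate_stress_response(strain, pc)
  expect_true(all(decompose_stress(simc)$sigma_p$value == 0))
  pe <- default_params("ecm_only")
  sime <- simulate_stress_response(strain, pe,
    init = equilibrium_state(pe, baseline_stress = 0.5))
  expect_true(all(decompose_stress(sime)$sigma_a$value == 0))
})

test_that("residual plastic strain is zero sub-yield, positive past yield, and matches the oracle", {
  # sub-yield closed cycle: no flow
  pe <- material_params(E_p = 50, eta_p = 1e4, sigma_Y_t = 2, sigma_Y_c = 2,
                        variant = "ecm_only")
  t <- seq(0, 60, 0.5)
  cyc <- time_series(t, 0.02 * sin(2 * pi * t / 60))  # |sigma_p| <= 1 < 2
  sim <- simulate_stress_response(cyc, pe)
  expect_equal(residual_plastic_strain(sim), 0)

  # yield-crossing stretch-unstretch: positive, equal to the oracle integral
  py <- material_params(E_p = 50, eta_p = 1e4, sigma_Y_t = 1, sigma_Y_c = 1,
                        variant = "ecm_only")
  strain <- short_yield_strain()
  simy <- simulate_stress_response(strain, py)
  expect_gt(residual_plastic_strain(simy), 0)
  orc <- euler_oracle(strain, py)
  expect_equal(residual_plastic_strain(simy),
               orc$eps_pl[length(orc$eps_pl)] - orc$eps_pl[1],
               tolerance = 1e-3)

  # full model with shielding: matrix never yields, no residual
  pf <- default_params()
  simf <- simulate_stress_response(time_series(t, 0.01 * sin(2 * pi * t / 60)),
                                   pf)
  expect_true(all(abs(simf$trajectory$sigma_p) < pf$sigma_Y_t))
  expect_equal(residual_plastic_strain(simf), 0)
})

test_that("plastic dissipation is non-negative on arbitrary paths", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      p <- material_params(E_s = 300, eta_a = 2e4, sigma_max = 5,
                           E_p = 10^runif(1, 1.2, 2.2),
                           eta_p = 10^runif(1, 3, 4.5),
                           sigma_Y_t = runif(1, 0.1, 1),
                           sigma_Y_c = runif(1, 0.1, 1))
      sim <- simulate_stress_response(
        random_strain_protocol(peak = 0.08), p)
      expect_gte(plastic_dissipation(sim), 0)
    }
  })
})

test_that("full model with matrix branch zeroed reproduces cell_only bit for bit", {
  strain <- short_yield_strain()
  pf <- material_params(E_s = 400, eta_a = 3e4, sigma_max = 5, E_p = 0,
                        eta_p = 1e5, sigma_Y_t = 0, sigma_Y_c = 0)
  pc <- material_params(E_s = 400, eta_a = 3e4, sigma_max = 5,
                        variant = "cell_only")
  simf <- simulate_stress_response(strain, pf)
  simc <- simulate_stress_response(strain, pc)
  expect_identical(simf$trajectory$eps_a, simc$trajectory$eps_a)
  expect_identical(simf$stress$value, simc$stress$value)
})

test_that("output is stable under integrator step refinement", {
  p <- default_params()
  strain <- short_yield_strain()
  s1 <- simulate_stress_response(strain, p, dt = 0.05)
  s2 <- simulate_stress_response(strain, p, dt = 0.01)
  expect_lt(max(abs(s1$stress$value - s2$stress$value)),
            1e-6 * max(abs(s1$stress$value)))
})

test_that("simulation input validation catches bad grids and steps", {
  p <- default_params()
  expect_error(time_series(c(0, 1, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(simulate_stress_response(time_series(0:10, rep(0, 11)), p,
                                        dt = 0.6), "half the minimum")
  expect_error(simulate_stress_response(time_series(0, 0), p),
               "at least 2")
})
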