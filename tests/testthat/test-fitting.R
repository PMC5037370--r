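test_that("normalized chi-squared matches hand-computed values", {
  g <- 0:3
  d <- time_series(g, c(1, 2, 0, 0), kind = "stress")
  m_same <- d
  expect_equal(chi_squared(m_same, d), 0)
  m0 <- time_series(g, rep(0, 4), kind = "stress")
  expect_equal(chi_squared(m0, d), 1)
  d2 <- time_series(0:1, c(1, 2), kind = "stress")
  m2 <- time_series(0:1, c(2, 2), kind = "stress")
  expect_equal(chi_squared(m2, d2), 0.2)
  expect_error(chi_squared(time_series(0:2, 1:3), d2), "time grid")
  expect_error(chi_squared(m0, time_series(g, rep(0, 4))), "identically zero")
})

test_that("random search is deterministic under a fixed seed and respects budgets", {
  ex <- generate_triton_experiment(noise = no_noise(),
                                   protocol = triton_protocol(0.05))
  # thin the series to keep the unit test fast
  idx <- seq(1, nrow(ex$strain), by = 5)
  strain <- time_series(ex$strain$t_s[idx], ex$strain$value[idx])
  absolute <- time_series(ex$stress$t_s[idx],
                          ex$stress$value[idx] + ex$baseline_stress,
                          kind = "stress")
  cfg <- fit_config("ecm_only", seed = 42, max_iterations = 400, dt = 0.5)
  f1 <- random_search_fit(strain, absolute, cfg,
                          baseline_stress = ex$baseline_stress)
  f2 <- random_search_fit(strain, absolute, cfg,
                          baseline_stress = ex$baseline_stress)
  expect_identical(f1$trace, f2$trace)
  expect_identical(unclass(f1$params), unclass(f2$params))

  # trace is non-increasing and the reported chi2 is reproducible
  expect_true(all(diff(f1$trace) <= 0))
  model <- simulate_stress_response(
    strain, f1$params,
    init = equilibrium_state(f1$params,
                             baseline_stress = ex$baseline_stress),
    dt = 0.5)
  expect_equal(chi_squared(model$stress, absolute), f1$chi2)

  # degenerate budget: best of a single uniform draw (zero matrix baseline
  # so every draw is feasible)
  cfg1 <- fit_config("ecm_only", seed = 7, max_iterations = 1, dt = 0.5)
  fb <- random_search_fit(strain, absolute, cfg1, baseline_stress = 0)
  expect_equal(fb$iterations, 1L)
  expect_length(fb$trace, 1L)
  expect_identical(fb$convergence, "max_iter")

  expect_error(fit_config("full", bounds = list(E_s = c(-1, 1))), "positive")
})

test_that("fit_experiment restricts the search space to the variant's parameters", {
  ex <- generate_triton_experiment(noise = no_noise())
  ft <- fit_synthetic(ex, config = fit_config("ecm_only", seed = 1,
                                              max_iterations = 50, dt = 0.5),
                      use_noisy = FALSE)
  expect_setequal(names(ft$config$bounds), c("E_p", "eta_p", "sigma_Y_t"))
  sc <- generate_single_cell_experiment(noise = no_noise())
  fc <- fit_synthetic(sc, config = fit_config(
    "cell_only", bounds = default_bounds("cell_only", force_units = TRUE),
    seed = 1, max_iterations = 50, dt = 0.5), use_noisy = FALSE)
  expect_setequal(names(fc$config$bounds), c("E_s", "eta_a", "sigma_max"))
  expect_error(fit_experiment("triton", ex$strain, ex$stress,
                              baseline = ex$baseline_stress,
                              config = fit_config("full")), "variant")
})

test_that("shielded control data leave matrix yield parameters unidentified but pin E_s", {
  ex <- generate_control_experiment(noise = no_noise())
  cfg <- fit_config("full", seed = 3, max_iterations = 40000,
                    chi2_threshold = 1e-8, dt = 0.5, stall_window = 400)
  fit <- fit_synthetic(ex, config = cfg, use_noisy = FALSE)
  expect_lt(fit$chi2, 1e-5)  # converged into the generating basin
  absolute <- time_series(ex$stress$t_s, ex$stress$value + ex$baseline_stress,
                          kind = "stress")
  # sweep the tensile yield over values above the (shielded) peak matrix
  # stress: the data cannot see it
  prof_y <- ecm_sensitivity_profile(fit, ex$strain, absolute, "sigma_Y_t",
                                    grid = seq(5, 50, length.out = 9))
  expect_true(attr(prof_y, "flat"))
  expect_lt(attr(prof_y, "ratio"), 1.1)
  # sweeping the series stiffness moves chi-squared by orders of magnitude
  prof_E <- ecm_sensitivity_profile(fit, ex$strain, absolute, "E_s",
                                    grid = fit$params$E_s * c(0.5, 1, 2))
  expect_gt(attr(prof_E, "ratio"), 10)
  # single-point grid returns the incumbent chi-squared
  prof_1 <- ecm_sensitivity_profile(fit, ex$strain, absolute, "E_s",
                                    grid = fit$params$E_s)
  expect_equal(prof_1$chi2, fit$chi2)
})

test_that("fit reports serialize with parameters, trace, and convergence reason", {
  ex <- generate_triton_experiment(noise = no_noise())
  fit <- fit_synthetic(ex, config = fit_config("ecm_only", seed = 2,
                                               max_iterations = 60, dt = 0.5),
                       use_noisy = FALSE)
  rp <- file.path(tempdir(), "fit.yaml")
  tp <- file.path(tempdir(), "trace.csv")
  write_fit_report(fit, rp, trace_path = tp)
  y <- yaml::read_yaml(rp)
  expect_equal(y$chi2, fit$chi2, tolerance = 1e-10)
  expect_equal(y$parameters$E_p, fit$params$E_p, tolerance = 1e-10)
  expect_identical(y$convergence, fit$convergence)
  tr <- read.csv(tp)
  expect_equal(nrow(tr), fit$iterations)
  expect_true(all(diff(tr$chi2) <= 0))
})
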