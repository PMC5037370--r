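# Independent fixed-step explicit-Euler integration of the model, written
# in plain R against the constitutive equations. Used as a brute-force
# oracle for the package's compiled Runge-Kutta integrator; it shares no
# code with it.
euler_oracle <- function(strain_ts, params, init = equilibrium_state(params),
                         dt = 1e-3) {
  tin <- strain_ts$t_s
  vin <- strain_ts$value
  active <- params$variant != "ecm_only"
  parallel <- params$variant != "cell_only"
  eps_a <- init$eps_a
  eps_pl <- init$eps_pl
  n_out <- length(tin)
  sig <- numeric(n_out)
  epl <- numeric(n_out)
  branch_stress <- function(eps) {
    sa <- if (active) params$E_s * (eps - eps_a) else 0
    sp <- if (parallel) params$E_p * (eps - eps_pl) else 0
    c(sa, sp)
  }
  s0 <- branch_stress(vin[1])
  sig[1] <- sum(s0)
  epl[1] <- eps_pl
  for (k in 2:n_out) {
    nstep <- ceiling((tin[k] - tin[k - 1]) / dt)
    h <- (tin[k] - tin[k - 1]) / nstep
    de <- (vin[k] - vin[k - 1]) / nstep
    for (j in seq_len(nstep)) {
      eps <- vin[k - 1] + de * (j - 1)
      if (active)
        eps_a <- eps_a +
          h * (params$E_s * (eps - eps_a) - params$sigma_max) / params$eta_a
      if (parallel) {
        sp <- params$E_p * (eps - eps_pl)
        rate <- if (sp > params$sigma_Y_t) {
          (sp - params$sigma_Y_t) / params$eta_p
        } else if (sp < -params$sigma_Y_c) {
          (sp + params$sigma_Y_c) / params$eta_p
        } else 0
        eps_pl <- eps_pl + h * rate
      }
    }
    s <- branch_stress(vin[k])
    sig[k] <- sum(s)
    epl[k] <- eps_pl
  }
  list(stress = sig, eps_pl = epl)
}

# Relative error helper
rel_err <- function(fit_value, true_value) abs(fit_value - true_value) / abs(true_value)
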