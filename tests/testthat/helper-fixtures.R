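# Shared fixtures: small, fast protocols and parameter sets used across
# the unit tests. The full-length study protocols are exercised in the
# acceptance tests.

# Parameters with no yielding over small strains (linear regime)
sls_params <- function() {
  material_params(E_s = 500, eta_a = 5000, sigma_max = 0, E_p = 100,
                  eta_p = 1e5, sigma_Y_t = 10, sigma_Y_c = 10)
}

# Short triangular strain ramp crossing the tensile yield (ecm_only)
short_yield_strain <- function() {
  t <- seq(0, 60, by = 0.5)
  peak <- 0.08
  v <- ifelse(t <= 30, peak * t / 30, peak * (60 - t) / 30)
  time_series(t, v, kind = "strain")
}

# Random piecewise-linear strain protocol on [0, span] with given peak scale
random_strain_protocol <- function(span = 60, peak = 0.05, n_knots = 5,
                                   by = 0.5) {
  knots_t <- sort(c(0, runif(n_knots - 2, 0, span), span))
  knots_v <- c(0, runif(n_knots - 2, -peak, peak), 0)
  t <- seq(0, span, by = by)
  time_series(t, approx(knots_t, knots_v, xout = t)$y, kind = "strain")
}
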