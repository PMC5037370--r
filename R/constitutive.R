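#' Active (Hill) strain rate
#'
#' Linearized Hill relation for the contractile element: the active strain
#' rate is proportional to the distance of the branch stress from the stall
#' stress, `(sigma_a - sigma_max) / eta_a`. The rate vanishes exactly at
#' stall; below stall the element shortens (negative rate, contraction),
#' above stall it lengthens. Sign convention: positive strain = elongation.
#'
#' @param sigma_a Active/series branch stress, kPa.
#' @param params `material_params` with a valid active branch.
#' @return Strain rate, 1/s.
#' @export
active_strain_rate <- function(sigma_a, params) {
  validate_material_params(params)
  if (params$variant == "ecm_only")
    stop("active branch absent in the ecm_only variant", call. = FALSE)
  (sigma_a - params$sigma_max) / params$eta_a
}

#' Viscoplastic (Bingham-Norton) strain rate of the matrix element
#'
#' Overstress flow rule: no flow while the matrix stress lies in the closed
#' elastic range `[-sigma_Y_c, sigma_Y_t]` (stress exactly at yield counts as
#' elastic, making the rule continuous); beyond it the plastic strain rate is
#' the overstress divided by the plastic viscosity `eta_p`.
#'
#' @param sigma_p Parallel (matrix) branch stress, kPa.
#' @param params `material_params` with a valid parallel branch.
#' @return Plastic strain rate, 1/s.
#' @export
plastic_strain_rate <- function(sigma_p, params) {
  validate_material_params(params)
  if (params$variant == "cell_only")
    stop("parallel branch absent in the cell_only variant", call. = FALSE)
  ifelse(sigma_p > params$sigma_Y_t, (sigma_p - params$sigma_Y_t) / params$eta_p,
  ifelse(sigma_p < -params$sigma_Y_c, (sigma_p + params$sigma_Y_c) / params$eta_p,
         0))
}

#' Stationary pre-actuation state of the model
#'
#' Constructs the reference (baseline) configuration: the tissue after
#' contractile activation and matrix compaction but before external force.
#' At equilibrium the active rate is zero, so the cell branch carries exactly
#' the stall stress; the matrix branch carries the baseline partition
#' `sigma_p0`, which must lie inside the yield range (no plastic flow at
#' rest). Total strain is measured from this configuration, so the returned
#' state has `eps_total = 0` and internal strains set so the branch stresses
#' take their baseline values. Simulating forward under frozen strain leaves
#' this state unchanged.
#'
#' For the full variant the partition is `sigma_p0 = baseline_stress -
#' sigma_max` when `baseline_stress` is supplied, and 0 otherwise (the
#' matrix contribution to the baseline folded into `sigma_max`, the default
#' for control tissues where the partition is unidentifiable).
#'
#' @param params `material_params`.
#' @param baseline_stress Total baseline stress `sigma_0`, kPa (or mN for
#'   force-unit cell parameters). Optional for `full`/`cell_only`; for
#'   `ecm_only` it is the matrix baseline itself (default 0).
#' @param baseline_matrix_stress Explicit matrix partition `sigma_p0`, kPa;
#'   overrides the default partition for the full variant.
#' @return A `system_state` list with fields `t`, `eps_total`, `eps_a`,
#'   `eps_pl`, `sigma_a`, `sigma_p`.
#' @export
equilibrium_state <- function(params, baseline_stress = NULL,
                              baseline_matrix_stress = NULL) {
  validate_material_params(params)
  variant <- params$variant
  active <- variant != "ecm_only"
  parallel <- variant != "cell_only"

  sigma_a0 <- if (active) params$sigma_max else 0
  if (parallel) {
    sigma_p0 <- if (!is.null(baseline_matrix_stress)) {
      baseline_matrix_stress
    } else if (variant == "ecm_only") {
      if (is.null(baseline_stress)) 0 else baseline_stress
    } else if (!is.null(baseline_stress)) {
      baseline_stress - params$sigma_max
    } else 0
    if (sigma_p0 > params$sigma_Y_t + 1e-12 ||
        sigma_p0 < -params$sigma_Y_c - 1e-12)
      stop(sprintf(paste0("inconsistent baseline: matrix stress %g kPa lies ",
                          "outside the elastic range [%g, %g]"),
                   sigma_p0, -params$sigma_Y_c, params$sigma_Y_t),
           call. = FALSE)
  } else sigma_p0 <- 0

  eps_a0 <- if (active) -sigma_a0 / params$E_s else 0
  eps_pl0 <- if (parallel && params$E_p > 0) -sigma_p0 / params$E_p else 0
  if (parallel && params$E_p == 0 && abs(sigma_p0) > 0)
    stop("nonzero matrix baseline requires E_p > 0", call. = FALSE)

  state <- list(t = 0, eps_total = 0, eps_a = eps_a0, eps_pl = eps_pl0,
                sigma_a = sigma_a0, sigma_p = sigma_p0)
  class(state) <- "system_state"
  state
}

#' Simulate the stress response to a prescribed total-strain history
#'
#' Integrates the model's two internal state variables (active strain and
#' accumulated plastic strain) under a prescribed total strain, with the
#' strain linearly interpolated between samples, using a fixed-step explicit
#' 4th-order Runge-Kutta scheme. Yield-surface crossings need no event
#' handling because the overstress rule is continuous. Returns the total
#' stress sampled at the input times together with the full state
#' trajectory.
#'
#' @param strain `time_series` of total strain (measured from the reference
#'   configuration of `init`), at least 2 samples.
#' @param params `material_params`.
#' @param init Initial `system_state`; defaults to
#'   `equilibrium_state(params)`.
#' @param dt Integrator step, s (default 0.05). Must not exceed half the
#'   smallest sampling interval of `strain`.
#' @return A `sim_result` list: `stress` (absolute total stress
#'   `time_series`), `trajectory` (data.frame with columns `t`, `eps_total`,
#'   `eps_a`, `eps_pl`, `sigma_a`, `sigma_p`), `baseline_stress` (the
#'   initial total stress), `params`, `dt`.
#' @examples
#' p <- default_params()
#' eps <- time_series(0:240, 0.01 * sin(2 * pi * (0:240) / 240))
#' sim <- simulate_stress_response(eps, p)
#' @export
simulate_stress_response <- function(strain, params, init = NULL, dt = 0.05) {
  stopifnot(inherits(strain, "time_series"))
  validate_material_params(params)
  if (nrow(strain) < 2)
    stop("strain series must have at least 2 samples", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  min_int <- min(diff(strain$t_s))
  if (dt > min_int / 2 + 1e-12)
    stop(sprintf("dt = %g s exceeds half the minimum sampling interval (%g s)",
                 dt, min_int), call. = FALSE)
  if (is.null(init)) init <- equilibrium_state(params)
  stopifnot(inherits(init, "system_state"))

  traj <- sim_strain_driven(strain$t_s, strain$value,
                            .params_for_core(params),
                            .variant_code[[params$variant]], dt,
                            init$eps_a, init$eps_pl)
  traj <- as.data.frame(traj)
  total <- traj$sigma_a + traj$sigma_p
  out <- list(stress = time_series(traj$t, total, kind = "stress",
                                   units = "kPa"),
              trajectory = traj,
              baseline_stress = init$sigma_a + init$sigma_p,
              params = params, dt = dt)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result (%s): %d samples, t = %g..%g s, stress %g..%g kPa\n",
              x$params$variant, nrow(x$trajectory),
              min(x$trajectory$t), max(x$trajectory$t),
              min(x$stress$value), max(x$stress$value)))
  invisible(x)
}

#' Split a simulated trajectory into cell and matrix stress contributions
#'
#' Returns the active/series branch stress `sigma_a(t)` and the parallel
#' matrix stress `sigma_p(t)` as separate series; they sum pointwise to the
#' total stress.
#'
#' @param sim A `sim_result` (or its `trajectory` data.frame).
#' @return A list with `time_series` elements `sigma_a` and `sigma_p`.
#' @export
decompose_stress <- function(sim) {
  traj <- if (inherits(sim, "sim_result")) sim$trajectory else sim
  stopifnot(is.data.frame(traj),
            all(c("t", "sigma_a", "sigma_p") %in% names(traj)))
  list(sigma_a = time_series(traj$t, traj$sigma_a, kind = "stress",
                             units = "kPa"),
       sigma_p = time_series(traj$t, traj$sigma_p, kind = "stress",
                             units = "kPa"))
}

#' Residual (permanent) plastic strain accumulated over a trajectory
#'
#' The change in the matrix element's accumulated plastic strain between the
#' first and last sample. Zero for any loading that keeps the matrix stress
#' inside its yield range throughout (e.g. control tissues shielded by cell
#' contraction); positive for monotone supra-tensile-yield loading (e.g.
#' Triton-lysed tissues stretched past yield).
#'
#' @param sim A `sim_result` (or its `trajectory` data.frame).
#' @return Dimensionless strain.
#' @export
residual_plastic_strain <- function(sim) {
  traj <- if (inherits(sim, "sim_result")) sim$trajectory else sim
  stopifnot(is.data.frame(traj), "eps_pl" %in% names(traj))
  traj$eps_pl[nrow(traj)] - traj$eps_pl[1]
}

#' Plastic dissipation along a trajectory
#'
#' Trapezoidal estimate of the plastically dissipated work density
#' `integral of sigma_p d(eps_pl)`, kPa (per unit volume). Non-negative for
#' the overstress flow rule, since the plastic rate always shares the sign
#' of the matrix stress beyond yield.
#'
#' @param sim A `sim_result` (or its `trajectory` data.frame).
#' @return Dissipated work density, kPa.
#' @export
plastic_dissipation <- function(sim) {
  traj <- if (inherits(sim, "sim_result")) sim$trajectory else sim
  n <- nrow(traj)
  if (n < 2) return(0)
  dpl <- diff(traj$eps_pl)
  smid <- (traj$sigma_p[-1] + traj$sigma_p[-n]) / 2
  sum(smid * dpl)
}
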