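#' Constitutive parameters of the three-element microtissue model
#'
#' Bundles the seven material constants of the model: an active contractile
#' (Hill) element with stall stress `sigma_max` and active viscosity `eta_a`,
#' in series with a linear spring `E_s`; this cell branch acts in parallel
#' with an elastic perfectly viscoplastic (Bingham-Norton) matrix element
#' with stiffness `E_p`, plastic viscosity `eta_p`, and tensile/compressive
#' yield stresses `sigma_Y_t` / `sigma_Y_c`.
#'
#' Units are fixed package-wide: seconds, dimensionless strain, kPa, and
#' kPa·s. For single-cell fits the same structure is reused in force units
#' (mN for `E_s` and `sigma_max`, mN·s for `eta_a`); see
#' [generate_single_cell_experiment()].
#'
#' @param E_s Series (cell-branch) stiffness, kPa. Must be > 0 when the
#'   active branch is present.
#' @param eta_a Active viscosity (slope of the linearized Hill relation),
#'   kPa·s. Must be > 0 when the active branch is present.
#' @param sigma_max Stall stress of the contractile element, kPa (>= 0).
#' @param E_p Parallel (matrix) stiffness, kPa (>= 0; 0 disables the
#'   parallel spring).
#' @param eta_p Plastic viscosity of the matrix beyond yield, kPa·s (> 0
#'   when the parallel branch is present).
#' @param sigma_Y_t Tensile yield stress, kPa (>= 0).
#' @param sigma_Y_c Compressive yield stress magnitude, kPa (>= 0; stored as
#'   a non-negative number, applied at `sigma_p = -sigma_Y_c`).
#' @param variant Model variant the parameters are intended for: `"full"`,
#'   `"ecm_only"` (cell branch removed, as after Triton lysis), or
#'   `"cell_only"` (matrix branch removed, as for single cells on
#'   microposts). Validation is variant-aware: parameters of absent branches
#'   are ignored.
#'
#' @return An object of class `material_params` (a named list).
#' @examples
#' material_params(E_s = 500, eta_a = 5e4, sigma_max = 6,
#'                 E_p = 50, eta_p = 1e5, sigma_Y_t = 1, sigma_Y_c = 1)
#' @export
material_params <- function(E_s = NA_real_, eta_a = NA_real_,
                            sigma_max = NA_real_, E_p = NA_real_,
                            eta_p = NA_real_, sigma_Y_t = NA_real_,
                            sigma_Y_c = NA_real_, variant = "full") {
  variant <- .check_variant(variant)
  p <- list(E_s = as.numeric(E_s), eta_a = as.numeric(eta_a),
            sigma_max = as.numeric(sigma_max), E_p = as.numeric(E_p),
            eta_p = as.numeric(eta_p), sigma_Y_t = as.numeric(sigma_Y_t),
            sigma_Y_c = as.numeric(sigma_Y_c), variant = variant)
  class(p) <- "material_params"
  validate_material_params(p)
  p
}

#' Validate material parameters for their model variant
#'
#' @param p A `material_params` object.
#' @return `p`, invisibly, after validation; errors describe the violated
#'   constraint.
#' @export
validate_material_params <- function(p) {
  stopifnot(inherits(p, "material_params"))
  active <- p$variant != "ecm_only"
  parallel <- p$variant != "cell_only"
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                 call. = FALSE)
  if (active) {
    chk(is.finite(p$E_s) && p$E_s > 0, "E_s must be finite and > 0")
    chk(is.finite(p$eta_a) && p$eta_a > 0, "eta_a must be finite and > 0")
    chk(is.finite(p$sigma_max) && p$sigma_max >= 0, "sigma_max must be >= 0")
  }
  if (parallel) {
    chk(is.finite(p$E_p) && p$E_p >= 0, "E_p must be finite and >= 0")
    chk(is.finite(p$eta_p) && p$eta_p > 0, "eta_p must be finite and > 0")
    chk(is.finite(p$sigma_Y_t) && p$sigma_Y_t >= 0, "sigma_Y_t must be >= 0")
    chk(is.finite(p$sigma_Y_c) && p$sigma_Y_c >= 0, "sigma_Y_c must be >= 0")
  }
  invisible(p)
}

#' @export
print.material_params <- function(x, ...) {
  cat("Three-element model parameters (variant: ", x$variant, ")\n", sep = "")
  active <- x$variant != "ecm_only"
  parallel <- x$variant != "cell_only"
  if (active)
    cat(sprintf("  cell branch:   E_s = %g, eta_a = %g, sigma_max = %g\n",
                x$E_s, x$eta_a, x$sigma_max))
  if (parallel)
    cat(sprintf("  matrix branch: E_p = %g, eta_p = %g, sigma_Y_t = %g, sigma_Y_c = %g\n",
                x$E_p, x$eta_p, x$sigma_Y_t, x$sigma_Y_c))
  invisible(x)
}

# Fill unused-branch fields with harmless finite values for the compiled core
.params_for_core <- function(p) {
  q <- unclass(p)
  fill <- function(v, d) if (is.na(v)) d else v
  q$E_s <- fill(q$E_s, 1); q$eta_a <- fill(q$eta_a, 1)
  q$sigma_max <- fill(q$sigma_max, 0)
  q$E_p <- fill(q$E_p, 0); q$eta_p <- fill(q$eta_p, 1)
  q$sigma_Y_t <- fill(q$sigma_Y_t, 0); q$sigma_Y_c <- fill(q$sigma_Y_c, 0)
  q
}

#' Default fixture parameters of the synthetic-experiment generators
#'
#' The reference parameter set used throughout the test fixtures and
#' examples: `E_s` = 500 kPa, `eta_a` = 2e4 kPa·s, `sigma_max` = 6 kPa,
#' `E_p` = 50 kPa, `eta_p` = 1e5 kPa·s, `sigma_Y_t` = `sigma_Y_c` = 1 kPa.
#' Chosen to reproduce the qualitative stretch-unstretch phenomenology of
#' control microtissues at percent-level strains: the active relaxation time
#' `eta_a / E_s` = 40 s puts the force-controlled response in the regime
#' where the strain peak lags the stress peak by tens of seconds, with
#' stress undershoot and active recovery after unload, and with the matrix
#' stress shielded inside its yield range throughout.
#'
#' @param variant Model variant, as in [material_params()].
#' @return A `material_params` object.
#' @export
default_params <- function(variant = "full") {
  material_params(E_s = 500, eta_a = 2e4, sigma_max = 6,
                  E_p = 50, eta_p = 1e5, sigma_Y_t = 1, sigma_Y_c = 1,
                  variant = variant)
}

#' Default single-cell parameters, in force units
#'
#' Cell-only variant parameters for a single smooth muscle cell on a
#' micropost array, fitted in force rather than stress units: the "stiffness"
#' maps strain to total traction force (mN), the stall parameter is the
#' baseline total contractile force (mN), and the active viscosity has units
#' mN·s. Defaults give a ~0.5 uN baseline force and a ~100 s relaxation time.
#'
#' @return A `material_params` object with `variant = "cell_only"`.
#' @export
default_cell_params <- function() {
  material_params(E_s = 2e-3, eta_a = 0.2, sigma_max = 5e-4,
                  variant = "cell_only")
}
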