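#' Stretch-unstretch-observe loading protocol
#'
#' Describes the piecewise-linear loading waveform used throughout: a linear
#' ramp from zero to `peak_value`, a linear ramp back to zero, an optional
#' hold at peak (default 0), and a zero-load observation window. The
#' microtissue protocol is force-controlled (25 uN peak, 120 s up, 120 s
#' down, 15 min observation); the single-cell protocol is strain-controlled
#' (10% peak over 3 min each way).
#'
#' @param peak_value Peak of the ramp: uN for force-controlled protocols,
#'   dimensionless strain for strain-controlled ones.
#' @param ramp_up_duration,ramp_down_duration Ramp durations, s (>= 0).
#' @param observation_duration Zero-load observation window, s (>= 0).
#' @param hold_duration Optional hold at peak, s (default 0).
#' @param sample_interval Sampling interval of the generated waveform, s
#'   (> 0, default 1).
#' @param kind Waveform kind tag: `"load"` (force) or `"strain"`.
#' @param units Unit tag for the waveform values.
#' @return A `loading_protocol` object.
#' @export
loading_protocol <- function(peak_value, ramp_up_duration = 120,
                             ramp_down_duration = 120,
                             observation_duration = 900,
                             hold_duration = 0, sample_interval = 1,
                             kind = c("load", "strain"), units = "uN") {
  kind <- match.arg(kind)
  if (!all(is.finite(c(peak_value, ramp_up_duration, ramp_down_duration,
                       observation_duration, hold_duration, sample_interval))))
    stop("protocol fields must be finite", call. = FALSE)
  if (min(ramp_up_duration, ramp_down_duration, observation_duration,
          hold_duration) < 0)
    stop("durations must be >= 0", call. = FALSE)
  if (sample_interval <= 0)
    stop("sample_interval must be > 0", call. = FALSE)
  p <- list(peak_value = peak_value, ramp_up_duration = ramp_up_duration,
            hold_duration = hold_duration,
            ramp_down_duration = ramp_down_duration,
            observation_duration = observation_duration,
            sample_interval = sample_interval, kind = kind, units = units)
  class(p) <- "loading_protocol"
  p
}

#' Default microtissue force protocol (25 uN, 120 s up/down, 15 min observe)
#' @param peak_uN Peak magnetic force, uN.
#' @return A `loading_protocol`.
#' @export
control_protocol <- function(peak_uN = 25) {
  loading_protocol(peak_uN, 120, 120, 900, kind = "load", units = "uN")
}

#' Default matrix-only strain protocol (5% peak, 120 s up/down)
#' @param peak_strain Peak applied strain.
#' @return A `loading_protocol`.
#' @export
triton_protocol <- function(peak_strain = 0.05) {
  loading_protocol(peak_strain, 120, 120, 900, kind = "strain", units = "")
}

#' Default single-cell biaxial strain protocol (10% over 3 min each way)
#' @param peak_strain Peak applied strain.
#' @return A `loading_protocol`.
#' @export
single_cell_protocol <- function(peak_strain = 0.10) {
  loading_protocol(peak_strain, 180, 180, 900, kind = "strain", units = "")
}

#' Sample a loading protocol into a waveform
#'
#' Builds the piecewise-linear waveform (ramp up, optional hold, ramp down,
#' zero observation) sampled at the protocol's interval. The waveform starts
#' and ends at zero and is continuous.
#'
#' @param protocol A `loading_protocol`.
#' @return A `time_series` spanning the full protocol.
#' @examples
#' w <- build_protocol_waveform(control_protocol())
#' w$value[w$t_s == 60]  # 12.5 uN, halfway up the ramp
#' @export
build_protocol_waveform <- function(protocol) {
  stopifnot(inherits(protocol, "loading_protocol"))
  p <- protocol
  t_up <- p$ramp_up_duration
  t_hold <- t_up + p$hold_duration
  t_down <- t_hold + p$ramp_down_duration
  t_end <- t_down + p$observation_duration
  times <- seq(0, t_end, by = p$sample_interval)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  v <- numeric(length(times))
  up <- times <= t_up & t_up > 0
  v[up] <- p$peak_value * times[up] / t_up
  hold <- times > t_up & times <= t_hold
  v[hold] <- p$peak_value
  down <- times > t_hold & times <= t_down
  if (p$ramp_down_duration > 0)
    v[down] <- p$peak_value * (t_down - times[down]) / p$ramp_down_duration
  time_series(times, v, kind = p$kind, units = p$units)
}

#' Device calibration constants
#'
#' Calibration of the two force sensors and tissue geometry: the flexible
#' PDMS micropillar pair holding a microtissue (spring constant 0.59 uN/um
#' for small deflections, optionally a monotone force-deflection table from
#' finite-element calibration for large deflections), the tissue
#' cross-section used to convert force to stress, the effective tissue
#' length converting pillar deflection to strain, and the micropost spring
#' constant of the single-cell arrays (22 nN/um).
#'
#' @param pillar_spring_constant uN/um, > 0.
#' @param pillar_force_table Optional data.frame with columns
#'   `deflection_um`, `force_uN`: a strictly monotone calibration curve
#'   passing through (0, 0). When supplied, pillar forces are interpolated
#'   through it (monotone Hermite); deflections outside its range error
#'   rather than extrapolate.
#' @param tissue_cross_section_um2 Tissue cross-sectional area, um^2, > 0.
#' @param tissue_length_um Effective tissue length between pillars, um, > 0.
#' @param micropost_spring_constant nN/um, > 0.
#' @return A `device_calibration` object.
#' @export
device_calibration <- function(pillar_spring_constant = 0.59,
                               pillar_force_table = NULL,
                               tissue_cross_section_um2 = 8000,
                               tissue_length_um = 500,
                               micropost_spring_constant = 22) {
  if (pillar_spring_constant <= 0 || micropost_spring_constant <= 0)
    stop("spring constants must be > 0", call. = FALSE)
  if (tissue_cross_section_um2 <= 0 || tissue_length_um <= 0)
    stop("tissue geometry must be > 0", call. = FALSE)
  if (!is.null(pillar_force_table)) {
    tb <- pillar_force_table
    if (!all(c("deflection_um", "force_uN") %in% names(tb)))
      stop("force table needs columns deflection_um, force_uN", call. = FALSE)
    if (any(diff(tb$deflection_um) <= 0) || any(diff(tb$force_uN) <= 0))
      stop("force table must be strictly monotone", call. = FALSE)
    if (!any(tb$deflection_um == 0 & tb$force_uN == 0))
      stop("force table must pass through (0, 0)", call. = FALSE)
  }
  cal <- list(pillar_spring_constant = pillar_spring_constant,
              pillar_force_table = pillar_force_table,
              tissue_cross_section_um2 = tissue_cross_section_um2,
              tissue_length_um = tissue_length_um,
              micropost_spring_constant = micropost_spring_constant)
  class(cal) <- "device_calibration"
  cal
}

#' Convert a sensor deflection to force
#'
#' Linear spring law by default (`force = k * deflection`); for the pillar
#' sensor a monotone calibration table, when present in the calibration,
#' replaces the spring law (monotone Hermite interpolation, no
#' extrapolation).
#'
#' @param deflection_um Deflection, um (vectorized).
#' @param calib `device_calibration`.
#' @param sensor `"pillar"` (returns uN) or `"micropost"` (returns nN).
#' @return Force in the sensor's units.
#' @examples
#' force_from_deflection(1.0, device_calibration(), "pillar")  # 0.59 uN
#' @export
force_from_deflection <- function(deflection_um, calib,
                                  sensor = c("pillar", "micropost")) {
  stopifnot(inherits(calib, "device_calibration"))
  sensor <- match.arg(sensor)
  if (sensor == "micropost")
    return(calib$micropost_spring_constant * deflection_um)
  tb <- calib$pillar_force_table
  if (is.null(tb))
    return(calib$pillar_spring_constant * deflection_um)
  rng <- range(tb$deflection_um)
  if (any(deflection_um < rng[1] | deflection_um > rng[2]))
    stop(sprintf("deflection outside calibration table range [%g, %g] um",
                 rng[1], rng[2]), call. = FALSE)
  f <- stats::splinefun(tb$deflection_um, tb$force_uN, method = "hyman")
  f(deflection_um)
}

#' Convert force to tissue stress
#'
#' `sigma = force / area`, returned in kPa (1 uN/um^2 = 10^3 kPa).
#'
#' @param force_uN Force, uN (vectorized).
#' @param area_um2 Cross-sectional area, um^2, > 0.
#' @return Stress, kPa.
#' @examples
#' stress_from_force(28, 1e4)  # 2.8 kPa
#' @export
stress_from_force <- function(force_uN, area_um2) {
  if (!is.numeric(area_um2) || length(area_um2) != 1 || !is.finite(area_um2) ||
      area_um2 <= 0)
    stop("area must be a positive finite scalar", call. = FALSE)
  force_uN / area_um2 * 1e3
}

#' Scale a single cell's active viscosity to the tissue level
#'
#' The tissue-level active viscosity is the single-cell value (fitted in
#' force units, mN·s) times the cross-sectional areal density of cells,
#' `eta_tissue = rho_A * eta_cell`, converted to kPa·s
#' (1 mN/um^2 = 10^6 kPa). Linear in both arguments.
#'
#' @param eta_a_cell Single-cell active viscosity, mN·s, >= 0.
#' @param areal_density Areal cell density `rho_A`, cells/um^2, >= 0.
#' @return Tissue active viscosity, kPa·s.
#' @examples
#' tissue_active_viscosity_from_cell(0.5, 1e-3)  # 500 kPa·s
#' @export
tissue_active_viscosity_from_cell <- function(eta_a_cell, areal_density) {
  if (any(eta_a_cell < 0) || any(areal_density < 0))
    stop("inputs must be non-negative", call. = FALSE)
  areal_density * eta_a_cell * 1e6
}

#' Areal cell density from volumetric cell density
#'
#' Dimensional bridge from a volumetric number density (cells/um^3) to the
#' cross-sectional areal density (cells/um^2) used by
#' [tissue_active_viscosity_from_cell()]: `rho_A = rho_c^(2/3)`. This
#' assumes roughly isotropic cell spacing; it is exposed as a replaceable
#' helper rather than hard-wired.
#'
#' @param rho_c Volumetric cell density, cells/um^3, >= 0.
#' @return Areal density, cells/um^2.
#' @export
areal_density_from_volumetric <- function(rho_c) {
  if (any(rho_c < 0)) stop("density must be non-negative", call. = FALSE)
  rho_c^(2 / 3)
}
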