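#' Additive measurement-noise model for synthetic experiments
#'
#' Independent Gaussian noise added per sample to the incremental stress
#' (or force) and strain channels, emulating bead-tracking measurement
#' scatter. Absolute standard deviations may be given directly; by default
#' each channel's sd is `relative` times the peak absolute value of its
#' noiseless incremental signal (default 2%).
#'
#' @param stress_sd Absolute sd of the stress/force channel (kPa or mN), or
#'   NULL for relative scaling.
#' @param strain_sd Absolute sd of the strain channel, or NULL.
#' @param relative Relative sd applied when the absolute sd is NULL.
#' @return A `noise_model` object.
#' @export
noise_model <- function(stress_sd = NULL, strain_sd = NULL, relative = 0.02) {
  for (v in c(stress_sd, strain_sd, relative))
    if (!is.null(v) && (!is.finite(v) || v < 0))
      stop("noise sds must be finite and >= 0", call. = FALSE)
  nm <- list(stress_sd = stress_sd, strain_sd = strain_sd,
             relative = relative)
  class(nm) <- "noise_model"
  nm
}

#' Noise-free generator settings
#' @return A `noise_model` with both sds 0.
#' @export
no_noise <- function() noise_model(stress_sd = 0, strain_sd = 0)

.resolve_sd <- function(sd, relative, signal) {
  if (!is.null(sd)) sd else relative * max(abs(signal), 0)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.new_experiment <- function(kind, variant, params, protocol, baseline_stress,
                            strain, stress, noise_sds, seed, trajectory,
                            dt, extra = list()) {
  add_noise <- function(ts, sd) {
    if (sd == 0) return(ts)
    time_series(ts$t_s, ts$value + rnorm(nrow(ts), 0, sd),
                kind = attr(ts, "kind"), units = attr(ts, "units"))
  }
  exp <- c(list(kind = kind, variant = variant, params = params,
                protocol = protocol, baseline_stress = baseline_stress,
                strain = strain, stress = stress,
                strain_noisy = add_noise(strain, noise_sds["strain"]),
                stress_noisy = add_noise(stress, noise_sds["stress"]),
                noise_sds = noise_sds, seed = seed,
                trajectory = trajectory, dt = dt),
           extra)
  class(exp) <- "synthetic_experiment"
  exp
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(paste0("synthetic_experiment (%s, %s): %d samples, baseline ",
                     "%g, noise sd (stress %g, strain %g), seed %d\n"),
              x$kind, x$variant, nrow(x$strain), x$baseline_stress,
              x$noise_sds["stress"], x$noise_sds["strain"], x$seed))
  invisible(x)
}

#' Generate a synthetic control-microtissue experiment (force-controlled)
#'
#' Emulates the magnetic stretch-unstretch protocol on an intact
#' microtissue: the applied magnetic force ramps up and back down while the
#' tissue (full three-element model) and the supporting pillar share the
#' load. At every sample the force balance `k L eps + A (sigma - sigma_0) =
#' F_mag` is solved self-consistently (bisection to 1e-6 uN), producing
#' coupled strain and stress records. For the default fixture parameters
#' the response shows the hallmark phenomenology: strain peak lagging the
#' stress peak, stress undershoot after unload followed by active recovery,
#' and matrix stress held inside the yield range throughout (shielding).
#'
#' @param params Full-variant `material_params` (default [default_params()]).
#' @param protocol Force-controlled `loading_protocol` (default
#'   [control_protocol()]).
#' @param calibration `device_calibration` providing the pillar spring
#'   constant, tissue length, and cross-section.
#' @param noise `noise_model` (default 2% of peak).
#' @param seed Integer seed for the noise draws.
#' @param dt Integrator step, s.
#' @return A `synthetic_experiment` with incremental `strain` and `stress`
#'   series (noiseless and noisy), the generating truth, and the full state
#'   trajectory.
#' @export
generate_control_experiment <- function(params = default_params(),
                                        protocol = control_protocol(),
                                        calibration = device_calibration(),
                                        noise = noise_model(), seed = 1L,
                                        dt = 0.05) {
  validate_material_params(params)
  if (params$variant != "full")
    stop("control experiments use the full variant", call. = FALSE)
  stopifnot(inherits(protocol, "loading_protocol"),
            protocol$kind == "load",
            inherits(calibration, "device_calibration"),
            inherits(noise, "noise_model"))
  wave <- build_protocol_waveform(protocol)
  init <- equilibrium_state(params)
  sigma0 <- init$sigma_a + init$sigma_p
  kL <- calibration$pillar_spring_constant * calibration$tissue_length_um
  A_f <- calibration$tissue_cross_section_um2 * 1e-3  # kPa -> uN
  traj <- sim_force_controlled(wave$t_s, wave$value, .params_for_core(params),
                               .variant_code[["full"]], dt,
                               init$eps_a, init$eps_pl, kL, A_f, sigma0, 1e-6)
  traj <- as.data.frame(traj)
  strain <- time_series(traj$t, traj$eps_total, kind = "strain")
  dstress <- time_series(traj$t, traj$sigma_a + traj$sigma_p - sigma0,
                         kind = "stress", units = "kPa")
  sds <- c(stress = .resolve_sd(noise$stress_sd, noise$relative,
                                dstress$value),
           strain = .resolve_sd(noise$strain_sd, noise$relative,
                                strain$value))
  .with_seed(seed,
    .new_experiment("control", "full", params, protocol, sigma0, strain,
                    dstress, sds, seed, traj, dt,
                    extra = list(calibration = calibration,
                                 applied_force = wave)))
}

#' Generate a synthetic Triton-treated (matrix-only) experiment
#'
#' Emulates the stretch-unstretch protocol on a cell-lysed tissue: the
#' matrix-only reduced model driven directly by the prescribed strain
#' waveform from a tensile baseline. For protocols whose peak matrix stress
#' crosses the tensile yield, the residual plastic strain is positive and
#' permanent, and the post-unload stress shows no recovery (constant over
#' the observation window) — the signature that distinguishes lysed from
#' intact tissues.
#'
#' @param params `material_params` with `variant = "ecm_only"`.
#' @param protocol Strain-controlled `loading_protocol` (default
#'   [triton_protocol()]).
#' @param baseline_stress Tensile matrix baseline `sigma_0`, kPa; must lie
#'   inside the yield range (default 0.8).
#' @param noise,seed,dt As in [generate_control_experiment()].
#' @return A `synthetic_experiment`.
#' @export
generate_triton_experiment <- function(params = default_params("ecm_only"),
                                       protocol = triton_protocol(),
                                       baseline_stress = 0.8,
                                       noise = noise_model(), seed = 1L,
                                       dt = 0.05) {
  validate_material_params(params)
  if (params$variant != "ecm_only")
    stop("Triton experiments use the ecm_only variant", call. = FALSE)
  stopifnot(inherits(protocol, "loading_protocol"),
            protocol$kind == "strain", inherits(noise, "noise_model"))
  wave <- build_protocol_waveform(protocol)
  init <- equilibrium_state(params, baseline_stress = baseline_stress)
  sim <- simulate_stress_response(wave, params, init = init, dt = dt)
  strain <- time_series(wave$t_s, wave$value, kind = "strain")
  dstress <- incremental_series(sim$stress, baseline_stress)
  sds <- c(stress = .resolve_sd(noise$stress_sd, noise$relative,
                                dstress$value),
           strain = .resolve_sd(noise$strain_sd, noise$relative,
                                strain$value))
  .with_seed(seed,
    .new_experiment("triton", "ecm_only", params, protocol, baseline_stress,
                    strain, dstress, sds, seed, sim$trajectory, dt))
}

# Post layout of the synthetic single-cell force fields: posts on a ring,
# magnitudes biased toward the polarization axis so F_parallel > F_perp,
# directions pointing at the cell center.
.post_layout <- function(n_posts, bias = 2, radius_um = 20) {
  theta <- 2 * pi * (seq_len(n_posts) - 0.5) / n_posts
  w <- 1 + bias * cos(theta)^2
  list(theta = theta, weights = w / sum(w),
       x = radius_um * cos(theta), y = radius_um * sin(theta))
}

#' Generate a synthetic single-cell micropost experiment
#'
#' Emulates a smooth muscle cell on a micropost array under biaxial
#' stretch, represented by its scalar strain magnitude driving the
#' cell-only model in force units: total traction force F(t) in mN, with
#' baseline F(0) equal to the stall force. Per-post force fields are
#' synthesized at each frame with all forces pointing at the cell center
#' and magnitudes (in nN) summing exactly to F(t), biased toward the
#' polarization axis so the summed parallel component exceeds the
#' perpendicular one. [total_cell_force()] applied to a field recovers the
#' noiseless F(t) exactly.
#'
#' @param params Cell-only `material_params` in force units (default
#'   [default_cell_params()]).
#' @param protocol Strain-controlled protocol (default
#'   [single_cell_protocol()]).
#' @param n_posts Number of posts under the cell (>= 2, default 12).
#' @param noise,seed,dt As in [generate_control_experiment()].
#' @param frame_stride Emit a force field every this many samples
#'   (default 30).
#' @return A `synthetic_experiment` whose `stress`/`stress_noisy` series
#'   hold incremental total force (mN), with extra elements `fields` (list
#'   of `cell_force_field`, one per frame), `frame_times`, and
#'   `total_force` (absolute F(t), mN).
#' @export
generate_single_cell_experiment <- function(params = default_cell_params(),
                                            protocol = single_cell_protocol(),
                                            n_posts = 12,
                                            noise = noise_model(),
                                            seed = 1L, dt = 0.05,
                                            frame_stride = 30) {
  validate_material_params(params)
  if (params$variant != "cell_only")
    stop("single-cell experiments use the cell_only variant", call. = FALSE)
  if (n_posts < 2) stop("n_posts must be >= 2", call. = FALSE)
  stopifnot(inherits(protocol, "loading_protocol"),
            protocol$kind == "strain", inherits(noise, "noise_model"))
  wave <- build_protocol_waveform(protocol)
  init <- equilibrium_state(params)
  sim <- simulate_stress_response(wave, params, init = init, dt = dt)
  F0 <- params$sigma_max
  total_force <- time_series(sim$stress$t_s, sim$stress$value,
                             kind = "force", units = "mN")
  dforce <- incremental_series(total_force, F0)
  strain <- time_series(wave$t_s, wave$value, kind = "strain")

  layout <- .post_layout(n_posts)
  frame_idx <- seq(1, nrow(wave), by = frame_stride)
  fields <- lapply(frame_idx, function(i) {
    mags_nN <- layout$weights * total_force$value[i] * 1e6  # mN -> nN
    cell_force_field(layout$x, layout$y,
                     fx_nN = -mags_nN * cos(layout$theta),
                     fy_nN = -mags_nN * sin(layout$theta),
                     axis = c(1, 0))
  })
  sds <- c(stress = .resolve_sd(noise$stress_sd, noise$relative,
                                dforce$value),
           strain = .resolve_sd(noise$strain_sd, noise$relative,
                                strain$value))
  .with_seed(seed,
    .new_experiment("single_cell", "cell_only", params, protocol, F0,
                    strain, dforce, sds, seed, sim$trajectory, dt,
                    extra = list(fields = fields,
                                 frame_times = wave$t_s[frame_idx],
                                 total_force = total_force,
                                 n_posts = n_posts)))
}

#' Fit a synthetic experiment with the matching model variant
#'
#' Convenience wrapper: dispatches a `synthetic_experiment` to
#' [fit_experiment()] with the experiment's kind, baseline, and (by
#' default) its noisy series.
#'
#' @param experiment A `synthetic_experiment`.
#' @param config Optional `fit_config`.
#' @param use_noisy Fit the noisy series (default) or the noiseless ones.
#' @param ... Passed to [fit_config()] when `config` is NULL.
#' @return A `fit_result`.
#' @export
fit_synthetic <- function(experiment, config = NULL, use_noisy = TRUE, ...) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  strain <- if (use_noisy) experiment$strain_noisy else experiment$strain
  resp <- if (use_noisy) experiment$stress_noisy else experiment$stress
  fit_experiment(experiment$kind, strain, resp,
                 baseline = experiment$baseline_stress, config = config, ...)
}

#' Serialize a synthetic experiment to a directory
#'
#' Writes `config.yaml` (kind, generating parameters, protocol, baseline,
#' noise sds, seed) plus the strain/stress series as delimited text, and,
#' for single-cell experiments, per-frame force-field files under `posts/`.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- unclass(experiment$params)
  cfg <- list(kind = experiment$kind, variant = experiment$variant,
              params = p[setdiff(names(p), "variant")],
              protocol = unclass(experiment$protocol),
              baseline_stress = experiment$baseline_stress,
              noise_sds = as.list(experiment$noise_sds),
              seed = experiment$seed, dt = experiment$dt)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 12)
  write_time_series(experiment$strain, file.path(dir, "strain.csv"))
  write_time_series(experiment$stress, file.path(dir, "stress.csv"))
  write_time_series(experiment$strain_noisy,
                    file.path(dir, "strain_noisy.csv"))
  write_time_series(experiment$stress_noisy,
                    file.path(dir, "stress_noisy.csv"))
  if (!is.null(experiment$fields)) {
    pd <- file.path(dir, "posts")
    dir.create(pd, showWarnings = FALSE)
    for (i in seq_along(experiment$fields))
      write_cell_force_field(experiment$fields[[i]],
                             file.path(pd, sprintf("frame_%04d.csv", i)))
  }
  invisible(dir)
}

#' Read a serialized synthetic experiment directory
#'
#' @param dir Directory written by [write_experiment()].
#' @return A list with the config and the four series (`strain`, `stress`,
#'   `strain_noisy`, `stress_noisy`), plus `fields` when present.
#' @export
read_experiment <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  units <- if (identical(cfg$kind, "single_cell")) "mN" else "kPa"
  skind <- if (identical(cfg$kind, "single_cell")) "force" else "stress"
  out <- list(config = cfg,
              strain = read_time_series(file.path(dir, "strain.csv"),
                                        "strain", ""),
              stress = read_time_series(file.path(dir, "stress.csv"),
                                        skind, units),
              strain_noisy = read_time_series(
                file.path(dir, "strain_noisy.csv"), "strain", ""),
              stress_noisy = read_time_series(
                file.path(dir, "stress_noisy.csv"), skind, units))
  pd <- file.path(dir, "posts")
  if (dir.exists(pd)) {
    files <- sort(list.files(pd, pattern = "^frame_.*\\.csv$",
                             full.names = TRUE))
    out$fields <- lapply(files, read_cell_force_field)
  }
  out
}
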