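#' Normalized sum of squared residuals between model and data
#'
#' The fit objective: `chi2 = sum_i (m_i - d_i)^2 / sum_i d_i^2`, i.e. the
#' residual sum of squares normalized by the summed squared data. The
#' normalization makes the statistic scale-free, so the convergence
#' threshold 2.5e-3 is comparable across tissues and units. Zero iff the
#' series are identical; 1 for an identically-zero model.
#'
#' @param model_stress,measured_stress `time_series` on identical time
#'   grids.
#' @return Dimensionless chi-squared, >= 0.
#' @export
chi_squared <- function(model_stress, measured_stress) {
  stopifnot(inherits(model_stress, "time_series"),
            inherits(measured_stress, "time_series"))
  if (!.same_grid(model_stress, measured_stress))
    stop("model and measured series must share the same time grid",
         call. = FALSE)
  denom <- sum(measured_stress$value^2)
  if (denom == 0)
    stop("normalization undefined: measured series is identically zero",
         call. = FALSE)
  sum((model_stress$value - measured_stress$value)^2) / denom
}

#' Default log-uniform search bounds
#'
#' Four decades around plausible magnitudes: stiffnesses 1..1e3 kPa,
#' viscosities 1e2..1e6 kPa·s, stresses 0.1..100 kPa. For single-cell fits
#' in force units the ranges shift accordingly (stiffness and stall force in
#' mN, viscosity in mN·s).
#'
#' @param variant Model variant.
#' @param force_units Use single-cell force-unit ranges.
#' @return Named list of `c(lower, upper)` per free parameter.
#' @export
default_bounds <- function(variant = "full", force_units = FALSE) {
  variant <- .check_variant(variant)
  if (force_units) {
    cell <- list(E_s = c(1e-5, 1e-1), eta_a = c(1e-3, 1e1),
                 sigma_max = c(1e-6, 1e-2))
  } else {
    cell <- list(E_s = c(1, 1e3), eta_a = c(1e2, 1e6),
                 sigma_max = c(0.1, 100))
  }
  ecm <- list(E_p = c(1, 1e3), eta_p = c(1e2, 1e6),
              sigma_Y_t = c(0.1, 100), sigma_Y_c = c(0.1, 100))
  switch(variant,
         full = c(cell, ecm),
         ecm_only = ecm,
         cell_only = cell)
}

#' Configuration of the random-search fit
#'
#' @param variant Model variant to fit.
#' @param bounds Named list of `c(lower, upper)` log-uniform search ranges
#'   per free parameter (see [default_bounds()]).
#' @param seed Integer RNG seed; identical seed and inputs give identical
#'   results.
#' @param max_iterations Iteration budget (>= 1); each iteration evaluates
#'   one candidate parameter vector.
#' @param chi2_threshold Stop once the best chi-squared falls below this
#'   (default 2.5e-3, the study's convergence threshold).
#' @param stall_tol,stall_window Stagnation rule: if the relative
#'   improvement of the best chi-squared over `stall_window` consecutive
#'   iterations stays below `stall_tol`, the proposal step is shrunk; after
#'   `max_shrinks` such shrinks a further stagnant window stops the search
#'   (convergence reason `"stall"`).
#' @param step_sigma Initial proposal scale: sd of the log10-space Gaussian
#'   perturbation around the incumbent (default 0.3 decades).
#' @param step_shrink Multiplier applied to `step_sigma` at each stall
#'   (default 0.5).
#' @param max_shrinks Number of shrinks before the step scale reaches its
#'   floor (`step_sigma * step_shrink^max_shrinks`). At the floor the
#'   search keeps proposing at that scale — this fine, improvement-directed
#'   random walk is what descends the narrow curved valleys produced by
#'   strongly correlated parameter pairs (yield stress and plastic
#'   viscosity) — and a descent is declared stalled only after
#'   `10 * stall_window` consecutive iterations without significant
#'   improvement.
#' @param restart_on_stall When a descent stalls and budget remains, start
#'   a fresh descent from new uniform-in-log draws while keeping the global
#'   best (default TRUE). Random restarts are what escape the model's
#'   competing local basin in which a low-yield matrix branch mimics the
#'   cell branch's viscoelasticity. With FALSE the first stall ends the
#'   search.
#' @param wide_prob Probability that an individual proposal coordinate is
#'   redrawn uniform-in-log over its full bound range instead of perturbed
#'   around the incumbent (default 0.1). This lets the search cross regions
#'   where the objective is flat in one parameter — e.g. any yield stress
#'   above the peak matrix stress fits identically — which pure local
#'   perturbation with improvement-only acceptance cannot traverse.
#' @param tie_yields Fit a single yield stress with
#'   `sigma_Y_c = sigma_Y_t` (default TRUE; the stretch protocols probe only
#'   the tensile branch, so an independent compressive yield is
#'   unidentifiable).
#' @param n_init Number of initial uniform-in-log draws before perturbation
#'   sampling starts (counted against the budget).
#' @param dt Integrator step used in fit evaluations, s.
#' @return A `fit_config` object.
#' @export
fit_config <- function(variant = "full", bounds = NULL, seed = 1L,
                       max_iterations = 4000L, chi2_threshold = 2.5e-3,
                       stall_tol = 1e-4, stall_window = 200L,
                       step_sigma = 0.3, step_shrink = 0.5,
                       max_shrinks = 10L, wide_prob = 0.1,
                       restart_on_stall = TRUE, tie_yields = TRUE,
                       n_init = 32L, dt = 0.05) {
  variant <- .check_variant(variant)
  if (is.null(bounds)) bounds <- default_bounds(variant)
  if (isTRUE(tie_yields)) bounds$sigma_Y_c <- NULL
  if (!all(vapply(bounds, function(b) length(b) == 2 && all(b > 0) &&
                    b[1] <= b[2], logical(1))))
    stop("bounds must be positive ordered pairs", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (chi2_threshold <= 0 || stall_tol <= 0 || stall_window < 1)
    stop("thresholds must be positive", call. = FALSE)
  cfg <- list(variant = variant, bounds = bounds, seed = as.integer(seed),
              max_iterations = as.integer(max_iterations),
              chi2_threshold = chi2_threshold, stall_tol = stall_tol,
              stall_window = as.integer(stall_window),
              step_sigma = step_sigma, step_shrink = step_shrink,
              max_shrinks = as.integer(max_shrinks), wide_prob = wide_prob,
              restart_on_stall = isTRUE(restart_on_stall),
              tie_yields = isTRUE(tie_yields),
              n_init = as.integer(n_init), dt = dt)
  class(cfg) <- "fit_config"
  cfg
}

# Assemble a material_params object from a named free-parameter vector
.assemble_params <- function(theta, variant, tie_yields) {
  g <- function(nm, d = NA_real_) if (nm %in% names(theta)) theta[[nm]] else d
  sYt <- g("sigma_Y_t"); sYc <- if (tie_yields) sYt else g("sigma_Y_c")
  material_params(E_s = g("E_s"), eta_a = g("eta_a"),
                  sigma_max = g("sigma_max"), E_p = g("E_p"),
                  eta_p = g("eta_p"), sigma_Y_t = sYt, sigma_Y_c = sYc,
                  variant = variant)
}

# Fast objective closure over fixed data: absolute-stress chi-squared of a
# candidate free-parameter vector. Candidates whose baseline partition
# violates the no-flow condition are infeasible (Inf).
.make_objective <- function(strain, measured_abs, variant, dt,
                            baseline_stress, baseline_matrix_stress,
                            tie_yields) {
  t_v <- strain$t_s; e_v <- strain$value; d_v <- measured_abs$value
  denom <- sum(d_v^2)
  if (denom == 0)
    stop("normalization undefined: measured series is identically zero",
         call. = FALSE)
  code <- .variant_code[[variant]]
  # Baseline partition: for the full variant the matrix baseline defaults to
  # 0 (matrix contribution folded into sigma_max), so the candidate's
  # stationary stress equals its stall stress and the measured baseline
  # level identifies sigma_max. For ecm_only the matrix carries the whole
  # measured baseline.
  eq_baseline <- if (variant == "ecm_only") baseline_stress else NULL
  function(theta) {
    p <- tryCatch(.assemble_params(theta, variant, tie_yields),
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)
    init <- tryCatch(
      equilibrium_state(p, baseline_stress = eq_baseline,
                        baseline_matrix_stress = baseline_matrix_stress),
      error = function(e) NULL)
    if (is.null(init)) return(Inf)
    traj <- sim_strain_driven(t_v, e_v, .params_for_core(p), code, dt,
                              init$eps_a, init$eps_pl)
    m <- traj[, 5] + traj[, 6]
    sum((m - d_v)^2) / denom
  }
}

#' Random-search least-squares fit of the constitutive model
#'
#' Fits the chosen model variant to a measured stress (or force) record,
#' with the measured strain taken as known input, by seeded random search:
#' an initial batch of uniform-in-log draws within the bounds, then
#' multiplicative log-normal perturbations around the incumbent, accepting
#' only improvements of the normalized chi-squared, with the perturbation
#' scale halved whenever progress stagnates. Stops at the chi-squared
#' threshold, on stall, or when the iteration budget is exhausted.
#'
#' The fit runs in absolute variables: the candidate model is initialized
#' at its own stationary baseline (matrix partition `sigma_p0` = 0 for the
#' full variant unless overridden; = `baseline_stress` for ecm_only) and its
#' absolute stress is compared against `measured_stress`. Fitting absolute
#' rather than incremental stress is what makes the stall stress
#' identifiable: it must reproduce the measured baseline level.
#'
#' @param strain `time_series` of measured incremental strain (the model
#'   input).
#' @param measured_stress `time_series` of measured absolute stress (kPa; or
#'   total force for single-cell fits), on the same grid as `strain`.
#' @param config A `fit_config`.
#' @param baseline_stress Measured baseline `sigma_0` (used for the
#'   ecm_only matrix partition); defaults to the first stress sample.
#' @param baseline_matrix_stress Optional explicit matrix partition for the
#'   full variant.
#' @return A `fit_result`: best `material_params`, final `chi2`,
#'   `iterations`, non-increasing per-iteration `trace`, `seed`,
#'   `convergence` reason (`"threshold"`, `"stall"`, `"max_iter"`).
#' @export
random_search_fit <- function(strain, measured_stress, config,
                              baseline_stress = NULL,
                              baseline_matrix_stress = NULL) {
  stopifnot(inherits(strain, "time_series"),
            inherits(measured_stress, "time_series"),
            inherits(config, "fit_config"))
  if (!.same_grid(strain, measured_stress))
    stop("strain and stress series must share the same time grid",
         call. = FALSE)
  if (is.null(baseline_stress)) baseline_stress <- measured_stress$value[1]

  obj <- .make_objective(strain, measured_stress, config$variant, config$dt,
                         baseline_stress, baseline_matrix_stress,
                         config$tie_yields)

  # seeded local RNG; caller's RNG state is restored on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  nm <- names(config$bounds)
  lo <- log10(vapply(config$bounds, `[`, numeric(1), 1))
  hi <- log10(vapply(config$bounds, `[`, numeric(1), 2))
  names(lo) <- names(hi) <- nm

  best_theta <- NULL; best_chi2 <- Inf
  trace <- numeric(config$max_iterations)
  reason <- "max_iter"; it <- 0L

  # state of the current descent; reset at every restart
  cur_theta <- NULL; cur_chi2 <- Inf
  draws_left <- config$n_init
  sigma <- config$step_sigma
  since_improve <- 0L; shrinks <- 0L

  while (it < config$max_iterations) {
    it <- it + 1L
    if (draws_left > 0L || is.null(cur_theta)) {
      lth <- lo + runif(length(nm)) * (hi - lo)
      draws_left <- draws_left - 1L
    } else {
      lth <- pmin(pmax(log10(cur_theta) + rnorm(length(nm), 0, sigma), lo),
                  hi)
      wide <- runif(length(nm)) < config$wide_prob
      if (any(wide))
        lth[wide] <- lo[wide] + runif(sum(wide)) * (hi - lo)[wide]
    }
    theta <- stats::setNames(10^lth, nm)
    chi2 <- obj(theta)
    if (is.finite(chi2) && chi2 < cur_chi2) {
      improved <- is.infinite(cur_chi2) ||
        (cur_chi2 - chi2) / cur_chi2 > config$stall_tol
      if (improved) since_improve <- 0L
      cur_chi2 <- chi2; cur_theta <- theta
    }
    if (is.finite(chi2) && chi2 < best_chi2) {
      best_chi2 <- chi2; best_theta <- theta
    }
    trace[it] <- best_chi2
    if (best_chi2 < config$chi2_threshold) { reason <- "threshold"; break }
    since_improve <- since_improve + 1L
    if (draws_left <= 0L && since_improve >= config$stall_window) {
      if (shrinks < config$max_shrinks) {
        sigma <- sigma * config$step_shrink
        shrinks <- shrinks + 1L
        since_improve <- 0L
      } else if (since_improve >= 10L * config$stall_window) {
        if (config$restart_on_stall &&
            it + config$n_init < config$max_iterations) {
          cur_theta <- NULL; cur_chi2 <- Inf
          draws_left <- config$n_init
          sigma <- config$step_sigma
          since_improve <- 0L; shrinks <- 0L
        } else {
          reason <- "stall"
          break
        }
      }
    }
  }
  trace <- trace[seq_len(it)]

  if (is.null(best_theta))
    stop("no feasible candidate found within the iteration budget",
         call. = FALSE)
  best_params <- .assemble_params(best_theta, config$variant,
                                  config$tie_yields)
  res <- list(params = best_params, chi2 = obj(best_theta), iterations = it,
              trace = trace, seed = config$seed, convergence = reason,
              config = config, baseline_stress = baseline_stress,
              n_obs = nrow(strain))
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): chi2 = %.4g after %d iterations (%s), seed %d\n",
              x$params$variant, x$chi2, x$iterations, x$convergence, x$seed))
  print(x$params)
  invisible(x)
}

#' Fit a control, Triton-treated, or single-cell experiment
#'
#' Dispatches to [random_search_fit()] with the variant and search space of
#' the experiment kind: `control` fits the full model (all seven constants,
#' yields tied by default), `triton` the matrix-only reduced model (cell
#' branch and its parameters excluded from the search), `single_cell` the
#' cell-only model in force units (mN, mN·s; matrix parameters excluded).
#' The measured incremental response plus its baseline are combined into
#' the absolute record the search compares against.
#'
#' @param kind `"control"`, `"triton"`, or `"single_cell"`.
#' @param strain `time_series` of measured incremental strain.
#' @param response `time_series` of measured incremental stress (kPa) or,
#'   for `single_cell`, incremental total force (mN).
#' @param baseline Measured baseline stress `sigma_0` (kPa) or baseline
#'   total force (mN).
#' @param config Optional `fit_config`; defaults to the kind's variant with
#'   its default bounds.
#' @param ... Passed to [fit_config()] when `config` is NULL.
#' @return A `fit_result`.
#' @export
fit_experiment <- function(kind = c("control", "triton", "single_cell"),
                           strain, response, baseline, config = NULL, ...) {
  kind <- match.arg(kind)
  variant <- switch(kind, control = "full", triton = "ecm_only",
                    single_cell = "cell_only")
  if (is.null(config)) {
    bounds <- default_bounds(variant, force_units = kind == "single_cell")
    config <- fit_config(variant = variant, bounds = bounds, ...)
  }
  if (config$variant != variant)
    stop(sprintf("config variant '%s' does not match kind '%s'",
                 config$variant, kind), call. = FALSE)
  absolute <- time_series(response$t_s, response$value + baseline,
                          kind = attr(response, "kind"),
                          units = attr(response, "units"))
  random_search_fit(strain, absolute, config, baseline_stress = baseline)
}

#' One-dimensional chi-squared sensitivity profile of a fitted parameter
#'
#' Re-evaluates the fit objective along a grid of values of one parameter,
#' all others held at their fitted values. Flat profiles (small max/min
#' chi-squared ratio) flag parameters the data do not constrain — for
#' control tissues this reproduces the insensitivity to the matrix
#' parameters expected when cell contraction shields the matrix from
#' yielding.
#'
#' @param fit A `fit_result`.
#' @param strain,measured_stress The series the fit used (`measured_stress`
#'   absolute, as in [random_search_fit()]).
#' @param param_name Name of a free parameter of the fit.
#' @param grid Numeric vector of parameter values to profile.
#' @param flat_ratio Profiles with `max(chi2)/min(chi2)` below this are
#'   flagged unidentifiable (default 1.1).
#' @return A data.frame with columns `value`, `chi2`, and attributes
#'   `flat` (logical) and `ratio`.
#' @export
ecm_sensitivity_profile <- function(fit, strain, measured_stress, param_name,
                                    grid, flat_ratio = 1.1) {
  stopifnot(inherits(fit, "fit_result"))
  cfg <- fit$config
  if (!param_name %in% names(cfg$bounds))
    stop("unknown free parameter: ", param_name, call. = FALSE)
  obj <- .make_objective(strain, measured_stress, cfg$variant, cfg$dt,
                         fit$baseline_stress, NULL, cfg$tie_yields)
  base <- unlist(unclass(fit$params)[names(cfg$bounds)])
  chi2 <- vapply(grid, function(v) {
    th <- base; th[[param_name]] <- v; obj(th)
  }, numeric(1))
  out <- data.frame(value = grid, chi2 = chi2)
  fin <- chi2[is.finite(chi2)]
  ratio <- if (length(fin) > 0 && min(fin) > 0) max(fin) / min(fin) else Inf
  attr(out, "ratio") <- ratio
  attr(out, "flat") <- ratio < flat_ratio
  out
}

#' Write a fit result as a structured text report
#'
#' YAML report (parameters, chi-squared, convergence reason, seed, sample
#' count) plus, optionally, the best-chi-squared trace as delimited text.
#'
#' @param fit A `fit_result`.
#' @param path Report path (YAML).
#' @param trace_path Optional path for the `iteration,chi2` trace CSV.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, trace_path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  p <- unclass(fit$params)
  rep <- list(variant = fit$params$variant,
              parameters = p[setdiff(names(p), "variant")],
              chi2 = fit$chi2, iterations = fit$iterations,
              convergence = fit$convergence, seed = fit$seed,
              baseline = fit$baseline_stress, n_obs = fit$n_obs)
  yaml::write_yaml(rep, path, precision = 12)
  if (!is.null(trace_path)) {
    con <- file(trace_path, open = "wb")
    writeLines(c("iteration,chi2",
                 paste(seq_along(fit$trace),
                       formatC(fit$trace, digits = 12, format = "g"),
                       sep = ",")), con, sep = "\n")
    close(con)
  }
  invisible(path)
}
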