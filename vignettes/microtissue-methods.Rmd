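---
title: "Modeling active viscoplastic mechanics of engineered microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling active viscoplastic mechanics of engineered microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtissue)
```

## The mechanical model

Engineered microtissues — smooth muscle cells compacting a collagen/fibrin
matrix between two flexible PDMS micropillars — respond to an applied
stretch with a mixture of active (cell-generated), viscoelastic, and
plastic behavior. `microtissue` implements a three-element uniaxial
constitutive model that separates these contributions:

* an **active contractile element** (Hill-type) in series with a **linear
  spring** `E_s`, together representing the cells (actomyosin contraction
  plus the stiffness of actin structures, cell-cell contacts, and taut
  inter-cell matrix regions);
* in parallel, an **elastic perfectly viscoplastic element** (`E_p`,
  `eta_p`, yield stresses `sigma_Y_t`, `sigma_Y_c`; a Bingham-Norton
  solid) representing the bulk extracellular matrix.

With total strain $\varepsilon$ decomposed as
$\varepsilon = \varepsilon_a + \varepsilon_s$ on the cell branch and the
parallel element sharing the total strain, the governing equations are

$$\sigma = \sigma_a + \sigma_p, \qquad
  \sigma_a = E_s(\varepsilon - \varepsilon_a), \qquad
  \sigma_p = E_p(\varepsilon - \varepsilon_{pl}),$$

$$\dot\varepsilon_a = \frac{\sigma_a - \sigma_{max}}{\eta_a}, \qquad
  \dot\varepsilon_{pl} = \begin{cases}
    (\sigma_p - \sigma_Y^t)/\eta_p & \sigma_p > \sigma_Y^t \\
    0 & -\sigma_Y^c \le \sigma_p \le \sigma_Y^t \\
    (\sigma_p + \sigma_Y^c)/\eta_p & \sigma_p < -\sigma_Y^c.
  \end{cases}$$

The active law is the linearized Hill relation: the strain rate is
proportional to the distance of the branch stress from the stall stress
$\sigma_{max}$, with active viscosity $\eta_a$ setting the slope; the
element shortens below stall and lengthens above it. The flow rule is the
standard overstress form, continuous at the yield surfaces (stress exactly
at yield is treated as elastic), which is also why time integration needs
no event detection. Linear elasticity is assumed throughout: the strains
of interest (a few percent) sit below the strain-stiffening threshold of
collagen/fibrin gels, and yield stresses are taken constant for the same
reason.

Three variants are exposed: `full` (intact tissue), `ecm_only` (cell-lysed
tissue; the active branch removed), and `cell_only` (a single cell on a
micropost array; no parallel matrix). The `cell_only` variant is fitted in
force units (mN, mN·s) because single-cell data are total traction forces,
not stresses.

### Reference configuration and baselines

The reference state is the tissue after contractile activation and matrix
compaction, before external force. At equilibrium the active rate
vanishes, so the cell branch carries exactly $\sigma_{max}$; the matrix
carries a baseline partition $\sigma_{p0}$ that must lie inside the yield
range (no flow at rest). For intact tissues the partition is
unidentifiable — the model's fit quality is insensitive to it — so
`equilibrium_state()` defaults to $\sigma_{p0}=0$, folding the matrix
contribution into $\sigma_{max}$. For lysed tissues the matrix carries the
whole (tensile) baseline, which therefore must not exceed $\sigma_Y^t$;
the generator default is 0.8 kPa for that reason, and the constructor
rejects inconsistent baselines.

## Parameters and defaults

| Parameter | Meaning | Units | Fixture default |
|---|---|---|---|
| `E_s` | series (cell-branch) stiffness | kPa | 500 |
| `eta_a` | active viscosity | kPa·s | 2e4 |
| `sigma_max` | stall stress | kPa | 6 |
| `E_p` | parallel (matrix) stiffness | kPa | 50 |
| `eta_p` | plastic viscosity | kPa·s | 1e5 |
| `sigma_Y_t`, `sigma_Y_c` | tensile / compressive yield | kPa | 1, 1 |

The fixture set (`default_params()`) was chosen once to reproduce the
qualitative stretch-unstretch phenomenology of intact tissues at
percent-level strains. The choice of `eta_a` deserves a note: the strain
peak can lag the stress peak in a force-controlled stretch only when the
active relaxation time $\eta_a/E_s$ is comparable to or shorter than the
unloading ramp. With $\eta_a/E_s = 40$ s against 120 s ramps, the model
shows a ~40 s lag, a clear post-unload stress undershoot with monotone
active recovery, and a matrix stress that never leaves its yield range
(peak $|\sigma_p| \approx 0.6$ kPa < 1 kPa) — the shielding effect that is
the model's central qualitative prediction. Relaxation times of 100 s or
more abolish the lag entirely under this protocol.

Device calibration defaults (`device_calibration()`): pillar spring
constant 0.59 uN/um, micropost spring constant 22 nN/um, effective tissue
length 500 um, and cross-section 8000 um². The geometric values are the
package's own choices, set so that a ~28 uN peak force produces roughly 2%
strain under the fixture parameters; an optional monotone force-deflection
table replaces the linear pillar law when pillar deflections leave the
linear regime (monotone Hermite interpolation, extrapolation refused).

## Forward simulation

`simulate_stress_response()` integrates the two internal state variables
$(\varepsilon_a, \varepsilon_{pl})$ with a fixed-step explicit 4th-order
Runge-Kutta scheme, `dt = 0.05` s by default, with the prescribed total
strain interpolated linearly between samples and every output sample hit
exactly (intervals are subdivided evenly). `dt` may not exceed half the
smallest sampling interval. The continuity of the overstress rule makes
yield crossings benign; the test suite holds the integrator to within 1%
of a `dt = 1e-3` s explicit-Euler brute-force oracle on randomized
yield-crossing protocols, and to within 0.1% of the closed-form
standard-linear-solid step response
$\delta\sigma(t) = \delta\varepsilon\,(E_p + E_s e^{-E_s t/\eta_a})$ when
plasticity is disabled.

## Synthetic experiments

The generators stand in for the study's raw data so the whole pipeline is
testable end to end.

* **Control** (`generate_control_experiment()`): force-controlled. The
  applied load ramps 0 → 25 uN over 120 s, back down over 120 s, then a
  900 s observation at zero load, sampled at 1 s. At every sample the
  balance $kL\,\delta\varepsilon + A\,\delta\sigma = F_{mag}$ (pillar
  restoring force plus tissue stress increment against the applied
  magnetic force) is solved for the strain by bisection to 1e-6 uN; the
  tissue model is advanced inside each bisection trial, so strain and
  stress come out self-consistently coupled.
* **Triton** (`generate_triton_experiment()`): the matrix-only variant
  driven directly by a strain trapezoid (default peak 5%, 120/120/900 s)
  from a tensile baseline of 0.8 kPa. The default protocol crosses the
  tensile yield, leaving a positive, permanent residual plastic strain and
  a post-unload stress with no recovery.
* **Single cell** (`generate_single_cell_experiment()`): the cell-only
  variant in force units under a 10%-over-3-min biaxial stretch,
  represented by its scalar strain magnitude (the measured response is
  dominated by the component along the cell's polarization axis).
  Per-post force fields are synthesized on a ring of posts with
  magnitudes summing exactly to the model's total force and biased toward
  the polarization axis, so `total_cell_force()` round-trips F(t) and
  $F_\parallel > F_\perp$ in every frame.

Measurement noise is additive white Gaussian per channel; the default sd
is 2% of the peak incremental signal, a plausible scale for bead-tracking
readout (the underlying studies report no noise figures). The generators
are pure functions of (parameters, protocol, noise, seed).

What the generators do **not** emulate: image formation and tracking
error structure (correlated, outlier-prone in real data), pillar
nonlinearity, tissue-to-tissue parameter variability, strain stiffening,
or the tissue formation/compaction history. Passing recovery tests on
these data therefore demonstrates the estimator's correctness and the
protocol's information content under the model's own assumptions, not
robustness to model misspecification.

## Fitting

`random_search_fit()` minimizes the normalized residual
$\chi^2 = \sum_i (m_i - d_i)^2 / \sum_i d_i^2$. The normalization by the
summed squared data makes the statistic scale-free, so the convergence
threshold $2.5\times10^{-3}$ is meaningful across tissues and across
stress/force units.

Fits run in **absolute** variables: the measured incremental response plus
its baseline is compared against the candidate model started from its own
stationary state. This is a deliberate choice: with the $\sigma_{p0}=0$
partition, $\sigma_{max}$ cancels from the incremental dynamics and would
be unidentifiable from the incremental series alone, whereas the absolute
baseline level pins it directly.

The search is a seeded adaptive random search:

1. `n_init` uniform-in-log draws inside the bounds (4 decades around
   plausible magnitudes by default);
2. multiplicative log-normal perturbations around the incumbent (sd 0.3
   in log10 space), accepting improvements only, with each coordinate
   redrawn uniformly over its full range with probability 0.1 — without
   this, the search cannot traverse regions where $\chi^2$ is exactly
   flat in one parameter (any yield stress above the peak matrix stress
   fits identically);
3. the step sd is halved whenever a `stall_window` passes without
   relative improvement above `stall_tol` (1e-4), down to a floor after
   `max_shrinks` halvings; the fine-scale improvement-directed walk at the
   floor is what descends the narrow curved valley traced by the
   strongly correlated pair (`sigma_Y_t`, `eta_p`);
4. when a descent exhausts 10 stall windows at the floor, the search
   restarts from fresh uniform draws, keeping the global best. Restarts
   matter because the model has a genuine competing local basin in which
   a low-yield, moderate-viscosity matrix branch imitates the cell
   branch's viscoelasticity.

Stopping: the $\chi^2$ threshold, budget exhaustion, or a stall with
restarts disabled. Identical seed and inputs give bitwise-identical
results; the incumbent trace is non-increasing and the reported $\chi^2$
is recomputed from the returned parameters.

`fit_experiment()` maps experiment kinds to variants and search spaces:
`control` → full model, `triton` → matrix-only (cell parameters excluded),
`single_cell` → cell-only in force units. The compressive yield is tied to
the tensile one by default (`tie_yields`): the stretch protocols never
probe compressive yielding, so an independent $\sigma_Y^c$ is
unidentifiable; untying is available for protocols that do.

Candidates whose baseline partition violates the no-flow condition (for a
lysed-tissue fit, $\sigma_Y^t$ below the measured baseline) are treated as
infeasible rather than as errors, which also steers the search toward the
physically admissible region.

## Identifiability

`ecm_sensitivity_profile()` sweeps one parameter with the others fixed.
On control-type data with the fixture parameters, cell contraction keeps
$|\sigma_p|$ strictly inside the yield range, so the profiles in
`sigma_Y_t` and `eta_p` are flat (max/min $\chi^2$ ratio below 1.1 over a
decade-wide sweep) while the profile in `E_s` varies by orders of
magnitude — the practical meaning of plastic shielding for parameter
estimation.

Two quantitative limits are worth stating plainly:

* **Noise-free recovery.** With the default protocols and fixture values,
  the random search recovers the cell-branch constants from control data
  and the matrix constants from yield-crossing lysed-tissue data to well
  under 5% (typically < 1%), at the budgets used in the test suite
  (~2.5×10⁵ iterations, under three minutes per fit on one CPU).
* **Noisy yield/viscosity recovery is data-limited.** With noise at 5% of
  the peak signal, the profile likelihood along the
  (`sigma_Y_t`, `eta_p`) ridge of the default lysed-tissue protocol is
  flat to ~0.1%, and its minimum wanders far from the generating values
  from one noise realization to the next. The plastic signature under
  these conditions (flow time $\eta_p/E_p = 2000$ s against a 240 s
  loading window) is simply too small relative to the noise; no estimator
  could do better from the same data. `E_p` remains sharply identified,
  as do all cell-branch constants on control data (within a few percent
  at this noise level).

Noise for the recovery analyses is applied to the measured stress/force
channel only; the procedure takes the measured strain as known input, and
noise on an *input* channel produces the classical errors-in-variables
attenuation of stiffness estimates, a separate phenomenon from estimator
quality.

## Other design decisions

* **Single-cell bridge to tissue viscosity.** The tissue-level active
  viscosity estimate scales the single-cell value by the cross-sectional
  areal cell density, $\eta_a^{tissue} = \rho_A\,\eta_a^{cell}$
  (1 mN/um² = 10⁶ kPa). The bridge from volumetric to areal density is
  taken as $\rho_A = \rho_c^{2/3}$, the dimensional choice for roughly
  isotropic cell spacing; it is a plain exported function
  (`areal_density_from_volumetric()`) precisely so it can be replaced.
* **Unit conventions.** Seconds, dimensionless strain, kPa, kPa·s
  package-wide; forces in uN (pillars), nN (microposts), mN (single-cell
  fits). Stress from force uses 1 uN/um² = 10³ kPa.
* **Text formats.** Time series as `t_s,value` CSV at 12 significant
  digits (lossless round trip at that precision); force fields as
  `post_id,x_um,y_um,fx_nN,fy_nN`; configurations and fit reports as
  YAML. The command-line layer (`run_cli()`, with an installable wrapper
  script) writes a run log with package version, seed, and a config
  digest alongside every output.

## Problem sizes

The test suite exercises full-length protocols (1141 samples at 1 s) for
generation, phenomenology, and fitting; integrator-versus-oracle
comparisons use 60 s randomized protocols against a 1 ms explicit-Euler
oracle; recovery fits use a 0.5 s integrator step (indistinguishable from
0.05 s at these relaxation times) with budgets of 8×10⁴–2.5×10⁵
iterations. The complete suite runs in a few minutes on one CPU.

## Known limitations

Uniaxial small-strain kinematics only; no strain stiffening or
tension/compression asymmetry in `E_p` within a single fit (intact and
lysed tissues are fitted separately instead); constant yield stresses; no
uncertainty quantification beyond 1-D sensitivity profiles; the random
search is the only optimizer (by design — gradient-based refinement would
change the procedure being modeled); synthetic data share the fitted
model's functional form, so recovery tests cannot detect structural
misspecification.
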