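---
title: "Single-cycle BLI kinetics: models, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cycle BLI kinetics: models, fitting and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbli)
```

## The measurement and its model

In a single-cycle (kinetic-titration) BLI run, one biosensor carrying an
immobilised binder visits a series of analyte wells of strictly increasing
concentration. Short buffer transfers ("mini-dissociations", 30 s by
default) separate the wells, and the run ends with one extended
dissociation. Because a single sensor sees every concentration, all
segments must be fitted **globally**: the free parameters are shared across
segments and each segment's start value is the previous segment's end.

The forward model assumes mass-action 1:1 binding with homogeneous ligand
and analyte. Association in well $i$ relaxes exponentially towards the
Langmuir equilibrium response at the observed rate $k_{on}C_i + k_{off}$;
dissociations decay at $k_{off}$. Under these assumptions the piecewise
closed form used by `predict_trace()` is the exact solution of
$dR/dt = k_{on} C (R_{max} - R) - k_{off} R$ with piecewise-constant $C$,
which is what the test suite verifies against independent ODE integration
(`deSolve::lsoda`, segment-restarted, tolerances $10^{-12}$), agreeing to
better than $10^{-8}$ nm over random rate draws spanning
$k_{on} \in [10^4, 10^7]$ M$^{-1}$s$^{-1}$, $k_{off} \in [10^{-6}, 1]$
s$^{-1}$.

Real traces sometimes decay towards a non-zero plateau. The
partial-dissociation variants keep the association form and replace each
decay with $R(t) = (R_0^i - R_{\infty,i})e^{-k_{off}(t - t_0)} +
R_{\infty,i}$. We parametrise the plateau either **globally** through one
mobile-fraction parameter $\varphi$ with $R_{\infty,i} = \varphi R_0^i$
(the default: one extra parameter, hard to over-fit) or **locally** with
one free plateau per dissociation segment. $\varphi$ is capped at 0.95 so
that at least 5% of the signal must eventually decay; a flatter
dissociation is better read as a very tight binder than as partial
dissociation, and should instead prompt a longer final dissociation.
$\varphi = 0$ reduces both variants exactly to the standard model, a
property the tests assert pointwise.

Two modelling caveats are deliberate. First, in global mode the immobile
fraction left by a mini-dissociation carries into the next association only
through the propagated start value; $R_{max}$ is *not* reduced by the
accumulated immobile population. This implements the plateau rule literally
and keeps the parameter count at four; a re-association ceiling that shrinks
with the immobile fraction would be a physically motivated extension, but it
changes the model class and is not provided. Second, local plateaus are
clamped to $[0, R_0^i]$ at evaluation time, since a decay cannot rise to its
plateau.

## Parameters that matter

| Parameter | Units | Default / bounds | Why |
|---|---|---|---|
| `k_on` | M⁻¹s⁻¹ | fit bounds $[10^2, 10^8]$ | brackets BLI's practical dynamic range (≈10 pM–1 mM affinities) |
| `k_off` | s⁻¹ | fit bounds $[10^{-7}, 1]$ | slower off-rates are indistinguishable from drift within a 600–1200 s dissociation |
| `R_max` | nm | bounds $(0, 10]$ | an order of magnitude above typical loadings (0.1–0.8 nm) |
| `phi` | — | $[0, 0.95]$ | see above |
| association dwells | s | 300→100, tapered | low-concentration wells approach steady state slowest, so they get the longest dwell |
| mini-dissociation | s | 30 | long enough to see curvature between wells, short enough to limit drift exposure |
| final dissociation | s | 600 (option 1200) | the only segment carrying most of the $k_{off}$ information |
| simulator `sigma` | nm | 0.005 | mid-range of realistic per-trace fit RMSEs (≈0.0035–0.018 nm) |
| simulator grid | s | 0.5 | BLI-like acquisition cadence; prediction grid defaults to 1 s |

Concentration series: configs accept nM (the unit people pipette in);
everything internal is molar. The schedule validator enforces the
lowest-to-highest ordering that single-cycle assays require — reversing the
series would make early wells deplete the fast-association signal and break
the tapered-dwell logic.

## Fitting: numerical choices

* **Objective.** Unweighted sum of squared residuals over all kinetic
  samples jointly (per-segment weights are exposed in `fit_options()` but
  off: there is no principled default weighting, and unweighted residuals
  make the reported RMSE interpretable in nm).
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  $\log_{10} k_{on}, \log_{10} k_{off}, \log_{10} R_{max}$ — the rates span
  decades and the log scale makes the problem well-conditioned — with
  $\varphi$ and plateaus on their natural scale. Tolerances are tight
  (`ftol = ptol = 1e-13`) so noiseless recovery reaches machine precision.
* **Starts.** A data-driven initial guess: $k_{off}$ from a log-linear
  regression on the final dissociation; per-well observed rates (profiled
  1-D exponential fits) regressed on concentration for $k_{on}$; $R_{max}$
  from the peak response over the implied top-well occupancy. Four further
  starts jitter the rates by up to ×/÷10 under a fixed seed, and the lowest
  deviance wins. Ties are impossible in practice; equal deviances keep the
  earlier start.
* **Degenerate inputs.** A response window below five times the noise floor
  (estimated from first differences) raises a guess error before any
  optimisation; $N \le p$ raises a dof error; an all-failed multistart
  raises a convergence error carrying the per-start deviances.
* **Uncertainty.** `parameter_uncertainty()` returns asymptotic standard
  errors from the Jacobian at the optimum scaled by residual variance,
  flagged approximate, with the Jacobian condition number attached
  (ill-conditioning beyond $10^{12}$ is an error, not a number). Replicate
  experiments remain the honest uncertainty estimate; summarise them as
  mean ± SD across runs.
* **RMSE.** $\sqrt{\sum r_i^2/(N - p)}$ with $N$ the fitted samples and $p$
  the free-parameter count. The dof correction matters little at
  $N \sim 10^3$, but it makes the zero-noise limit exact and penalises the
  local-plateau variant for its extra parameters.
* **Model choice.** `select_model()` keeps the standard model unless the
  partial fit reduces RMSE by ≥5% *and* fits $\varphi \ge 0.02$ —
  parsimony first; both thresholds are arguments.

## Pre-processing

Alignment trusts the *programmed* schedule: step boundaries come from the
configured durations (instruments execute dwell times faithfully), with a
one-sample default tolerance for acquisition jitter; boundaries are not
detected from the data. Reference subtraction interpolates the control
trace linearly onto the assay grid. `correct_interstep_shifts()` rigidly
re-joins kinetic segments so each segment's first sample equals the
previous segment's last — this removes cumulative bulk-refractive offsets
exactly but attributes the genuine one-sample kinetic change at each
boundary to the shift, a bias of order (rate × grid) per boundary
(≈$5×10^{-4}$ nm at default settings). It is therefore **off by default**
and meant for traces where a matched reference has confirmed bulk shifts.

## What the simulator emulates — and what it does not

`simulate_sensorgram()` adds, in order: linear drift $d·t$, cumulative
Gaussian bulk shifts at step boundaries (each boundary's offset carries
forward, as real bulk artefacts do), and iid Gaussian read noise; a seed
fixes the entire stream without touching the caller's RNG.
`simulate_loading()` models covalent, irreversible pseudo-first-order
capture $R_{sat}(1 - e^{-k C t})$: every sensor reaches the same final
density given enough time, so only the approach *rate* reflects the binder
concentration — which is exactly why `rank_expression()` scores sensors by
the fitted capture rate.

Not modelled: mass-transport limitation, analyte depletion, heterogeneous
ligand populations, non-specific binding isotherms, temperature effects,
and coloured instrument noise. Passing the recovery tests therefore shows
the estimator is correct *for data generated by its own model class with
white noise*; it does not certify robustness against the heterogeneity
artefacts that dominate difficult real traces. That is the usual status of
self-consistency validation, and the reason the reference-sensor and
residual-inspection workflow exists.

## Problem sizes used in validation

The suite runs noiseless recovery on a seven-member affinity panel whose
$K_D$ values span 3 pM to 772 nM (concentration series scaled to
$0.625×$–$10×$ each $K_D$, 1:2 dilutions, long final dissociation below
100 pM), recovering both rates to within 0.01% — affinity span is limited
by assay design, not by the fitter. Stochastic recovery uses 50 seeded
replicates (standard model) and 25 (partial, $\varphi = 0.3$) at
$\sigma = 0.005$ nm on a mid-nanomolar truth, checking the *median*
$K_D$ and $\varphi$ errors (observed ≈0.6% and ≈0.001, against acceptance
bands of 15% and 0.05). ODE-oracle agreement uses 100 random draws. These
sizes give stable medians while keeping the full suite around half a
minute on one core.

## Known limitations

* Multi-cycle (one concentration per sensor) global fitting is out of
  scope, as are mass-transport, bivalent and conformational-change models.
* The time base assumes the exported trace starts exactly at the
  schedule's first step; traces with leading dead time need trimming first.
* Baseline offset is assumed zeroed by alignment and is not a nuisance
  parameter; visible baseline steps should be handled with a reference
  sensor or the shift correction.
* Proprietary instrument exports are not parsed — convert to the tidy CSV
  (`time_s,response_nm`) + YAML schedule contract documented in
  `read_sensorgram_table()` / `read_schedule()`.
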