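# scbli — single-cycle kinetic analysis of biolayer interferometry data

`scbli` estimates binding kinetics from **single-cycle** (kinetic-titration)
biolayer interferometry experiments: one fiber-tip biosensor, loaded with an
immobilised binder (the ligand), moves through a series of analyte wells of
*increasing* concentration, separated by short buffer "mini-dissociations"
and ending in one extended dissociation. All segments are fitted **globally**
with piecewise 1:1 Langmuir models, so a full affinity measurement needs a
single sensor. The package is aimed at binder-screening labs (nanobodies,
scFvs, designed mini-binders) that want scriptable, reproducible fitting of
exported sensorgrams, plus a simulator to validate the pipeline end to end.

## The model

On a continuous clock that starts when the sensor enters the first analyte
well (t = 0), association in well *i* (concentration *C&#7522;*, entered at
*t&#7522;*) follows

    R(t) = R_eq,i + [R_0(t_i) − R_eq,i] · exp{−(k_on C_i + k_off)(t − t_i)}
    R_eq,i = R_max · k_on C_i / (k_on C_i + k_off)

and every dissociation decays mono-exponentially from the value at the end
of the previous step — to zero in the standard model, or towards a plateau
`R_∞,i` in the partial-dissociation variants. Segment start values are
propagated (`R_0` of each step equals the end of the previous step), so the
trace is continuous by construction and the standard model has only three
global parameters: `k_on` (M⁻¹s⁻¹), `k_off` (s⁻¹) and `R_max` (nm), with
`K_D = k_off / k_on`. The global partial model adds one mobile-fraction
parameter `φ ∈ [0, 0.95]` with `R_∞,i = φ·R_0^i`; the local variant fits one
plateau per dissociation segment. Goodness of fit is the dof-corrected RMSE
`sqrt(Σ(R_obs − R_fit)² / (N − p))`, also reported as a fraction of the
response window.

## Worked example

A small synthetic fixture ships with the package: a mid-nanomolar binder
(true `k_on` = 2.3×10⁵ M⁻¹s⁻¹, `k_off` = 1.12×10⁻² s⁻¹, `R_max` = 0.14 nm,
so K_D = 48.7 nM) probed at 25/50/100/200/400 nM with tapered dwell times
(300…100 s), 30 s mini-dissociations, a 600 s final dissociation, and
0.005 nm Gaussian read noise.

```r
library(scbli)
csv <- system.file("extdata", "synthetic_nanobody.csv", package = "scbli")
yml <- system.file("extdata", "schedule.yaml", package = "scbli")
schedule <- read_schedule(yml)
sg <- align_to_assay_clock(read_sensorgram_table(csv), schedule)
fit <- fit_single_cycle(sg, schedule, model = "standard")
fit
#> Single-cycle fit (standard model)
#> 1:1 kinetics: k_on = 2.296e+05 1/(M s), k_off = 0.01132 1/s, R_max = 0.1412 nm, K_D = 4.931e-08 M
#>   N = 861 samples, p = 3 free parameters
#>   RMSE = 0.004988 nm (3.27% of the 0.1525 nm response window)
```

The fitted `K_D` of 49.3 nM sits ~1% from the generating 48.7 nM; the RMSE
of 0.005 nm recovers the injected noise level. Asymptotic standard errors
(`parameter_uncertainty(fit)`) give ≈3.4×10³, 1.4×10⁻⁴ and 7.8×10⁻⁴ for
`k_on`, `k_off`, `R_max` — about 1–2% of each estimate at this noise level.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/scbli fit --data trace.csv --schedule schedule.yaml \
        --model standard --out results/
Rscript inst/cli/scbli simulate --config sim.yaml --seed 1 --out fixtures/
Rscript inst/cli/scbli rank --data loading_csvs/ --out results/
```

`fit` writes a JSON report (rates, K_D, R_max, φ where fitted, RMSE in nm
and % of window, N, p, seed, config hash); `simulate` emits a deterministic
fixture plate; `rank` orders sensors by expression level from their loading
traces (pseudo-first-order capture rate).

Other entry points: `predict_trace()` (noiseless model traces),
`simulate_sensorgram()` / `simulate_loading()` / `make_fixture_plate()`
(seeded synthetic data), `fit_steady_state()` (equilibrium isotherm for weak
binders), `subtract_reference()` and `correct_interstep_shifts()`
(pre-processing), `rank_expression()`, and `select_model()` (parsimony rule
between standard and partial fits).

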