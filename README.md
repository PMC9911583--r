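# msnlme

Population model selection and single-time-point dosimetry for
radionuclide therapy.

## The problem

Absorbed-dose calculations in molecular radiotherapy need the
time-integrated activity (TIA) of an organ — the area under its
activity–time curve — which classically requires imaging each patient at
several times after injection. `msnlme` implements a population
alternative: the complete time–activity data of a patient cohort are
fitted with a nonlinear mixed-effects (NLME) model over a family of
sum-of-exponential (SOE) curves, the curve shape best supported by the
data is selected by Akaike weights, and the TIA of a new patient is then
obtained from a **single** measurement by fitting that patient jointly
with the population. It is aimed at medical-physics and pharmacometrics
users who want a reproducible, data-driven way to choose the fit function
that single-time-point (STP) dosimetry depends on.

## The model

Eleven SOE parameterisations with 3–5 adjustable parameters are provided
(`soe_model_ids()`), all constrained to `f(0) = 0`, carrying the physical
decay constant of the nuclide (In-111 by default,
`lambda_phys = 1.72e-4 /min`) and — for the 4/5-parameter forms — a fixed
fast uptake term with a one-minute half-life representing blood
circulation. Individual parameters are log-normal around population
typical values,

    P_j = TVP_j * exp(ETA_j),   ETA_j ~ N(0, omega2_j),

with a multiplicative (log-scale) residual error. Fitting maximises a
Laplace-approximated marginal likelihood (first-order-conditional-style
inner modes). Candidates are ranked by the small-sample corrected AIC,

    AICc = OFV + 2K + 2K(K+1)/(N-K-1),  K = 2p + 1,

and Akaike weights `exp(-Delta/2)/sum exp(-Delta/2)` over the models whose
fixed effects are all estimated with CV <= 50% (the goodness-of-fit gate).
Stability of the ranking is assessed by a leave-one-patient-out jackknife.
STP accuracy is summarised by relative deviations against all-time-point
(ATP) reference TIAs and `RMSE = sqrt(MeanRD^2 + SDRD^2)`.

## Worked example

Real cohorts of this kind are not publicly deposited, so the package
ships a synthetic-cohort generator calibrated to a published population
model (8 patients, five imaging sessions, N = 40 observations):

```r
library(msnlme)

cohort <- simulate_cohort(seed = 1)
fit <- fit_population(cohort$data, "f4d", fit_control(multistart = 2, seed = 1))
fit
#> Population NLME fit, model f4d
#>   patients: 8, observations: 40
#>   OFV (-2 log marginal likelihood): 8.0531159
#>         fixed effect  CV%  omega^2
#> A1         1.269e+02  7.6 3.14e-02
#> alpha      3.532e-01 13.5 9.75e-05
#> lambda1    1.976e-04 23.7 5.22e-02
#> lambda2    1.746e-03 41.2 5.53e-01
#> residual variance (log scale): 0.0443
```

The generating population had `A1 = 129.36` %·min (the population TIA),
`alpha = 0.31`, `lambda1 = 1.5e-4 /min` and residual variance 0.044: the
amplitude (the quantity dosimetry needs) is recovered to ~2% and the
residual variance almost exactly, while the rates carry larger
uncertainty, visible in their CVs.

Model selection and single-time-point dosimetry:

```r
sel <- select_models(cohort$data, c("f3d", "f4b", "f4d", "f5b"),
                     control = fit_control(multistart = 2, seed = 1))
sel
#> Model selection over 4 candidate functions (N = 40 observations)
#>  model  K weight % max CV %  gof
#>    f3d  7    86.09     25.0 pass
#>    f4d  9    13.91     41.2 pass
#>    f4b  9        -     67.9 fail
#>    f5b 11        -        - fail

atp <- atp_reference_tias(best_fit(sel))
stp <- stp_tia(cohort$data, "P3", sel$model[1], time_label = "T4",
               control = fit_control(multistart = 2, seed = 1),
               atp_fit = best_fit(sel))
stp$tia
#> [1] 124.9013
relative_deviation(stp$tia, atp$tia[atp$patient_id == "P3"])
#> [1] 0.04508652
```

On this cohort the bi-exponential `f3d` carries the highest weight, two
models fail the precision gate and get no weight, and the STP TIA of
patient P3 computed from a single ~47 h measurement lands within 4.5% of
the all-time-point reference. `run_pipeline()` chains all stages
(fit → gate → weights → jackknife → ATP → STP → accuracy) and writes CSV/
JSON reports; `inst/cli/msnlme.R` exposes the same pipeline as a shell
command. See the vignette in `vignettes/msnlme-methods.Rmd` for the model,
its assumptions, and the validation experiments, including which findings
of the underlying study design the synthetic conditions do and do not
reproduce.

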