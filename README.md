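# emgknee

**EMG-driven knee musculoskeletal modelling, genetic-algorithm parameter
identification, Sobol' sensitivity analysis, and sensitivity-based model
simplification.**

`emgknee` is for biomechanists and human-robot-interaction researchers who
estimate knee joint torque from wearable sensing: four surface-EMG channels
(biceps femoris long head; rectus, lateral and medial vastus), muscle-tendon
geometry over time, and a reference torque for calibration. The package
covers the full workflow:

1. **Forward model** — a four-muscle Hill-type model. Each muscle-tendon
   unit has a contractile element with active force-length and
   force-velocity curves, a parallel elastic element, an EMG-to-activation
   nonlinearity `a = (e^{Au} − 1)/(e^A − 1)`, and a fixed-length tendon at a
   pennation angle; net knee torque is the signed sum of muscle forces times
   moment arms (flexion positive). 26 parameters: 6 shared curve parameters
   (A, ΔW_asc, ν_asc, ΔW_des, ν_dec, ε0) + 5 per muscle (l_o, φ_o, F_o,
   q_v, l_t).
2. **Signal conditioning** — zero-phase Butterworth band-pass (20–450 Hz),
   rectification, 6 Hz envelope, MVC normalization, resampling of EMG
   (2 kHz) and motion-capture streams (200 Hz) onto a common analysis grid.
3. **Identification** — a real-coded genetic algorithm minimizes the mean
   squared torque error over a bounded box (curve parameters in fixed
   ranges; muscle-tendon parameters within ±20–50% of scaled initial
   values), reporting RMSE, range-normalized NRMSE and R².
4. **Sensitivity analysis** — Saltelli-style Monte-Carlo estimators of
   first-order, total-effect and second-order Sobol' indices of the torque
   disturbance functional `Y(λ) = mean((τ(λ) − τ(λ₀))²)`, sampled with an
   in-package scrambled Sobol' sequence; interaction indices
   `INi = ST − S1` and `IN = 1 − ΣS1` gate the expensive pairwise analysis.
5. **Simplification** — rank parameters by mean total-effect index across
   subjects, freeze low-sensitivity parameters at population means (keeping
   high-interaction parameters mandatory), and sweep the number of
   identified parameters `q`, reporting the precision ratio
   `R = RMSE_full / RMSE_reduced`.

A synthetic-subject generator (`make_subject()`) emulates the whole
measurement chain — knee-angle cycling, angle-dependent muscle geometry via
the tendon-excursion principle, burst-like activations, amplitude-modulated
band-limited EMG noise, MVC trials, and reference torque with optional
noise — from a known ground-truth parameter vector, so every stage is
testable end to end without any data download.

## Worked example

```r
library(emgknee)

# a synthetic subject with known ground truth
subject <- make_subject(synth_config(seed = 21))
ds      <- subject_dataset(subject, "clean")

# identify the 26 parameters from its torque + EMG + geometry
fit <- ga_identify(ds, config = ga_config(seed = 77))
glance(fit)
#> # A tibble: 1 × 6
#>    rmse nrmse_pct    r2 n_free generations best_mse
#>   <dbl>     <dbl> <dbl>  <int>       <int>    <dbl>
#> 1 0.251     0.535 0.999     26         500   0.0632

# out-of-sample validation on a second trial of the same subject
val <- make_subject(validation_config(subject))
unlist(evaluate_fit(fit$lambda_opt, subject_dataset(val, "clean")))
#>      rmse nrmse_pct        r2
#> 0.6869328 0.7857961 0.9983970

# how close are the recovered maximum isometric forces to the truth?
fo <- grep("^fo_", param_names())
round(100 * abs(unclass(fit$lambda_opt)[fo] /
                unclass(subject$lambda_true)[fo] - 1), 1)
#> fo_bf fo_rf fo_vl fo_vm
#>   3.6   2.2   2.7   2.9
```

The fit reproduces the held-out trial's torque to about 0.8% of its range
(R² ≈ 0.998), and the high-sensitivity maximum forces come back within a few
percent — while low-sensitivity parameters (the velocity-scaling factors,
for instance) do not, which is precisely the redundancy the sensitivity
analysis quantifies:

```r
f    <- output_functional(ds, fit$lambda_opt)
des  <- sobol_design(make_bounds(), P = 1024, seed = 1)
sens <- sobol_analyze(f, des)
tidy(sens)            # S1, ST, INi per parameter
autoplot(sens)        # index bar chart

plan   <- rank_parameters(list(sens), list(fit))
report <- q_sweep(list(S1 = ds), plan, list(fit), q_grid = c(4, 10, 16, 26))
autoplot(report)      # precision ratio R vs number of identified parameters
```

A thin command-line interface over the same functions ships in
`inst/cli/emgknee.R` (subcommands `simulate`, `identify`, `evaluate`,
`sensitivity`, `simplify`, `pipeline`).

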