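# stoverheat

Microbial self-heating and dry matter loss in aerated corn stover storage
reactors: a lumped-parameter dynamical model with calibration, validation
and synthetic-data tooling.

## The problem

Corn stover stored between harvest and biofuel conversion loses dry matter
to aerobic microbial respiration, and the heat that respiration releases
feeds back on the microbes' own temperature response. `stoverheat` is for
bioprocess and feedstock-logistics researchers who want to simulate that
coupled thermal–kinetic system at laboratory reactor scale, calibrate its
uncertain parameters against instrument time series (biomass temperature,
off-gas CO₂, condensate volumes), and quantify predictive error on
held-out reactors.

## The model

A single thermal node carries the biomass temperature *T*, coupled to
bi-phasic (diauxic) first-order substrate kinetics:

    dSᵢ/dt = k_{d,i} · f_T(T) · f_M(M) · (S₀,ᵢ − Sᵢ)        (phase i, after its lag)
    C_th · dT/dt = Q_m + Q_k + Q_h + E

where `f_T` is the cardinal temperature model with inflection (CTMI,
parameters T_min, T_opt, T_max per phase), `f_M = M/(0.25 + M)` is a Monod
moisture factor on the wet-basis moisture content M (a prescribed linear
drying schedule), and the heat flows are microbial (`Q_m = y_m · ΣdSᵢ/dt`),
conductive to the water jacket (`Q_k = (K/L)·A·(T_j − T)`), convective to
ambient (`Q_h = h·A·(T_a − T)`, flat-plate Nusselt correlation) and
evaporative (`E = −h_vap·ṁ_w`). Cumulative CO₂ and microbial heat are
exactly proportional to substrate degraded (y_co2 = 1.44 g/g, y_m = 9.7
J/g). Dry matter loss is the degraded fraction of loading dry matter.
Integration uses the adaptive Dormand–Prince 4(5) pair; calibration is
bounded Levenberg–Marquardt on jointly weighted temperature + substrate
residuals. The methods vignette
(`vignettes/stover-storage-model.Rmd`) documents the model, its numerical
choices and its identifiability limits in detail.

## Worked example

Generate a synthetic 34-day benchmark-reactor campaign with known ground
truth, then calibrate four parameters back from the noisy observations:

```r
library(stoverheat)

cfg <- reactor_fixtures()$reactor_2   # 7080 g dry matter, 347 cm3/min airflow
sc  <- biphasic_scenario()            # calibrated two-phase kinetics
ds  <- generate_dataset(cfg, sc$phases, sc$yields, noise = noise_spec(seed = 42))
glance(ds$sim)
#> # A tibble: 1 × 7
#>   duration_days final_temperature_C peak_temperature_C substrate_degraded_g ...
#> 1          34.1                20.5               40.0                 353.
dry_matter_loss(ds$sim)
#> [1] 4.99
```

The noiseless truth rises from 12.9 °C to a 40.0 °C peak and decays, while
the two pools degrade 353 g of the 354 g degradable substrate — a 4.99%
dry matter loss. Now recover the phase-1 degradation rate and optimum
temperature (plus the shared heat yield and conductivity) from Table-2-style
baselines:

```r
obs <- ds$observed
obs$stover_temp_C[(obs$time_days * 24) %% 1 >= 1e-9] <- NA   # hourly grid
obs <- obs[rowSums(!is.na(obs[-1])) > 0, ]

specs <- parameter_specs(name     = c("k_d_1", "t_opt_1", "y_m", "k_cond"),
                         baseline = c(8.9e-6,  41.3,      10,    9),
                         lower    = c(0,       35,        0,     6),
                         upper    = c(Inf,     55,        Inf,   14))
fit <- calibrate_reactor(obs, cfg, sc$phases, specs, yields = sc$yields)
fit
#> <stover calibration> 4 parameters, 5 iterations, converged
#>   k_d_1          7.55452e-06  (start 8.9e-06)
#>   t_opt_1        46.5647  (start 41.3)
#>   y_m            10.0005  (start 10)
#>   k_cond         9.00554  (start 9)
#>   cost 10.0587 -> 1.61857; temperature MAE 0.163 degC; DML error 0.06%
```

The generating values were k_d = 7.6e-6 s⁻¹ and T_opt = 46.7 °C: both come
back within ~1% / 0.2 °C of truth. The heat yield y_m stays at its
baseline — it is structurally unidentifiable from these observables (its
imprint on the temperature trace is ~10⁻⁴ K), and the estimator is
deliberately regularized so it reports that honestly instead of wandering;
see the vignette. `tidy(fit)`, `glance(fit)` and `autoplot(fit)` give the
parameter table, the one-row fit summary and observation-vs-model plots;
`validate_reactor()` scores a calibrated parameter set on a reactor not
used for fitting.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/stover-reactor.R generate --reactor 2 --seed 7 --out obs.csv
Rscript inst/cli/stover-reactor.R simulate --reactor 2 --out sim.csv
```

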