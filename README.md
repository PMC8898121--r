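# ferrokin

Quantitative analysis of free-iron (Fe²⁺) toxicity on packed red blood
cells (pRBCs) in vitro. Excess ferrous iron drives the Fenton reaction
(Fe²⁺ + H₂O₂ → OH· + OH⁻ + Fe³⁺); the hydroxyl radicals oxidize
oxyhemoglobin (HbO₂) to methemoglobin (MetHb) and stiffen the cell
membrane. `ferrokin` is for researchers who need to turn the raw
measurements of such an experiment — absorbance spectra, MetHb time
courses, AFM force–indentation curves — into derivative concentrations,
kinetic rate constants and membrane moduli, with seeded synthetic
generators standing in for instrument data so the whole pipeline is
testable end to end.

## What it computes

**Spectral unmixing.** Absorbance between 500 and 700 nm is modeled as

    D(λ) = [ε_HbO2(λ)·C_HbO2 + ε_Hb(λ)·C_Hb + ε_MetHb(λ)·C_MetHb]·10⁻³·L
           + K + S·(λ/550)⁻⁴

and inverted by bounded Levenberg–Marquardt least squares
(`fit_spectrum()`), yielding the three derivative concentrations, the
scattering baseline (K, S), and adjusted R². Percentages follow from
`derivative_fractions()` (C_MetHb% = 100·C_MetHb/C_total) and
`hemolysis_level()` estimates pigment loss between paired spectra.

**Kinetics.** With constant H₂O₂ concentration *a*, mass action gives
the closed forms

    y(t) = y₀·exp(−βat)                                  (Fe²⁺)
    x(t) = Z₀·(1 − exp(−γy₀(1 − exp(−βat))/β))           (MetHb)
    x_ss = Z₀·(1 − exp(−γy₀/β))                          (steady state)

implemented in `fe_decay()`, `methb_time()`, `methb_steady_state()` with
an independent `deSolve` cross-check (`ode_solve()`). Because x(t)
depends on (a, β, γ) only through u = βa and v = γ/β,
`fit_methb_curve()` fits the identifiable pair and resolves (β, γ) when
the H₂O₂ concentration is supplied (`fix_a`); `recovery_experiment()`
reruns the whole multi-concentration fitting study on synthetic data.

**Mechanics.** Young's moduli from force curves via the spherical-indenter
Hertz model F = (4/3)·E/(1−ν²)·√R·h^(3/2) (`fit_youngs_modulus()`,
default R = 150 nm, ν = 0.5), plus distribution summaries
(`modulus_distribution()`), the exceedance statistic
`fraction_beyond_control()` and AFM profile features
(`profile_features()`).

**Preparation arithmetic and I/O.** `stock_molarity()`,
`dilution_series()`, and validated CSV readers/writers for every format
(`read_spectrum_csv()`, `read_methb_csv()`, `read_force_csv()`,
`read_extinction_csv()`, `write_kinetics_csv()`, `write_fit_report()`).

## Worked example

```r
library(ferrokin)

## bench arithmetic: 20 mg FeSO4·7H2O in 1.0 ml, then 100 µl into 4.2 ml
stock_molarity(20, 1.0)                          # 71.94 (mM)
dilution_series(71.94, dilution_step(100, 4100)) # 1712.9 (µM, "1700 µM" nominal)

## kinetic model at the fitted constants, 1700 µM initial iron
p <- kinetic_params(a = 9e-4, beta = 0.973, gamma = 3e-3, y0 = 1700, z0 = 5)
methb_steady_state(p, percent = TRUE)            # 99.5 (% of Z0)

## fit one synthetic noisy MetHb time course (1 % of Z0 noise)
cfg <- simulation_config(kinetic_params = p, seed = 7)
sim <- simulate_methb_timeseries(cfg)
d   <- sim[sim$replicate == 1, ]
fit_methb_curve(d$time_min, d$methb_um, y0 = 1700, z0 = 5, fix_a = 9e-4)
#> MetHb kinetic curve fit (n = 8 points)
#>   u = beta*a    = 0.00080964 min^-1
#>   v = gamma/beta = 0.00326468 uM^-1
#>   a = 0.0009 uM, beta = 0.8996 uM^-1 min^-1, gamma = 0.002937 uM^-2 min^-1
#>   R-squared = 0.99866, converged = TRUE

## unmix the 120-min spectrum of the matching synthetic series
tab  <- make_extinction_fixture()
sp   <- simulate_spectra_series(cfg)$spectra[[7]]
sfit <- fit_spectrum(sp, tab, allow_scatter = FALSE)
derivative_fractions(sfit)$methb_percent         # 41.3 (% MetHb at 120 min)

## membrane stiffness, 100 cells per group at the 1 h group moments
probe <- probe_params()                          # R = 150 nm, nu = 0.5
ens    <- simulate_force_curves(simulation_config(seed = 7), probe)
e_ctrl <- sapply(ens$control_1h$curves, fit_youngs_modulus, probe = probe)
e_exp  <- sapply(ens$exposed_1h$curves, fit_youngs_modulus, probe = probe)
c(mean(e_ctrl), mean(e_exp))                     # 11.6, 15.9 (kPa)
fraction_beyond_control(e_exp, e_ctrl)           # 33 (% beyond control, 0.95 level)
```

The fitted rate constants land near their generating values (β within
~8 % on this single curve, tightening to ~1 σ of the between-curve SD
when averaged over the full recovery experiment), the unmixed MetHb
fraction tracks the kinetic ground truth at 120 min, and the
iron-exposed group shows both a higher mean modulus and a third of cells
beyond the 0.95 control quantile.

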