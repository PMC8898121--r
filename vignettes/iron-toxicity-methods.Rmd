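---
title: "Models and methods: free-iron toxicity analysis of packed red blood cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: free-iron toxicity analysis of packed red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrokin)
```

# Scope

`ferrokin` analyzes in-vitro experiments in which packed red blood cells
(pRBCs) — stored erythrocyte concentrate — are exposed to ferrous sulfate.
Free Fe²⁺ triggers the Fenton reaction
(Fe²⁺ + H₂O₂ → OH· + OH⁻ + Fe³⁺), and the resulting hydroxyl radicals
oxidize oxyhemoglobin (HbO₂) to methemoglobin (MetHb), the biomarker of
oxidative stress the package quantifies. Four measurement types are
supported: absorbance spectra of hemolysates and suspensions,
MetHb time courses, atomic-force-spectroscopy force–indentation curves,
and AFM surface profiles. Because no instrument data ship with the
package, a seeded synthetic module emulates each measurement type with
known ground truth; every analysis stage is tested against it.

# Spectral unmixing

The absorbance of a hemoglobin solution between 500 and 700 nm is modeled
as the Beer–Lambert mixture

$$D(\lambda) = \left[\varepsilon_{HbO_2}(\lambda)\,C_{HbO_2}
 + \varepsilon_{Hb}(\lambda)\,C_{Hb}
 + \varepsilon_{MetHb}(\lambda)\,C_{MetHb}\right] 10^{-3} L
 + K + S\,g(\lambda),$$

with molar absorptivities ε in mM⁻¹cm⁻¹, concentrations in µM, path
length $L$ in cm (default 1), a wavelength-flat scattering term $K$ and a
Rayleigh term $S\,g(\lambda)$. `fit_spectrum()` inverts the model by
bounded Levenberg–Marquardt least squares (concentrations, $K$ and $S$
constrained nonnegative), followed by an active-set refinement that
exploits the model's linearity in all five parameters; the refinement
guarantees that freeing $K$ and $S$ can never worsen the residual of the
nested no-scatter fit. Goodness of fit is reported as adjusted R².

Design choices worth knowing:

* **Scattering basis.** Rayleigh scattering by sub-wavelength particles
  scales as $\lambda^{-4}$, so the default basis is
  $g(\lambda) = (\lambda/550\,\mathrm{nm})^{-4}$, normalized at 550 nm to
  keep $S$ on the absorbance scale and the design matrix well
  conditioned. A `scatter_exponent = 4` switch selects the literal
  $\lambda^{+4}$ reading for users who want it.
* **Hemolysate mode.** Lysed samples contain no cells to scatter light;
  `allow_scatter = FALSE` fixes $K = S = 0$ and frees only the three
  concentrations. On pure-absorption input the five-parameter fit
  recovers $K = S = 0$, which is the package's consistency check between
  the two modes.
* **Initial guesses.** The peak absorbance divided by the mean extinction
  is split equally over the three derivatives; $K$ starts at the spectrum
  minimum, $S$ at 0. Because the problem is linear, the refinement step
  makes the result insensitive to these starts.
* **Extinction table.** The bundled `make_extinction_fixture()` builds a
  smooth synthetic table on the 500–700 nm / 0.5 nm grid (401 rows) from
  Gaussian bands at the landmark wavelengths of the real chromophores
  (HbO₂ double peak near 542/577 nm, broad Hb band near 555 nm, the
  diagnostic MetHb peak at 630 nm). It is a literature-*shaped* stand-in,
  not digitized data: absolute concentrations unmixed with it are
  self-consistent within the package but not transferable to real
  spectra. Users with measured absorptivities load them with
  `read_extinction_csv()`; tables on a different grid are linearly
  interpolated onto the spectrum grid.

Derivative percentages follow from
$C_{total} = C_{HbO_2} + C_{Hb} + C_{MetHb}$, each derivative reported as
$100\,C_i/C_{total}$. The hemolysis estimator is a declared convention:
the fractional loss of cell-associated total pigment between time 0 and
time $t$, $100\,(1 - C_{total}(t)/C_{total}(0))$, clipped to [0, 100].
The underlying spectrophotometric measurement is described in the
literature only as a residual absorbance level, so other conventions are
possible; this one is exact on the synthetic generator by construction.

# Kinetic model

With the H₂O₂ concentration held constant at $a$ (quasi-steady state —
peroxide consumed by the Fenton reaction is regenerated by downstream
radical chemistry), mass action gives

$$\frac{dy}{dt} = -\beta a y, \qquad
  \frac{dx}{dt} = \gamma a y (Z_0 - x),$$

for $y$ the Fe²⁺ and $x$ the MetHb concentration, with $y(0) = y_0$,
$x(0) = 0$, and $Z_0$ the initial HbO₂ (5 µM under the emulated assay
conditions). The closed forms are

$$y(t) = y_0 e^{-\beta a t}, \qquad
  x(t) = Z_0\!\left(1 - e^{-\gamma y_0 (1 - e^{-\beta a t})/\beta}\right),
  \qquad
  x_{ss} = Z_0\!\left(1 - e^{-\gamma y_0/\beta}\right).$$

The model conserves total hemoglobin ($C_{HbO_2}(t) = Z_0 - x(t)$), the
MetHb curve is nondecreasing, and the steady state saturates at $Z_0$ for
large iron loads (all HbO₂ oxidized) while at low loads the plateau is
set by iron exhaustion. Units are fixed: minutes, µM, β in µM⁻¹min⁻¹,
γ in µM⁻²min⁻¹. `ode_solve()` integrates the same system numerically
(`deSolve::lsoda`, rtol 1e-10) as an independent cross-check; closed form
and integration agree to better than 1e-6 relative in the test suite.

Numerical care: $1 - e^{-x}$ is evaluated as `-expm1(-x)` throughout, so
the curve and its Jacobian remain accurate for $\beta a t \ll 1$; the
degenerate limit $\beta \to 0$ is replaced by its continuous series limit
$x(t) = Z_0(1 - e^{-\gamma a y_0 t})$.

## Identifiability

$x(t)$ depends on $(a, \beta, \gamma)$ only through $u = \beta a$ and
$v = \gamma/\beta$: the transformation
$(a, \beta, \gamma) \to (k a, \beta/k, \gamma/k)$ leaves every MetHb
curve unchanged (the suite checks invariance to 1e-12). A three-parameter
fit to a MetHb curve alone is therefore degenerate. `fit_methb_curve()`
always fits $(u, v)$, with starts taken from the observed plateau (via
the steady-state relation) and the initial slope
($V(0) = Z_0 v y_0 u$). Resolution of the ridge requires outside
information: passing `fix_a`, the independently known H₂O₂ concentration,
returns $\beta = u/a$ and $\gamma = v u / a$ with a delta-method
covariance; without it the fit is reported on the $(u, v)$ scale with a
ridge diagnostic rather than an arbitrary triple.

# The recovery experiment

`recovery_experiment()` regenerates the fitting study on synthetic data:
for each initial Fe²⁺ concentration in
{212.5, 425, 850, 1700, 3400, 6800, 13600} µM it draws 20 noisy MetHb
curves from the closed form at the generating parameter set
(a = 0.00090 µM, β = 0.973 µM⁻¹min⁻¹, γ = 0.0030 µM⁻²min⁻¹, Z₀ = 5 µM),
fits each with $a$ fixed at its generating value, and averages the
recovered constants (arithmetic mean ± sample SD, `summarize_fits()`).

Conditions the generator emulates, chosen once:

* **Time grid** `c(0, 15, 30, 45, 60, 90, 120, 1440)` min — the
  hemolysate incubation schedule of the emulated assay, which samples
  every 15–30 min over the first two hours and once at 24 h. The 24 h
  point matters structurally: at low iron loads the curve is still nearly
  linear at 120 min, and without a reading near the plateau the
  combination $u = \beta a$ is essentially unidentified per curve, making
  averaged rate constants meaningless. With it, per-curve fits reach
  R² > 0.96 across the whole concentration range.
* **Noise** — additive Gaussian with SD 1 % of Z₀ on MetHb (clipped to
  the physical range [0, Z₀]), SD 0.002 absorbance on spectra,
  multiplicative 2 % on force curves. The emulated study reports no noise
  magnitudes, so these are declared defaults of realistic instrument
  scale, exposed in `simulation_config()`.
* **What passing does not show.** The generator draws from the same model
  family that is fitted, so recovery tests demonstrate correctness of the
  estimator, not adequacy of the model for real hemolysates (no
  model-misfit, drift, or baseline artifacts are simulated).

A property of the geometry worth documenting: at the extreme iron
concentrations the per-curve likelihood is nearly flat in $u$ (at low
$y_0$ the curve is close to linear; at high $y_0$ it saturates before the
Fe²⁺ pool decays appreciably), so per-curve $\beta$ estimates are
heavy-tailed there even though $\gamma$ — identified through the product
$v u$ — is tight. The grand mean of $\beta$ over the 140 fits remains
within one between-curve SD of the generating value; single-curve
$\beta$ values at 212.5 or 13600 µM should not be over-interpreted, and
the per-curve covariance reports the corresponding variance explosion.

# Membrane mechanics

For a spherical (paraboloidal) indenter of radius $R$ on an elastic
half-space the Hertz model gives

$$F(h) = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,h^{3/2},$$

so `fit_youngs_modulus()` recovers $E$ by exact linear projection
(the model is linear in $E$). Defaults: $R = 150$ nm (the deep-indentation
cantilever used for pRBC membranes), $\nu = 0.5$ (incompressible
membrane, the standard assumption for cells); both are configurable in
`probe_params()`. The contact point is taken at $h = 0$: synthetic and
fixture curves are defined that way, and real-world AFM preprocessing
(deflection conversion, tilt and contact-point detection) is out of
scope. Unit bookkeeping is internal: kPa, nm and nN at the interface.

Group comparisons use the empirical distribution:
`modulus_distribution()` returns a relative-frequency-density histogram
(area 1) and the ECDF, and `fraction_beyond_control()` reports the
percentage of treated cells whose modulus exceeds the empirical type-7
quantile of the control sample at a given level (default 0.95). The
empirical quantile — not a fitted normal — is used because the exceedance
statistic is defined directly on the measured distribution functions.
When treatment and control are the same large sample the statistic is
5 % at level 0.95 by construction, which the suite checks.

Surface profiles: `profile_features()` locates interior local extrema by
sign changes of the first difference and reports the mean spacing between
successive minima (spatial period of the membrane structure) and the mean
rise from the flanking concaves to each maximum (structure height). A
flat or monotone profile, or fewer than three resolvable minima, is an
error rather than a number.

# Solution preparation

`stock_molarity()` and `dilution_series()` reproduce the bench
arithmetic: a 20 mg/ml stock of iron(II) sulfate heptahydrate
(278.01 g/mol — the heptahydrate *sulfate*; the occasionally seen
"7H₂O₂" formula is a typesetting slip, and only the heptahydrate molar
mass reproduces the 71.9 mM stock) and aliquot dilutions with additive
volumes. The functions return exact mass-balance values; nominal labels
(the 100 µl → 4.2 ml assembly is conventionally labeled 1700 µM though
the exact value is 1711.9 µM) are the caller's concern, since different
assembly orders carrying the same label differ below the 1 % level.

# Problem sizes and determinism

The test suite and the acceptance script run the full recovery
experiment at its study size (7 concentrations × 20 replicates × 8 time
points), 100–200-replicate Monte Carlo checks for unbiasedness, and
property suites over dozens of random parameter draws; everything
completes in well under a minute on one core. All generators are pure
functions of `(config, seed)`: they save and restore the caller's RNG
state, identical seeds give identical output, and every simulated object
records its seed.

# Known limitations

* The extinction fixture is shaped, not measured; absolute unmixed
  concentrations are only meaningful against a user-supplied measured
  table.
* The hemolysis estimator is a declared convention (total-pigment loss).
* The kinetic model hard-codes constant H₂O₂ and has no explicit radical
  chain, lipid-peroxidation or transport dynamics; suspension kinetics
  (several-fold slower than hemolysate) are not modeled.
* Hertz estimation assumes the contact point is given and the indenter
  spherical; no AFM raw-signal preprocessing is provided.
* Cell-shape classification and aggregate morphometry are out of scope.
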