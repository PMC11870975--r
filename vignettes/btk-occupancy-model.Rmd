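---
title: "The ibrutinib-BTK covalent binding model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ibrutinib-BTK covalent binding model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btksim)
```

## The model

Ibrutinib inactivates Bruton's tyrosine kinase (BTK) by covalent binding to
Cys481. Because the reaction runs to completion rather than to equilibrium,
an IC50 is assay-time-dependent and unsuitable as a potency measure; the
field instead characterizes covalent inhibitors by $k_{inact}/K_I$, and that
is the parameterization this package implements. The model has three parts.

**Pharmacokinetics.** An open two-compartment disposition model with
sequential zero/first-order oral absorption after a lag time. Each dose
event feeds a depot compartment with a zero-order input of rate
$F_1 \cdot \mathrm{dose} / D$ over $[t + T_{lag},\, t + T_{lag} + D]$; the
depot empties into the central compartment at a first-order rate $k_a$:

$$
\begin{aligned}
dA_1/dt &= R(t) - k_a A_1 \\
dA_2/dt &= k_a A_1 - (k_{el} + k_{23}) A_2 + k_{32} A_3 \\
dA_3/dt &= k_{23} A_2 - k_{32} A_3
\end{aligned}
$$

with $k_{el} = CL/V_2$, $k_{23} = Q/V_2$, $k_{32} = Q/V_3$ (volumes after
allometric body-weight scaling with exponent 0.641 around the 80.4 kg
reference). The free plasma concentration driving binding is
$C_2 = 1000 \cdot f_u \cdot (A_2/V_2) / MW$, exact in nM when amounts are
kept in micrograms and volumes in litres ($f_u = 0.03$, $MW = 440.5$
g/mol). A high-fat meal lengthens the zero-order duration (3.29 h fed vs
1.10 h fasted) and fasting lowers bioavailability ($F_1$ = 0.67 vs 1);
antacids stretch $D$ by a factor 1.61. These covariates are carried per
dose event.

**Target turnover.** Free BTK is produced at a zero-order rate
$k_{syn} = BTK_0 \cdot k_{deg}$ and degraded at
$k_{deg} = \ln 2 / t_{1/2,BTK}$, so without drug it sits at the baseline
$BTK_0$ (1.04 nM in CLL).

**Covalent binding.** Free drug and free BTK form a reversible complex
($k_{on}$, $k_{off}$) which is irreversibly inactivated at $k_{inact}$; the
covalent complex degrades at $k_{degc} = k_{deg}$:

$$
\begin{aligned}
dBTK_f/dt &= k_{syn} - k_{on} C_2\, BTK_f + k_{off} BTK_{rc} - k_{deg} BTK_f \\
dBTK_{rc}/dt &= k_{on} C_2\, BTK_f - (k_{off} + k_{inact}) BTK_{rc} \\
dBTK_{cc}/dt &= k_{inact} BTK_{rc} - k_{degc} BTK_{cc}
\end{aligned}
$$

Binding does not deplete the drug amounts (target-site binding is a
negligible fraction of dose), which makes the PK strictly linear in dose
and the BTK subsystem linear in the BTK states given $C_2(t)$. Two useful
invariants follow and are asserted in the test suite: occupancy is
invariant to $BTK_0$, and $C_2(t)$ scales exactly with dose.

The reversible complex has no degradation term, so total BTK
($BTK_f + BTK_{rc} + BTK_{cc}$) is only *approximately* conserved; because
$k_{inact} \gg k_{off}$ the reversible pool stays transiently small and the
deviation from $BTK_0$ is below 2% at steady state under 420 mg once daily.
We implement the equations exactly as written above and treat the
conservation claim as approximate.

**Occupancy.** The modelled readout is the fraction of total BTK bound,

$$
BTK_{OCC} = 100 \cdot \frac{BTK_{rc} + BTK_{cc}}{BTK_f + BTK_{rc} + BTK_{cc}},
$$

evaluated at the steady-state trough, defined here as 24 h after the last
dose (the pre-dose sample of the next day) — the only unambiguous trough
under once-daily dosing. Measured occupancy additionally carries additive
residual error with variance 27.1 on the percent scale (`add_ruv()`),
clipped to $[0, 100]$; the intrinsic occupancy used for the headline
summaries excludes it.

## Parameters

| parameter | value | units | variability (%CV) |
|---|---|---|---|
| CL/F | 1060 | L/h | 21.9 |
| V2/F | 246 | L | 153 |
| Q/F | 865 | L/h | 60.7 |
| V3/F | 9620 | L | 47.3 |
| $k_a$ | 0.463 | 1/h | — |
| $T_{lag}$ | 0.283 | h | 27.8 |
| $D$ (fed) | 3.29 | h | 20.9 |
| $F_1$ (fed) | 1 | — | 62.8 |
| $BTK_0$ | 1.04 | nM | 78.9 |
| $t_{1/2,BTK}$ | 60 / 24 / U(12, 120) | h | 25 (fixed scenarios) |
| $k_{on}$ | 1.72 (SD 0.60) | 1/nM/h | uncertainty, not BSV |
| $k_{off}$ | 0.205 | 1/h | — |
| $k_{inact}$ | 95.76 (SD 88.56) | 1/h | uncertainty, not BSV |
| $f_u$ | 0.03 | — | — |
| RUV variance | 27.1 | %² | residual |

Between-subject variability uses the exponential model
$\theta_i = \theta \cdot e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$,
independently per parameter (no correlation matrix is available), with no
variability on $k_a$.

**The %CV convention.** A reported lognormal %CV maps to $\omega$ either
approximately ($\omega = CV/100$) or exactly
($\omega = \sqrt{\ln(1 + CV^2)}$, `cv_to_omega()`). The two are
indistinguishable below ~30 %CV but diverge badly at the 153 %CV on
$V_2/F$ ($\omega$ 1.10 vs 1.53). This package uses the exact relation: it
is the mathematically consistent reading of a lognormal CV, and with it the
simulated dose-response summaries (occupancy table, ED90 values per
turnover scenario) agree with the published results of the source model
within their Monte-Carlo tolerance, whereas the approximate reading
overdisperses the population and shifts the fixed-half-life ED90 estimates
about 20% high. `population_spec()` accepts arbitrary %CV overrides, so
either convention can be emulated.

$F_1$ variability (62.8 %CV on a fed typical value fixed at 1) is applied
as an uncapped exponential multiplier, reading the variability column
literally; subjects can therefore have $F_1 > 1$, interpreted as relative
(not absolute) bioavailability.

## Half-life scenarios and parameter uncertainty

BTK turnover in CLL is uncertain: in-vitro half-lives are 8-12 h while
model-based estimates in patients are near 60 h. Three population scenarios
are provided: *slow* (lognormal around 60 h, 25 %CV), *fast* (around 24 h,
25 %CV) and *uniform* (half-lives drawn from U(12, 120) h, no extra
spread). The uniform scenario represents a clinical population mixing
tumor biologies and is the default.

Uncertainty in $k_{on}$ and $k_{inact}$ is propagated by drawing 100,000
values from their reported normal distributions, truncated to positive
support by rejection sampling (the untruncated 5th-10th percentiles of
$k_{inact}$ would be negative, which is physically meaningless — truncation
was chosen over log-transformation as the minimal intervention), and taking
the 11 percentiles 5, 10, ..., 95. The two parameters are paired by
percentile rank, giving 11 binding-parameter scenarios whose extremes trace
the uncertainty band of a dose-response curve and whose middle pair is the
central scenario. A full cross of the two grids was rejected: rank pairing
reproduces a band with 11 curves and keeps the extreme curves
interpretable. Note that because both distributions are nearly symmetric
around their means and $k_{inact}$ almost cancels from the effective
association rate $k_{on} C_2 k_{inact}/(k_{off}+k_{inact})$ when
$k_{inact} \gg k_{off}$, the band width is driven almost entirely by
$k_{on}$.

## Virtual trials

`run_virtual_trial()` simulates each subject under once-daily dosing
(default 7 days — PK steady state is reached after about 4 days) and
records intrinsic occupancy at the trough. The same sampled subjects are
reused at every dose level (common random numbers): dose-response curves
are then smooth and per-subject monotone in dose, and cross-dose contrasts
are not diluted by sampling noise. `simulate_dose_reduction()` integrates
each subject continuously through consecutive 28-day cycles (default
420, 280, 140 mg) and evaluates the final trough of each cycle;
steady-state within a cycle makes the choice between "last trough" and a
cycle-end average immaterial, and the last trough is the cleaner estimand.

`dose_response_sweep()` computes, per dose and per uncertainty pair, the
proportion of subjects with occupancy strictly above 90% (a tie at exactly
90.000 counts as non-responder; under the continuous model ties have
measure zero). The default dose grid is dense (10 mg steps) through the
rising limb up to 150 mg, 25 mg steps to 600 mg, then 50 mg steps to
1100 mg.

**ED90.** The proportion-vs-dose curve is summarized by a sigmoid Emax
(Hill) fit $p(d) = p_{max} d^h / (d_{50}^h + d^h)$ by least squares
(`minpack.lm`), and ED90 is the dose at 90% of the *fitted plateau*,
$ED_{90} = d_{50} \cdot 9^{1/h}$. The plateau is left free (bounded by 1)
because no population reaches a proportion of exactly 1; the fit refuses to
extrapolate when the observed maximum is far below the fitted plateau.
ED90 of an exact Hill curve is recovered analytically, which the tests
assert. Estimates for curves of this shape are sensitive to the fit family
in roughly the 10-15% range, which should be treated as the reproduction
accuracy of any ED90 quoted from this kind of analysis.

## Evaluation against observed occupancy proportions

The package embeds a 21-dose table of observed pre-dose occupancy
measurements (320 observations, 80-1400 mg, days 2/8/15/29 of once-daily
dosing). Responder counts are reconstructed from the printed percentages by
rounding `pct * n / 100`; the reconstruction is exact bookkeeping for all
rows and reproduces the printed overall responder rate of 82%. Because
many dose levels have fewer than 10 observations, records are pooled into
five dose groups (80-140, >140-300, >300-500, >500-800, >800-1400 mg) with
exact Clopper-Pearson 95% intervals (`binom.test`); the method for the
observed intervals is not documented in the source data, and the exact
interval is the conservative default. `predicted_vs_observed()` compares
each group's pooled proportion against model predictions averaged over the
group's member doses with observed-sample-size weights, run with residual
error added so predictions and data carry the same measurement noise.

`generate_synthetic_study()` emulates this design end to end (dose
allocation, pre-dose sampling days, residual error, clipping) and is the
data generator for the package's self-consistency tests. What it does
*not* emulate: tumor-type strata, dropout, dosing-history irregularities,
assay floor/ceiling artifacts beyond simple clipping, or any correlation
between a subject's PK and their measurement error. Passing
self-consistency tests therefore demonstrates internal coherence of
generator and evaluator, not fidelity to every feature of real assay data.

## Numerical implementation

The six-state system is stiff: $k_{inact} \approx 96$/h against turnover
rates of order 0.01/h. The integrator (C++, `src/simulate.cpp`) is a
fixed-step classical Runge-Kutta scheme with two safeguards:

- **Discontinuity alignment.** Integration restarts at every breakpoint of
  the piecewise-constant absorption input (dose time + lag, + lag +
  duration) and at every requested output time, so the right-hand side is
  smooth within each step sequence.
- **Stability cap.** The step is bounded by $2/\lambda_{max}$, where
  $\lambda_{max}$ is the largest first-order rate in the subject's system
  (RK4's real-axis stability limit is 2.785); subjects in the far tails of
  the clearance/volume distributions automatically get smaller steps. The
  default cap is 0.01 h.

Accuracy is validated in the test suite against `deSolve::lsoda` at
rtol 1e-10 on the same equations (agreement better than 0.001 occupancy
percentage points at troughs) and against the closed-form constant-infusion
steady state (better than 0.1 percentage points across four orders of
magnitude of concentration). The fast binding mode decays with
$|R(z)| \approx e^{z}$ well inside the stability region, so the capped
explicit scheme is adequate despite the stiffness; an adaptive implicit
solver was rejected because per-subject solver calls dominate runtime at
population scale. Population sweeps additionally exploit dose-linearity:
each subject's unit-dose concentration profile is integrated once and
rescaled per dose before the three BTK states are integrated.

Degenerate inputs are handled explicitly: zero dose yields zero input and
baseline BTK; occupancy at an all-zero BTK state is an error (it is
undefined); zero %CV collapses the sampler to the typical subject; a
single-curve sweep reduces the predicted band to a point comparison.

## Problem sizes

The published analyses used 10,000 subjects per dose. The package defaults
keep that size, while the test suite and the acceptance script use reduced
populations chosen so that Monte-Carlo error stays well inside the
comparison tolerances: 2,000-4,000 subjects for trials, sweeps and the
reduction cascade (binomial error on a proportion near 90% is then 0.5-1.5
percentage points, against tolerances of 2-2.5 points), and 19 doses for
ED90 sweeps. Typical-patient results are deterministic and run in well
under a second each.

## Known limitations

- PK and PD parameters are sampled independently; real population models
  estimate correlated random effects, so joint tails (e.g. high clearance
  with small volume) are somewhat misrepresented.
- The plasma unbound fraction is a constant 3%; no protein-binding
  kinetics.
- No inter-occasion variability, adherence gaps or missed doses; dose
  reductions are modelled as clean 28-day switches.
- The allometric weight model is carried but populations default to the
  reference 80.4 kg, matching the source analyses.
- ED90 values inherit ~10-15% procedural uncertainty from the unreported
  fit family of the original analysis (free-plateau Hill chosen here).
- No exposure-response (efficacy or safety) modelling: occupancy above 90%
  is the terminal endpoint of this package.
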