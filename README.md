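# btksim

Simulation of Bruton's tyrosine kinase (BTK) occupancy under once-daily
oral ibrutinib in chronic lymphocytic leukemia (CLL) populations.

Ibrutinib inhibits B-cell receptor signaling by binding BTK covalently at
Cys481, so target recovery requires de novo protein synthesis and the usual
IC50 is not a meaningful potency measure. This package implements the
mechanistic alternative used for covalent inhibitors: a population
pharmacokinetic model (two-compartment disposition, sequential
zero/first-order absorption with lag) coupled to a covalent binding model
parameterized by k_inact/K_I on top of free-BTK turnover,

    dBTKf/dt  = k_syn − k_on·C2·BTKf + k_off·BTKrc − k_deg·BTKf
    dBTKrc/dt = k_on·C2·BTKf − (k_off + k_inact)·BTKrc
    dBTKcc/dt = k_inact·BTKrc − k_degc·BTKcc

with k_deg = ln(2)/t(1/2,BTK), k_syn = BTK0·k_deg and the free plasma
concentration C2 = 1000·fu·(A2/V2)/MW. The readout is the occupancy

    BTKocc = 100·(BTKrc + BTKcc)/(BTKf + BTKrc + BTKcc)

at the steady-state trough (24 h after the last dose). It is intended for
pharmacometricians and clinical pharmacologists exploring dose selection
and dose-reduction strategies: which once-daily doses keep more than 90% of
subjects above 90% occupancy over the whole dosing interval, and how the
answer depends on BTK turnover, which in CLL is uncertain (half-life
somewhere between 12 and 120 h).

The package provides:

- a compiled six-state simulator for individual regimens, including food
  and antacid effects on absorption (`simulate_profile()`,
  `qd_regimen()`, `reduction_regimen()`);
- virtual populations with lognormal between-subject variability and three
  BTK half-life scenarios — 60 h, 24 h, or uniform 12-120 h
  (`population_spec()`, `sample_individuals()`, `half_life_scenario()`);
- virtual trials, dose-response sweeps with common random numbers and
  kon/kinact uncertainty bands, sequential 28-day dose-reduction cycles,
  and sigmoid-Emax ED90 estimation (`run_virtual_trial()`,
  `dose_response_sweep()`, `simulate_dose_reduction()`,
  `estimate_ed90()`);
- evaluation against an embedded 320-observation table of measured
  occupancy proportions, pooled into dose groups with exact binomial
  intervals, plus a synthetic-study generator with residual assay error
  (`observed_occupancy()`, `pool_dose_groups()`,
  `predicted_vs_observed()`, `generate_synthetic_study()`).

## Worked example

Deterministic typical-patient troughs across doses and turnover rates:

```r
library(btksim)
typical_patient_profiles(doses_mg = c(140, 420), half_lives = c(24, 60))
#>   dose_mg t_half_h c2_trough_nM btkf_trough_nM reduction_pct ratio_c2_btkf occupancy_pct
#> 1     140       24         0.11         0.1167          88.8         0.941          88.8
#> 2     420       24         0.33         0.0470          95.5         7.016          95.5
#> 3     140       60         0.11         0.0496          95.2         2.217          95.2
#> 4     420       60         0.33         0.0193          98.1        17.095          98.1
```

Even at the trough, 420 mg once daily keeps free BTK 98% below baseline
when BTK turns over slowly (60 h half-life); faster turnover (24 h) lets
more BTK resynthesize between doses, and the lowest dose then only reaches
an 89% reduction.

A virtual trial in the uniform-turnover CLL population (intrinsic
occupancy at the day-7 trough, 2,000 subjects shared across doses):

```r
tr <- run_virtual_trial(c(140, 280, 420, 560), n = 2000, seed = 42)
summary(tr)
#>   dose_mg    n median    p5   p95 prop_gt90
#> 1     140 2000  95.05 80.99 98.55     79.30
#> 2     280 2000  97.16 87.77 99.23     91.70
#> 3     420 2000  98.01 90.79 99.48     96.15
#> 4     560 2000  98.46 92.71 99.60     97.70
```

The median subject exceeds 90% occupancy at every dose; the proportion of
subjects above 90% drops from ~96% at the standard 420 mg to ~79% at
140 mg — the basis for arguing that a reduction to 280 mg (per-subject
monotonicity and the 92% proportion) largely preserves target coverage.
`simulate_dose_reduction()` makes the same point dynamically across
sequential 420 → 280 → 140 mg cycles, and `estimate_ed90()` summarizes a
dose-response sweep by the dose reaching 90% of the fitted plateau.

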