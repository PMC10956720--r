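# corrscale

Box-scaling analysis of connected spatial correlations in neural
population recordings.

## What problem this solves

Single cortical neurons respond variably to repeated presentations of the
same stimulus. `corrscale` asks how that trial-by-trial variability is
organised *in space*: are the moment-to-moment deviations of individual
units from the population response correlated over distance, and does
that correlation have a characteristic scale? The package is aimed at
analyses of cellular two-photon calcium imaging, multi-electrode LFP
arrays, and simulated population rasters.

The core quantity is the connected correlation function

    C(r, L) = (1 / C0) *  < sum_{i != j} u_i(t) u_j(t) delta(r - r_ij) >
                          / < sum_{i != j} delta(r - r_ij) >,

where `u_i(t) = v_i(t) - vbar(t)` is unit i's signal after subtracting the
instantaneous mean over all units inside a square observation window of
side `L`, and `C0` normalises `C(0) = 1`. Subtracting the population mean
removes common input, so `C(r, L)` isolates correlations intrinsic to the
network. From the family of curves over window sizes the package derives:

* `r0(L)` — zero crossing of `C(r, L)`, via a cubic fit around the first
  sign change;
* `xi(L)` — integral correlation length,
  `xi^2 = ∫ r^2 C dr / ∫ C dr` over `(0, r0]`;
* a chi-squared test of linear growth of `xi` with `L`
  (`chi_c^2 = sum (xi - R)^2 / R` against the regression line `R(L)`),
  linear growth being the signature of scale-free, criticality-like
  correlations;
* the scaling collapse `C(r/r0) * r0^gamma = F(r/r0)` with the exponent
  `gamma` estimated from the decay of the correlation derivative at the
  rescaled crossing, and its collapse error `Delta`;
* the susceptibility `chi` (area under `C` up to `r0`), which peaks at a
  critical point.

Controls: `trial_shuffle()` (permute responses across repetitions of the
same stimulus, per unit) and `position_shuffle()` destroy the intrinsic
correlations while `pearson_vs_distance()` (no mean subtraction) shows
what common input alone produces — the key dissociation.

Synthetic data: a stochastic three-state excitable lattice model
(`lattice_config()`, `simulate_lattice()`) with distance-dependent
connectivity (K = 8 targets, exp(-r/5) kernel, cutoff 20, drive 1e-7)
whose transmission probability `P` tunes it across subcritical
(P = 0.059), critical (P = 0.066) and supercritical (P = 0.073) regimes,
plus Gaussian-field populations with known correlation scale and
trial-structured evoked surrogates with common input
(`gaussian_field_population()`, `evoked_surrogate()`).

## Worked example

A critical lattice (S = 96, P = 0.066), analysed on its central 40 x 40
observation grid with six window sizes and a trial-shuffling control:

```r
library(corrscale)
cfg <- run_config(
  input = list(type = "lattice", S = 96, P = 0.066, steps = 2e5,
               bin_steps = 100, obs_side = 40, n_trials = 10),
  L_values = c(12, 16, 20, 24, 32, 40),
  bin_width = 1, stride = 4, shuffle = "trial", seed = 1)
bundle <- run_pipeline(cfg)
writeLines(bundle$report)
```

prints

```
== box-scaling correlation analysis ==
windows analysed: 12, 16, 20, 24, 32, 40
L, r0, xi:
        12    2.711   0.9198
        16    4.906     1.94
        20    7.357    2.929
        24    10.44     4.12
        32    14.83    5.845
        40    18.92    7.622
gamma = 0.648   Delta = 0.0003608   chi = 0.3466
linear xi(L): slope = 0.2398, chi_c^2 = 0.02491 (df = 4), p_upper = 1, p_lower = 7.69e-05, R^2 = 0.9976
xi/r0 CV = 0.0614
shuffle control (trial): gamma = NA, Delta = NA, first-bin C (largest window) = 0.002393
```

Reading it: the zero crossing `r0` and the correlation length `xi` both
grow with the window — `xi(L)` is linear to `R^2 = 0.998` (`p_upper = 1`:
the points are fully consistent with the line), the collapse exponent is
0.65 with a small collapse error, and `xi/r0` is constant to 6%, as the
collapse predicts. After trial shuffling the correlation function is flat
at zero (first bin 0.002 versus ~0.05 before), so the spatial structure
lives in the within-trial co-fluctuations, not in anything
stimulus-locked.

## Package tour

| area | functions |
|---|---|
| containers | `population_recording()`, `read_recording()`, `write_recording()` |
| response statistics | `baseline_normalize()`, `trial_responses()`, `variance_mean_ratio()`, `direction_selectivity()`, `dsi_significance()` |
| lattice model | `lattice_config()`, `build_connectivity()`, `simulate_lattice()`, `lattice_to_recording()`, `measure_branching()`, `lattice_box_family()`, `lattice_extent_family()` |
| surrogates | `surrogate_spec()`, `gaussian_field_population()`, `evoked_surrogate()` |
| correlation | `smooth_time()`, `enumerate_windows()`, `subtract_population_mean()`, `correlation_vs_distance()`, `windowed_correlation()`, `average_over_windows()`, `zero_crossing()`, `pearson_vs_distance()`, `trial_shuffle()`, `position_shuffle()` |
| scaling | `correlation_length()`, `gamma_estimate()`, `collapse_curves()`, `susceptibility()`, `linear_scaling_test()`, `xi_r0_ratio()`, `xi_saturation_ratio()` |
| pipeline | `run_config()`, `run_pipeline()`, `report_bundle()`, `generate_fixtures()` |

A thin command-line wrapper over the same functions lives at
`inst/exec/corrscale` (subcommands `simulate`, `correlate`, `run`,
`fixtures`, `report`). The methods vignette
(`vignettes/box-scaling-methods.Rmd`) documents the estimators, the
model, and every numerical design choice in detail.
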