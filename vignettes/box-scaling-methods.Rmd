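---
title: "Box scaling of connected correlations: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box scaling of connected correlations: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrscale)
```

## The problem

Repeated presentations of the same stimulus (or repetitions of the same
movement) evoke variable responses in single cortical neurons. corrscale
quantifies the *spatial* organisation of that trial-by-trial variability.
The central object is the connected correlation function

$$C(r) = \frac{1}{C_0}\,
\frac{\sum_{i \ne j} \langle u_i(t)\, u_j(t) \rangle_t\, \delta(r - r_{ij})}
     {\sum_{i \ne j} \delta(r - r_{ij})},
\qquad u_i(t) = v_i(t) - \bar v(t),$$

where $v_i(t)$ is the signal of unit $i$ (dF/F, estimated spikes, LFP
amplitude, or binned model activity), $\bar v(t)$ is the instantaneous mean
over all units inside the observation window, $r_{ij}$ is the pair
distance, and $C_0$ is the $r \to 0$ self term
$\langle u_i^2 \rangle_{i,t}$, so that $C(0) = 1$ by construction.
Subtracting $\bar v(t)$ removes whatever is common to the whole observed
population at each moment — the stimulus-locked response and any global
drive — so $C(r)$ measures how the *residual* fluctuations of different
units co-vary as a function of distance.

Because the cortex (or the model lattice) is much larger than any
practical recording, the analysis varies the size $L$ of compact square
observation windows into the fixed system ("box scaling") instead of the
system size itself. For each $L$, $C(r, L)$ decays with $r$ and crosses
zero at $r_0(L)$; the correlation length is the integral scale

$$\xi^2(L) = \frac{\int_0^{r_0} r^2\, C(r, L)\, dr}{\int_0^{r_0} C(r, L)\, dr},$$

with $C$ forced to 0 at both $r = 0$ and $r = r_0$, so the quadrature
effectively starts at the shortest sampled pair distance. Linear growth of
$\xi(L)$ with $L$ — rather than saturation at some intrinsic scale — is
the signature of scale-free correlations, as expected at a critical point.
When the whole family $C(r, L)$ collapses onto one function
$F(r/r_0)$ after rescaling distances by $r_0(L)$ and amplitudes by
$r_0(L)^\gamma$, the correlations have no characteristic scale within the
observed range, and $\xi(L) \propto r_0(L)$ follows analytically from the
collapse by a change of variables in the two integrals.

## Estimators and their numerical choices

**Distance binning.** The smoothed delta function is realised as
fixed-width distance bins: width equal to the median nearest-neighbour
distance for scattered populations, or the grid/electrode pitch for
gridded data (`distance_breaks()`, `bin_width`). Bins without pairs are
omitted. Refining the bin width moves $r_0$ by less than one coarse bin on
smooth data (tested).

**Zero crossing.** $r_0$ is the root of a cubic least-squares fit to the
bins within three bins of the first sign change, scanned from the smallest
distance (later re-crossings are noise-dominated). The root is constrained
to the bracketing interval, with linear interpolation as fallback. The
same fit supplies $dC/dr$ at $r_0$, hence the rescaled derivative
$dC/dr'|_{r'=1} = r_0\, dC/dr|_{r_0}$ used for the collapse exponent. If
$C$ never changes sign the crossing is flagged undefined rather than
raising an error.

**Quadrature.** All integrals ($\xi$, susceptibility $\chi$) use the
trapezoid rule on the observed bins with the stated end conditions. With
100 bins the closed forms $\xi = R/\sqrt 3$ (constant $C$),
$\xi = R/\sqrt 6$ and $\chi = R/2$ (linear $C$) are reproduced to better
than 1%.

**Windows.** All axis-aligned squares of side $L$ at a configurable
stride; windows with fewer than 5 units are discarded because the
population-mean subtraction is strongly biased for tiny populations (for
$N$ independent units the floor of the estimator is $-1/(N-1)$, which the
suite verifies). Per-bin results are pooled across windows weighted by
pair count, which equals pooling all pairs. The default stride is $L/8$
for scattered units; for lattice analyses we use a stride of a few grid
steps — the exhaustive one-step stride is available but changes results
negligibly while multiplying runtime.

**Temporal smoothing.** An optional per-unit running median
(`smooth_time()`; 20 samples is a typical choice for 2-photon calcium
recordings, 8 for LFP arrays) stabilises the estimates for continuous
data. It is off by default for simulated spike counts, where a median
filter of a sparse train is degenerate.

**Frames.** Frames are restricted by trial epoch label (stimulus-on
versus baseline) and pooled across trials; a per-trial variant would
average correlation functions over trials instead. Pooling is the default
because the estimator is a time average either way, and pooling weights
every frame equally.

## The collapse exponent and its sign

$\gamma$ is estimated by fitting a power law to the magnitude of the
rescaled derivative $|dC/dr'|_{r'=1}$ against $r_0(L)$ on log-log axes
(fitting against $r_0$ rather than $L$ is the default: the two are
proportional exactly when scaling holds, and $r_0$ is the quantity the
rescaling actually uses; `gamma_x = "L"` selects the alternative).
`gamma_estimate()` reports

* `gamma` — the magnitude of the fitted exponent, the number quoted as
  "the collapse exponent"; and
* `gamma_signed` — the signed exponent, which is what the amplitude
  rescaling $C \cdot r_0^{\gamma_s}$ in `collapse_curves()` uses.

The sign deserves a remark. For continuous signals whose correlation
amplitude decays with window size, the signed and quoted exponents
coincide. For the lattice model analysed as binned spike counts, the
amplitude of $C(r, L)$ at fixed $r$ *grows* approximately as
$r_0(L)^{+0.8}$: the subtracted window mean removes less of the global
activity fluctuation in larger windows, and the self-term normalisation
$C_0$ is dominated by shot noise and therefore window-independent. The
magnitude of the exponent is the meaningful, convention-free quantity; the
direction of the amplitude rescaling is carried separately and
transparently by `gamma_signed`.

## Collapse error

`collapse_curves()` maps each curve to $(r/r_0,\ C \cdot r_0^{\gamma_s})$,
resamples onto a common grid of 50 points on $(0, 1.2]$ by linear
interpolation, and averages to estimate $F$. There are no free parameters
and no minimisation over $\gamma$. Three error summaries are returned:

* `Delta` — the mean absolute deviation of the rescaled curves from $F$;
* `Delta_rel` — `Delta` divided by the mean magnitude of $F$;
* `Delta_shape` — the same deviation after normalising every rescaled
  curve to unit mean magnitude.

`Delta` is the plain definition but is dominated by overall curve
amplitude when conditions are compared: in the lattice model the critical
correlation amplitudes are about three times the off-critical ones, so raw
`Delta` ranks regimes by amplitude, not by collapse quality.
`Delta_shape` is invariant to any per-curve rescaling and measures purely
whether the curves share one shape; it is the quantity that is robustly
minimised at criticality and the one the regime-discrimination tests use.

## Linear-growth statistic

`linear_scaling_test()` fits $R(L)$ by ordinary least squares and forms
$\chi_c^2 = \sum_i (\xi(L_i) - R(L_i))^2 / R(L_i)$ with $n - 2$ degrees of
freedom (two fitted line parameters). Both tails of the reference
chi-squared distribution are reported: `p_upper` is the conventional
goodness-of-fit probability — *large* when the points hug the line — and
`p_lower` the probability of a fit at least this good by chance. Reports
of small p-values as evidence *for* linearity invert the usual
goodness-of-fit reading; the package computes both tails and leaves the
interpretation explicit rather than guessing a convention. The statistic
is calibrated in the suite: under homoskedastic Gaussian scatter with
variance equal to the regression level, its distribution is
indistinguishable from $\chi^2_{n-2}$ by a KS test over 1000 replicates.

## The lattice model

The synthetic criticality benchmark is a stochastic three-state excitable
lattice: $S^2$ units on a periodic square grid, states rest / active /
two refractory steps. Each unit projects to $K = 8$ targets drawn with
probability $\propto e^{-r/R_0}$ ($R_0 = 5$ lattice units) under a hard
cutoff $I_c = 4 R_0 = 20$, sampled without replacement by minimum-image
distance. A resting unit fires at the next step with probability
$1 - (1-h)(1-P)^a$, where $a$ counts its active neighbours, $P$ is the
transmission probability per link, and $h = 10^{-7}$ per unit per step is
a weak Poisson drive. Updates are synchronous; runs start from rest and
discard a $10^4$-step burn-in.

**Coupling semantics.** The package treats the $K$ drawn links as
*symmetric* couplings by default: a unit's interacting neighbours are the
union of its targets and its sources, giving mean degree close to
$2K = 16$. This choice is forced by the model's stated operating points:
with strictly directed links the branching parameter at vanishing activity
is $\sigma \approx K P = 0.53$ at $P = 0.066$ — deeply subcritical, with
the susceptibility peak far above the studied range of $P$ — whereas with
symmetric couplings the measured branching ratio reaches 1 at
$P \approx 0.066 \approx 1/(2K)$, and the susceptibility scan peaks at the
grid point nearest 0.066, exactly where the critical / subcritical (0.059)
/ supercritical (0.073) reference points sit. `coupling = "directed"` is
available for comparison. The branching ratio itself is measured by
`measure_branching()` as the ratio of successive population activity,
and increases monotonically with $P$ (tested).

**Time binning.** The analysis time bin for simulated activity is exposed
as `bin_steps` (default 100 steps in the packaged workflows): fine enough
that frames resolve individual propagation events, coarse enough that
co-active cluster members land in the same frame. The scaling conclusions
(growth of $r_0$ with $L$, linearity of $\xi(L)$, peak of $\chi$ at the
critical $P$) are stable across bins from 10 to 1000 steps; the exponent
magnitude varies by roughly $\pm 0.1$ across that range.

**Workflows and problem sizes.** `lattice_box_family()` pools connected
correlation functions across independent runs (wiring and dynamics both
reseeded) on a central observation grid. The packaged demonstrations use:
for the collapse exponent, $S = 128$, a $48 \times 48$ observation grid,
nine windows $L = 14 \ldots 48$, $5 \times 10^5$ recorded steps, twelve
runs pooled (per-run derivative estimates are far too noisy — pooling the
curves first is the analogue of averaging curves over animals before
fitting); for the susceptibility scan, $S = 96$ with three runs per $P$;
for regime discrimination, $S = 160$ with windows up to $L = 96$, since
at $P = 0.059$ the intrinsic correlation scale is comparable to 40 grid
units and saturation of $\xi(L)$ only becomes visible beyond it. These
sizes were chosen as the smallest at which the respective effects are
stable across master seeds.

## Surrogate generators

`gaussian_field_population()` draws stationary zero-mean series with
pairwise covariance $\sigma^2 e^{-d/\lambda}$ at uniformly scattered
positions (Cholesky factorisation with a $10^{-10}$ diagonal jitter). It
is the parameter-recovery oracle: the downstream $\xi$ must increase
monotonically with the imposed $\lambda$, and the sampled covariance is
verified entrywise against the kernel. `evoked_surrogate()` adds trial
structure: a stimulus-locked waveform *identical across units* (common
input), plus the Gaussian-field residual, plus i.i.d. unit noise, with
stimulus order randomised under seed.

These surrogates emulate spatially correlated residual variability and
common input, but not: calcium-indicator dynamics (rise/decay kernels,
saturation), non-stationary state drift, inhomogeneous unit density, or
spike-count discreteness. Passing the recovery tests therefore shows the
estimators are correct for stationary Gaussian spatial structure, not that
real recordings satisfy those assumptions.

**Controls.** `trial_shuffle()` permutes each unit's responses across
repetitions of the same stimulus independently per unit, destroying
within-trial co-fluctuations while preserving everything stimulus-locked;
`position_shuffle()` permutes unit positions. After trial shuffling the
connected $C(r)$ drops to the estimator's floor: exactly zero is not
attainable, because the mean subtraction contributes $-1/(N-1)$ and pairs
fall into the same source trial with probability $1/n_\text{repeats}$,
retaining that fraction of the original correlation. The control tests
bound the shuffled curve by this known finite-sample zero. The
dissociation with the no-subtraction analysis is the key contrast: the
plain pairwise Pearson $C(r)$ of a common-input surrogate stays positive
at all distances *even after trial shuffling*, which is why linear growth
of a Pearson-based correlation length is not evidence of intrinsic
correlations.

## Small response statistics

`baseline_normalize()` implements the sliding low-percentile baseline for
dF/F (mean of samples at or below the 10th percentile of the preceding
40-frame window; during warm-up all preceding frames are used, and the
first frame serves as its own baseline — the initial-condition rule is
unstated in the field and this choice is the least surprising one).
`variance_mean_ratio()` divides response variance by response mean across
repetitions within stimulus (Poisson reference = 1).
`direction_selectivity()` uses $\mathrm{DSI} = (R_P - R_O)/(R_P + R_O)$
with the preferred direction chosen as the argmax of the trial-mean
response, ties broken toward the lowest angle for determinism;
significance comes from reassembling the spike train with permuted
inter-spike intervals (`dsi_significance()`, 1000 surrogates by default).
The ISI-shuffle null preserves burstiness, so it is conservative for
sparsely firing units.

## Known limitations

* Box scaling is a proxy for true finite-size scaling; windowed and
  whole-system analyses agree on the length scalings ($r_0$, $\xi$) but
  can differ in amplitude exponents, as the sign discussion above makes
  explicit.
* Regimes slightly off criticality are hard to distinguish when the
  intrinsic scale exceeds the largest window; the saturation diagnostic
  (`xi_saturation_ratio()`) needs windows beyond that scale.
* The chi-squared linearity statistic assumes scatter with variance
  proportional to the regression level; for pooled curves the residuals
  are partly systematic, so its p-values are descriptive, not inferential.
* `trial_shuffle()` requires equal trial lengths within a stimulus group
  and leaves inter-trial frames untouched.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- run_config(
  input = list(type = "lattice", S = 96, P = 0.066, steps = 2e5,
               bin_steps = 100, obs_side = 40),
  L_values = c(12, 16, 20, 24, 32, 40),
  bin_width = 1, stride = 4, shuffle = "trial", seed = 1,
  out_dir = "lattice_demo")
bundle <- run_pipeline(cfg)
writeLines(bundle$report)
```
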