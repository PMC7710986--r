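---
title: "Models and methods: simulating and fitting hexacoordinate globin kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glbkin)
```

## The system

Class 1 phytoglobins are hexacoordinate hemoglobins: in the unliganded
ferrous state the distal histidine (His_d) occupies the sixth coordination
position of the heme iron. Exogenous ligands (O2, CO, NO) can only bind the
transient pentacoordinate state, so binding is *gated*,

$$ 6c \xrightleftharpoons[k_{H}]{k_{-H}} 5c
   \xrightarrow{k'_{on}[L]} \text{bound}, $$

with observed pseudo-first-order rate

$$ k_{obs} = \frac{k_{-H}\,k'_{on}[L]}{k_{H} + k'_{on}[L]}, $$

bounded above by the His_d off-rate $k_{-H}$. Once ligand capture
outcompetes His re-association, $k_{obs}$ becomes independent of ligand
concentration — the experimental signature that `classify_dependence()`
detects.

`glbkin` models a globin as one or two heme sites (`protein_model()`,
`heme_site()`), each carrying the per-site constants of the five supported
assays, and realises each assay as a mass-action reaction network
(`build_scheme()`) integrated with a stiff solver (`simulate_scheme()`,
`deSolve::lsoda`, relative tolerance 1e-8, absolute tolerance 1e-12 M).
Two-site proteins get an independent heme-state chain per site; free ligand
pools are shared, which matters (see *Numerical choices*).

The bundled parameterisations `glb_wt1()` (two non-equivalent hemes) and
`glb_wt4()` (one heme) carry the published constants: O2 dissociation
0.319/0.190 and 0.277 s^-1; apparent CO association 11.7e5/1.32e5 and
1.43e5 M^-1 s^-1; gated NO binding 126 and 114 s^-1; nitrite reduction 726
and 382 M^-1 s^-1 at pH 7.

## The four assays

**Dithionite-trap O2 dissociation.** Oxyferrous protein is mixed with
excess dithionite, which scavenges free O2 (one coarse-grained bimolecular
step, `k_trap`) in competition with rebinding; the deoxy product relaxes
into the hexacoordinate state. The observed rate rises hyperbolically with
trap concentration and saturates at the true `k_off`, which
`fit_trap_saturation()` extracts, mirroring how such data are analysed.

**Flash photolysis.** `CO_rebinding_LFP` starts from the photolysed carboxy
complex (instantaneous initial-state transformation; fraction configurable,
default 1). With dithionite and no O2 the scheme yields pure CO rebinding.
With O2 present, O2 is captured within microseconds and then displaced by
CO in the dark; exact mass action shows the slow oxy-to-carboxy rate is
$k_{off}\,k_{CO}[CO]/(k_{CO}[CO]+k_{O2}[O_2]_{free})$, which equals
$k_{off}$ — the observed behaviour — only when the liberated O2 is removed.
The scheme therefore includes the O2 scavenging step whenever dithionite is
present, and the displacement property is simulated in that configuration.

**NO binding.** Deoxyferrous protein (initialised at the 6c/5c gating
equilibrium) plus NO. For gated sites the observed rate is `k_-H`-limited;
for distal-His-null mutants binding proceeds at the intrinsic rate and
outruns the stopped-flow dead time entirely.

**NO dioxygenase (NOD).** Oxyferrous + NO gives ferric + nitrate
(`k_NOD`, default 7e7 M^-1 s^-1, consistent with the reaction completing
within the mixing dead time at 5 uM NO), followed by weak ferric-NO
complexation (1e4 M^-1 s^-1 on, 1 s^-1 off) that reproduces the qualitative
ferric-to-ferric-NO spectral sequence.

**Nitrite reductase (NiR).** Deoxyferrous + nitrite under excess
dithionite: each turnover oxidises one heme (quickly re-reduced,
pseudo-first-order 10 s^-1, present only when dithionite is) and releases
one NO, which captures another deoxy heme. The net deoxy decay is
therefore pseudo-first-order at $k_{NiR}[\mathrm{NO_2^-}]$, the quantity
regressed by `fit_second_order()`. Without reductant the ferric species
accumulates instead of the nitrosyl end state. The reactive species is
nitrous acid, so the apparent constant scales with the protonated fraction
(`nitrite_rate()`: $f(\mathrm{pH}) = 1/(1+10^{\mathrm{pH}-pK_a})$,
$pK_a = 3.25$ at 25 C), giving a log-slope of -1 per pH unit well above the
pKa.

## Parameters the experiments do not determine

Several constants needed for simulation are not experimentally resolved;
they were fixed once, as follows, and are all configurable:

* **`k_H` = 500 s^-1** (His_d re-association). Two observations constrain
  it jointly: the deoxyferrous spectra are predominantly hexacoordinate
  (requiring $k_H \gtrsim 4k_{-H}$), and NO binding at 10-160 uM is
  concentration independent (requiring $k'_{on}[NO] \gg k_H$ already at
  10 uM). With $k_{-H} \approx 126$ s^-1, 500 s^-1 gives ~80% 6c at
  equilibrium — a moderate hexacoordination equilibrium, consistent with
  the strained ("highly anisotropic low spin") His coordination seen
  spectroscopically.
* **`k_prime_on_NO` = 5e9 M^-1 s^-1.** Chosen so the gate, not NO
  association, is rate limiting across the whole titration (capture flux
  5e4 s^-1 at 10 uM, >=99% of saturation). This is deliberately near the
  diffusion limit; the data constrain only a lower bound, and the His-null
  mutants' dead-time-censored binding is insensitive to the exact value.
* **`k_on_O2` = 1e9 M^-1 s^-1**, above the measured floor of 5e8 (a bound,
  not a value).
* **`k_trap` = 5e6 M^-1 s^-1.** The dithionite radical mechanism is
  deliberately not modelled. The value is set so that trapping dominates
  rebinding for *both* proteins across the 6.75-27.5 mM titration while
  saturation behaviour remains visible: with a slower trap the shared
  free-O2 pool of the two-heme protein couples the sites (fast-site O2
  rebinds the slow site), the decays become non-exponential, and the
  biphasic fit misestimates the fast rate by >15% even without noise.

## Synthetic data and what it does (not) emulate

`apply_instrument()` converts trajectories to absorbance by Beer-Lambert at
one wavelength, discards everything before the dead time (1.2 ms stopped
flow; 5 us flash-photolysis detector), resamples at the instrument
interval, and adds homoscedastic Gaussian noise (default 0.002 AU — typical
diode-array noise; none is stated for the original instruments). Per-trace
seeds derive deterministically from a master seed (`derive_seed()`,
counter-hash), so datasets are bit-reproducible. `truth` blocks carry the
generating parameters for recovery studies.

Observation channels: trap, NO-binding and NiR traces are read near the
deoxyferrous Soret (423-424 nm); the NOD reaction at 417 nm where the
oxyferrous and ferric bands separate best. The trap assay is sampled at
20 ms over 30 s: resolving two dissociation rates only 1.68-fold apart at
0.002 AU noise needs the photometric channel's time resolution — at the
200 ms full-spectrum scan interval the per-trace biphasic rates scatter by
~15% and the phase pair is not reliably recoverable. Non-equivalent signal
contributions of the two hemes are expressed through `signal_weights`
(60:40 in the analyses here; the amplitude split is otherwise
unconstrained).

The generator does **not** emulate: mixing artefacts, geminate
recombination faster than the detector limit, baseline drift, wavelength
calibration error, or heteroscedastic shot noise. Passing recovery tests
therefore demonstrates the inference chain is correct and well-conditioned
under idealised instrument physics, not that it is robust to every
pathology of real stopped-flow data.

Spectra are sums of Gaussian bands (`species_catalogue()`): measured
positions for the ferric (410/532/563 nm), deoxy 6cLS (423/527/556 nm,
one catalogue value resolving the 422-424 nm spread across experiments) and
deoxy 5cHS (435 nm) species; generic globin positions, flagged
`non_measured`, for the oxyferrous, carboxy and nitrosyl complexes. All
Soret peaks share the 150 mM^-1 cm^-1 quantitation coefficient — an
approximation the data only support for the ferric form. Q/Soret amplitude
ratio defaults to 0.1; Soret widths 10 nm (6cLS) and 14 nm (5cHS), Q widths
14 nm (chosen to match the published spectra's proportions visually).

## The fitting chain

`fit_multiexponential()` fits $b + \sum_i a_i e^{-k_i t}$ by separable
(variable-projection) least squares: for trial rates the baseline and
amplitudes are profiled out linearly, and the rates are optimised from five
deterministic log-spaced starts. The signal is internally normalised to
unit range so convergence is amplitude-scale invariant. The phase count
(0-2) is chosen by AICc, then guarded: a phase below 5% amplitude share, or
within 1.5-fold of another phase's rate, is demoted to the simpler model
(the data cannot support it). Uncertainties come from the local quadratic
approximation. Fitting is unweighted, treating the noise as homoscedastic.

`censored_bound()` implements dead-time censoring: with samples every
$\Delta t$, a reaction with apparent half time below $2.5\Delta t$ (3 ms at
the 1.2 ms default) cannot be characterised, and only the lower bound
$\ln 2 / (2.5\Delta t) = 231$ s^-1 is reported. A trace is censored when at
least 95% of the expected amplitude (known from initial/final spectra) is
already missing at the first observable sample, *or* when the apparent half
time — read non-parametrically off the trace as the first crossing of half
the expected amplitude — falls below the resolution limit. The
non-parametric half time matters: an exponential fit is biased upward by
the second-order tail of the NOD reaction at near-stoichiometric NO, which
would make censoring of a 350 s^-1 reaction depend on the noise seed. The
bound is reported as computed (231 s^-1), not rounded to a half-decade.

`classify_dependence()` calls a titration gated (concentration independent)
when the slope's 95% CI contains zero *and* the linear model fails to
improve on the constant model by 2 AICc units, or when the dependence is
kinetically negligible — the fitted line predicts less than 5% change in
$k_{obs}$ across the measured range. The second branch is an equivalence
criterion, needed because the gated mechanism itself retains a sub-percent
residual saturation curvature that arbitrarily precise rate estimates will
eventually detect as a "significant" slope; a bimolecular rate, by
contrast, scales with the concentration span itself (16-fold over a
16-fold range), so the two verdicts cannot be confused. Fewer than 3
concentrations or less than a 4-fold span is `indeterminate`. No
multiple-testing correction is applied (one planned comparison per assay).

`affinity_constants()` combines the association floor with fitted
dissociation rates into minimum affinity constants, reported at the
two-significant-figure precision such constants carry.

## Numerical choices and degenerate inputs

* Integration: `lsoda` with rtol 1e-8, atol 1e-12 M; the internal step is
  capped at 1/40 of the grid span (with a retry ladder) because schemes
  that go flat after a stiff transient can otherwise push the
  interpolation window past requested output times. Per-site heme
  conservation holds to ~1e-14 relative in all assays (tested at 1e-8).
* `hexacoordinate_kobs()` degenerate inputs: zero ligand gives 0; zero
  `k_H` with ligand present gives exactly `k_minus_H`.
* `fit_trap_saturation()` on spread-free rates returns the saturated limit
  (`k_max` = the common value, `c_half` = 0) without invoking the nonlinear
  fitter; a fitted `c_half` beyond the titration range raises an
  extrapolation warning.
* `unmix_series()` requires a full-rank basis and names the collinear pair
  otherwise; non-negativity is enforced per time point
  (`pracma::lsqnonneg`).
* Savitzky-Golay derivatives (order 4, 15 points) trim half a window at
  each edge; band positions from `d2_minima()` are window-invariant even
  though the D2 values themselves carry window-dependent smoothing bias.

## Problem sizes used in the checks

The recovery studies run at the assay's own scale: trap titrations are
triplicates at three dithionite concentrations (9 traces of ~1500 points),
repeated over 100 noise realisations for the one-heme recovery study; the
NiR regression uses 5 nitrite concentrations repeated over 50 seeds; the
closed-form/ODE cross-check spans a (k_H, capture-flux) grid of more than
four decades. These sizes make the Monte-Carlo statements (e.g. ">=95% of
runs within 5%") meaningful while each study still runs in seconds to a
couple of minutes.

## Known limitations

* The dithionite trap and ferric re-reduction are single coarse-grained
  steps with effective constants; they reproduce the assays' observable
  behaviour but not dithionite radical chemistry.
* Amplitude shares of the two hemes are free parameters of the generator,
  not predictions.
* No global multi-trace fitting, Bayesian inference, autoxidation, or
  temperature dependence; pH enters only through the nitrous-acid
  equilibrium.
* The per-molecule vs per-heme normalisation of the two-heme NiR constant
  cannot be decided from bulk data; both conventions are exposed
  (`glb_wt1(nir_convention=)`) and reported.
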