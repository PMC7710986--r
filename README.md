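# glbkin

Ligand-binding kinetics of one- and two-heme hexacoordinate phytoglobins:
mechanistic simulation of the classical rapid-kinetics assays and the
inference chain that turns absorbance time courses back into rate
constants, censored bounds and oxygen affinities.

## The problem

Class 1 phytoglobins are plant hemoglobins whose heme iron is
*hexacoordinate*: a distal histidine (His_d) occupies the sixth
coordination position, so every exogenous ligand (O2, CO, NO) must wait for
the His gate to open. The observed binding rate is

```
k_obs = k_-H * k'_on[L] / (k_H + k'_on[L])      (bounded by k_-H)
```

which saturates at the His_d off-rate and becomes independent of ligand
concentration — the signature that separates gated binding from ordinary
bimolecular kinetics. These proteins combine very slow O2 release with
extremely fast O2 capture (affinities in the 1e9 M^-1 range, Kd below a
nanomolar), scavenge NO through their NO dioxygenase activity when O2 is
present, and *produce* NO from nitrite when it is not — a pH-dependent
nitrite reductase whose reactive species is nitrous acid.

Characterising this behaviour experimentally means four assays, each with
its own trick: dithionite-trap O2 dissociation (the trap scavenges free O2
so the oxyferrous decay reports `k_off`), laser-flash CO
rebinding/displacement, stopped-flow NO binding, and anaerobic nitrite
reduction. `glbkin` implements each assay as a mass-action ODE scheme,
generates instrument-realistic synthetic data (dead times, discrete
sampling, photometric noise, seeded replicates), and provides the fitting
chain used on such data: multi-exponential decomposition with
information-criterion phase selection, hyperbolic trap-saturation fits,
second-order regression, concentration-independence classification,
dead-time censoring bounds, spectral second-derivative deconvolution and
non-negative unmixing.

The package is aimed at kineticists who want to sanity-check an analysis
pipeline against data with known ground truth, and at modellers who want a
compact, tested simulator of hexacoordinate-globin reaction schemes.

## Worked example

Simulate a dithionite-trap titration for the one-heme protein (generating
`k_off` = 0.277 s^-1), refit it blind, and derive the minimum O2 affinity:

```r
library(glbkin)

wt4 <- glb_wt4()
trap <- trap_koff_experiment(wt4, seed = 42)   # 3 x triplicate, 0.002 AU noise
trap$k_off
#>    phase1
#> 0.2771454

aff <- affinity_constants(5e8, trap$k_off[["phase1"]])
sprintf("K >= %.2g /M, Kd <= %.2g nM", aff$K_2sf, aff$Kd_2sf * 1e9)
#> "K >= 1.8e+09 /M, Kd <= 0.55 nM"
```

The recovered dissociation rate is within 0.1% of the generator, and the
affinity chain reproduces the two-significant-figure constants such data
support: a minimum association constant of 1.8e9 M^-1, i.e. an equilibrium
dissociation constant below 0.6 nM.

Gated NO binding and nitrite reduction, same pattern:

```r
no <- no_binding_experiment(glb_wt1(), seed = 42)   # 10-160 uM NO
sprintf("NO binding: %s, k_NO = %.0f /s", no$verdict, no$mean_kobs)
#> "NO binding: gated_independent, k_NO = 125 /s"

nir <- nir_experiment(wt4, seed = 42)               # 0.05-1 mM nitrite
sprintf("NiR: k = %.0f /M/s (%s)", nir$k_nir_per_heme, nir$verdict)
#> "NiR: k = 377 /M/s (bimolecular_dependent)"

compare_to_references(382)[c("SynHb", "sperm_whale_Mb", "human_neuroglobin")]
#>             SynHb    sperm_whale_Mb human_neuroglobin
#>              5.62            132.00           1530.00
```

The NO titration is flat at the gate rate (generator 126 s^-1); the
nitrite titration is linear with slope near the generating 382 M^-1 s^-1;
and the fold-change table places the nitrite-reductase activity 5.6-fold
above the cyanobacterial SynHb and two orders of magnitude above sperm
whale myoglobin.

## Analysis workflow

The `analysis/` scripts run the full study over the packaged protein
models, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_assays.R     # synthetic datasets (CSV)
Rscript analysis/02_oxygen_kinetics.R     # trap fits, recovery study, displacement, affinities
Rscript analysis/03_no_and_nitrite.R      # NO gating, censoring, NiR regression, pH, references
Rscript analysis/04_spectral_analysis.R   # D2 deconvolution, spectral unmixing
```

Every step is a thin driver over exported package functions; the vignette
(`vignettes/glbkin-methods.Rmd`) documents the models, the synthetic-data
assumptions and the numerical choices.

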