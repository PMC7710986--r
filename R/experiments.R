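# End-to-end assay pipelines: simulate -> instrument -> fit. These are the
# workhorses behind the analysis scripts, the test-suite recovery studies
# and the acceptance report.

# Add a fresh noise realisation to the noiseless signal kept in a trace's
# truth block (cheap replication without re-integrating the ODE system).
.renoise <- function(tc, seed) {
  noiseless <- tc$truth$noiseless
  sdev <- tc$instrument$noise_sd
  noise <- .with_seed(seed, stats::rnorm(length(noiseless), 0, sdev))
  tc$signal <- noiseless + noise
  tc$seed <- seed
  tc
}

# Average fitted rates over replicates at each varied value. `n_phases`
# fixes how many rates are extracted per trace (sorted descending).
.kobs_table <- function(traces, max_phases = 1) {
  rows <- lapply(traces, function(tc) {
    fit <- fit_multiexponential(tc, max_phases = max_phases)
    ks <- sort(fit$rates, decreasing = TRUE)
    data.frame(value = tc$truth$value, replicate = tc$truth$replicate,
               phase = seq_along(ks), kobs = ks,
               n_phases = fit$n_phases)
  })
  do.call(rbind, rows)
}

#' Dithionite-trap oxygen-dissociation experiment
#'
#' Simulates the trap assay over a dithionite titration, fits each trace
#' with single-vs-double exponential selection, averages the observed rates
#' per phase across replicates, and extracts the limiting `k_off(O2)` per
#' phase from a hyperbolic saturation fit.
#'
#' @param protein a [protein_model()].
#' @param dithionite_concs trap concentrations, M (default the 6.75, 13.5,
#'   27.5 mM series).
#' @param n_replicates replicates per concentration (default 3).
#' @param seed master seed.
#' @param instr,wavelength instrument overrides.
#' @param traces optional pre-generated dataset (bypasses simulation).
#' @return List: `kobs` (per trace, phase-resolved), `saturation` (per
#'   phase hyperbola fits), `k_off` (named vector of limiting rates,
#'   fastest first), `n_phases_mode` (most frequently selected phase
#'   count).
#' @export
trap_koff_experiment <- function(protein,
                                 dithionite_concs = c(6.75, 13.5, 27.5) * 1e-3,
                                 n_replicates = 3, seed = 1,
                                 instr = NULL, wavelength = NULL,
                                 traces = NULL) {
  max_phases <- length(protein$sites)
  if (is.null(traces)) {
    cond <- assay_conditions("O2_dissociation_trap")
    traces <- generate_assay_dataset(protein, cond, "dithionite_conc",
                                     dithionite_concs, n_replicates, seed,
                                     instr = instr, wavelength = wavelength)
  }
  kobs <- .kobs_table(traces, max_phases = max_phases)
  n_phases_mode <- as.integer(names(which.max(table(kobs$n_phases))))
  phases <- sort(unique(kobs$phase))
  saturation <- lapply(phases, function(ph) {
    sub <- kobs[kobs$phase == ph, ]
    agg <- stats::aggregate(kobs ~ value, data = sub, FUN = mean)
    fit_trap_saturation(data.frame(conc = agg$value, kobs = agg$kobs))
  })
  names(saturation) <- paste0("phase", phases)
  k_off <- vapply(saturation, `[[`, numeric(1), "k_max")
  list(kobs = kobs, saturation = saturation, k_off = k_off,
       n_phases_mode = n_phases_mode)
}

#' Repeated-seed recovery study for the trap experiment
#'
#' Runs `n_runs` noise realisations of [trap_koff_experiment()] on shared
#' deterministic trajectories (only the noise is redrawn, seeds derived
#' from the master) and reports the recovered limiting rate per run.
#'
#' @param protein a one-phase-per-site [protein_model()].
#' @param n_runs number of seeded runs (default 100).
#' @param seed master seed.
#' @param ... forwarded to [trap_koff_experiment()] for the base dataset.
#' @return List: `k_max` (per run, fastest phase only for one-site
#'   proteins), `relative_error` against the generating `k_off_O2` of site
#'   1, `fraction_within_5pct`.
#' @export
trap_recovery_study <- function(protein, n_runs = 100, seed = 1, ...) {
  cond <- assay_conditions("O2_dissociation_trap")
  base <- generate_assay_dataset(protein, cond, "dithionite_conc",
                                 c(6.75, 13.5, 27.5) * 1e-3,
                                 n_replicates = 3, seed = seed, ...)
  k_true <- protein$sites[[1]]$k_off_O2
  k_max <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    traces <- lapply(seq_along(base), function(i) {
      .renoise(base[[i]], derive_seed(seed, r * 1000L + i))
    })
    res <- trap_koff_experiment(protein, traces = traces)
    k_max[r] <- res$k_off[["phase1"]]
  }
  rel_err <- abs(k_max - k_true) / k_true
  list(k_max = k_max, relative_error = rel_err,
       fraction_within_5pct = mean(rel_err <= 0.05))
}

#' Gated NO-binding experiment
#'
#' Simulates stopped-flow NO binding over an NO titration, fits a single
#' exponential per trace, and classifies the concentration dependence of
#' the observed rates (gated binding is concentration independent because
#' the distal-His off-rate is limiting).
#'
#' @param protein a [protein_model()].
#' @param no_concs NO concentrations, M (default 10-160 uM doubling
#'   series).
#' @param n_replicates replicates per concentration.
#' @param seed master seed.
#' @return List: `kobs` table, `verdict` from [classify_dependence()],
#'   `mean_kobs`, `second_order` regression.
#' @export
no_binding_experiment <- function(protein,
                                  no_concs = c(10, 20, 40, 80, 160) * 1e-6,
                                  n_replicates = 1, seed = 1) {
  cond <- assay_conditions("NO_binding")
  traces <- generate_assay_dataset(protein, cond, "ligand_conc", no_concs,
                                   n_replicates, seed)
  kobs <- .kobs_table(traces, max_phases = 1)
  tab <- data.frame(conc = kobs$value, kobs = kobs$kobs)
  list(kobs = kobs, verdict = classify_dependence(tab),
       mean_kobs = mean(kobs$kobs), second_order = fit_second_order(tab))
}

#' Nitrite-reductase experiment
#'
#' Simulates the anaerobic NiR assay over a nitrite titration under excess
#' dithionite, fits the deoxyferrous decay per trace, and regresses the
#' observed rates on nitrite concentration to recover the apparent
#' bimolecular NiR constant (per heme).
#'
#' @param protein a [protein_model()].
#' @param nitrite_concs nitrite concentrations, M.
#' @param n_replicates replicates per concentration.
#' @param seed master seed.
#' @param pH assay pH (default 7).
#' @return List: `kobs` table, `second_order` (a [rate_determination()]),
#'   `k_nir_per_heme` (slope), `k_nir_per_molecule` (slope times number of
#'   sites), `verdict`.
#' @export
nir_experiment <- function(protein,
                           nitrite_concs = c(0.05, 0.1, 0.25, 0.5, 1) * 1e-3,
                           n_replicates = 1, seed = 1, pH = 7) {
  cond <- assay_conditions("NiR", dithionite_conc = 10e-3, pH = pH)
  traces <- generate_assay_dataset(protein, cond, "ligand_conc",
                                   nitrite_concs, n_replicates, seed)
  kobs <- .kobs_table(traces, max_phases = 1)
  tab <- data.frame(conc = kobs$value, kobs = kobs$kobs)
  so <- fit_second_order(tab)
  list(kobs = kobs, second_order = so,
       k_nir_per_heme = so$second_order_k,
       k_nir_per_molecule = so$second_order_k * length(protein$sites),
       verdict = classify_dependence(tab))
}

#' NO-dioxygenase censoring experiment
#'
#' Simulates the stopped-flow NOD reaction (oxyferrous + NO -> ferric) and
#' applies the dead-time censoring rule. The expected total amplitude is
#' computed from the initial and final species spectra of the noiseless
#' trajectory, as it would be from static spectra of the reactant and
#' product.
#'
#' @param protein a [protein_model()].
#' @param no_conc NO concentration, M (default 5 uM, the lowest assayed).
#' @param seed noise seed.
#' @param assay_kind `"NOD"` (default) or `"NO_binding"` (to test censoring
#'   of ungated, very fast NO binding by distal-His-null mutants).
#' @return The [rate_determination()] from [censored_bound()].
#' @export
nod_censoring_experiment <- function(protein, no_conc = 5e-6, seed = 1,
                                     assay_kind = c("NOD", "NO_binding")) {
  assay_kind <- match.arg(assay_kind)
  cond <- assay_conditions(assay_kind, ligand_conc = no_conc)
  instr <- default_instrument(assay_kind)
  wavelength <- default_wavelength(assay_kind)
  basis <- make_basis(names(species_catalogue()))
  scheme <- build_scheme(protein, cond)
  t_grid <- unique(c(0, seq(instr$dead_time, instr$duration,
                            by = instr$sampling_interval)))
  traj <- simulate_scheme(scheme, t_grid)
  tc <- apply_instrument(traj, basis, instr, wavelength,
                         seed = derive_seed(seed, 0L))
  A <- .project_absorbance(traj, basis, wavelength, instr$pathlength)
  expected_amplitude <- abs(A[1] - A[length(A)])
  censored_bound(tc, expected_amplitude)
}

#' pH dependence of the apparent nitrite-reduction rate
#'
#' Evaluates [nitrite_rate()] over a pH grid and regresses log10(k_app) on
#' pH; well above the nitrous-acid pKa the log-slope is -1 per pH unit.
#'
#' @param k_NiR_pH7 apparent constant at pH 7 (M^-1 s^-1).
#' @param pH_grid pH values (default 5 to 7 by 0.25).
#' @param pKa nitrous-acid pKa.
#' @return List: `pH`, `k_app` (M^-1 s^-1), `log_slope`.
#' @export
nir_ph_sweep <- function(k_NiR_pH7, pH_grid = seq(5, 7, by = 0.25),
                         pKa = 3.25) {
  k_app <- vapply(pH_grid, function(p) {
    nitrite_rate(k_NiR_pH7, pH = p, pKa = pKa, nitrite = 1)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(log10(k_app) ~ pH_grid))[2])
  list(pH = pH_grid, k_app = k_app, log_slope = slope)
}

#' Fit the slow (gate-limited) rate of a gated-binding simulation
#'
#' Helper for validating the closed-form gated rate against the full ODE
#' system: simulates the NO-binding scheme for a single gated site and
#' fits the decay of the unbound heme pool, returning the fitted dominant
#' slow rate.
#'
#' @param k_minus_H,k_H,k_prime_on,ligand gating parameters as in
#'   [hexacoordinate_kobs()].
#' @param protein_conc protein concentration, M; defaults to `ligand / 1000`
#'   so the ligand pool stays effectively constant (pseudo-first-order
#'   regime).
#' @return Fitted rate, s^-1.
#' @export
fitted_gated_rate <- function(k_minus_H, k_H, k_prime_on, ligand,
                              protein_conc = ligand / 1000) {
  site <- heme_site(has_distal_his = TRUE, k_minus_H = k_minus_H, k_H = k_H,
                    k_prime_on_NO = k_prime_on)
  prot <- protein_model("gated", list(site))
  cond <- assay_conditions("NO_binding", protein_conc = protein_conc,
                           ligand_conc = ligand)
  scheme <- build_scheme(prot, cond)
  k_pred <- hexacoordinate_kobs(k_minus_H, k_H, k_prime_on, ligand)
  t_end <- 7 / max(k_pred, 1e-12)
  t_grid <- seq(0, t_end, length.out = 400)
  traj <- simulate_scheme(scheme, t_grid)
  unbound <- traj$s1.deoxy5c + traj$s1.deoxy6c
  # drop the fast pre-equilibration transient (the initial pentacoordinate
  # fraction binds at the fast eigenvalue), then fit the dominant slow decay
  burn <- t_grid > 12 / (k_minus_H + k_H + k_prime_on * ligand)
  d <- data.frame(time = t_grid[burn], signal = unbound[burn])
  fit <- fit_multiexponential(d, max_phases = 1)
  fit$rates[1]
}
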