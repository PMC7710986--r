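#!/usr/bin/env Rscript
# Oxygen kinetics: fit the dithionite-trap datasets (biphasic for the
# two-heme protein, monophasic for the one-heme), extract the limiting
# k_off from hyperbolic saturation, verify the CO displacement behaviour,
# and derive the minimum O2 affinity constants.

suppressPackageStartupMessages(library(glbkin))

seed <- 20201119
dir.create("results", showWarnings = FALSE)

wt1 <- protein_model("WT1", glb_wt1()$sites, signal_weights = c(0.6, 0.4))
wt4 <- glb_wt4()

read_set <- function(label) {
  files <- list.files("results/datasets", pattern = paste0("^", label, "_[0-9]+\\.csv$"),
                      full.names = TRUE)
  stopifnot(length(files) > 0)
  lapply(files, read_timecourse)
}

message("== dithionite-trap O2 dissociation ==")
trap1 <- trap_koff_experiment(wt1, traces = read_set("wt1_trap"))
trap4 <- trap_koff_experiment(wt4, traces = read_set("wt4_trap"))
message(sprintf("WT1: %d phases; k_off = %.3f and %.3f /s",
                trap1$n_phases_mode, trap1$k_off[["phase1"]],
                trap1$k_off[["phase2"]]))
message(sprintf("WT4: %d phase;  k_off = %.3f /s",
                trap4$n_phases_mode, trap4$k_off[["phase1"]]))

message("== recovery study (100 noise realisations, one-heme) ==")
study <- trap_recovery_study(wt4, n_runs = 100, seed = derive_seed(seed, 9))
message(sprintf("median k_max %.4f /s; %.0f%% of runs within 5%%",
                median(study$k_max), 100 * study$fraction_within_5pct))

message("== CO displacement after flash photolysis ==")
# photolysed carboxy protein + 500 uM CO + 20 uM O2 (scavenger present):
# O2 is captured within microseconds, then displaced by CO at k_off(O2)
cond <- assay_conditions("CO_rebinding_LFP", CO_conc = 500e-6,
                         O2_conc = 20e-6, dithionite_conc = 1e-3)
tr <- simulate_scheme(build_scheme(wt4, cond),
                      unique(c(0, 10^seq(-6, -2, length.out = 30),
                               seq(0.02, 30, by = 0.02))))
slow <- tr$time > 0.1
disp <- fit_multiexponential(data.frame(tr$time[slow], tr$s1.carboxy[slow]),
                             max_phases = 2)
message(sprintf("slow oxy->carboxy phase: %.4f /s (k_off = 0.277 /s)",
                disp$rates[disp$n_phases]))

message("== minimum O2 affinity constants (k_on floor 5e8 /M/s) ==")
aff <- list(
  WT1_fast = affinity_constants(5e8, trap1$k_off[["phase1"]]),
  WT1_slow = affinity_constants(5e8, trap1$k_off[["phase2"]]),
  WT4 = affinity_constants(5e8, trap4$k_off[["phase1"]]))
for (nm in names(aff)) {
  message(sprintf("%s: K >= %.2g /M (Kd <= %.2g nM)", nm, aff[[nm]]$K_2sf,
                  aff[[nm]]$Kd_2sf * 1e9))
}

out <- list(
  k_off_per_s = list(WT1_fast = trap1$k_off[["phase1"]],
                     WT1_slow = trap1$k_off[["phase2"]],
                     WT4 = trap4$k_off[["phase1"]]),
  recovery = list(median_k_max_per_s = median(study$k_max),
                  fraction_within_5pct = study$fraction_within_5pct),
  displacement_rate_per_s = disp$rates[disp$n_phases],
  affinity = lapply(aff, function(a) list(K_min_per_M = a$K_2sf,
                                          Kd_max_nM = a$Kd_2sf * 1e9)))
jsonlite::write_json(out, "results/oxygen_kinetics.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/oxygen_kinetics.json")
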