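#!/usr/bin/env Rscript
# Generate the synthetic datasets for the downstream analyses: every assay
# for the two characterised proteins, written as annotated CSVs under
# results/datasets/. Deterministic for the seed below.

suppressPackageStartupMessages(library(glbkin))

seed <- 20201119
out_dir <- "results/datasets"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

wt1 <- protein_model("WT1", glb_wt1()$sites, signal_weights = c(0.6, 0.4))
wt4 <- glb_wt4()

write_set <- function(traces, label) {
  for (i in seq_along(traces)) {
    write_timecourse(traces[[i]],
                     file.path(out_dir, sprintf("%s_%03d.csv", label, i)))
  }
  message(sprintf("%-28s %3d traces", label, length(traces)))
}

# Dithionite-trap O2 dissociation: triplicates at 6.75 / 13.5 / 27.5 mM
for (p in list(wt1, wt4)) {
  traces <- generate_assay_dataset(
    p, assay_conditions("O2_dissociation_trap"), "dithionite_conc",
    c(6.75, 13.5, 27.5) * 1e-3, n_replicates = 3,
    seed = derive_seed(seed, 1))
  write_set(traces, paste0(tolower(p$name), "_trap"))
}

# Gated NO binding: 10-160 uM NO
for (p in list(wt1, wt4, strip_distal_his(wt1, name = "MUT"))) {
  traces <- generate_assay_dataset(
    p, assay_conditions("NO_binding"), "ligand_conc",
    c(10, 20, 40, 80, 160) * 1e-6, n_replicates = 1,
    seed = derive_seed(seed, 2))
  write_set(traces, paste0(tolower(p$name), "_no_binding"))
}

# Nitrite reduction under excess dithionite: 0.05-1 mM nitrite
for (p in list(wt1, wt4)) {
  traces <- generate_assay_dataset(
    p, assay_conditions("NiR", dithionite_conc = 1e-2), "ligand_conc",
    c(0.05, 0.1, 0.25, 0.5, 1) * 1e-3, n_replicates = 1,
    seed = derive_seed(seed, 3))
  write_set(traces, paste0(tolower(p$name), "_nir"))
}

# NOD at the lowest assayed NO concentration (5 uM): the reaction outruns
# the stopped-flow dead time, so this trace exists to exercise censoring
traces <- generate_assay_dataset(
  wt4, assay_conditions("NOD"), "ligand_conc", 5e-6,
  n_replicates = 1, seed = derive_seed(seed, 4))
write_set(traces, "wt4_nod")

# Time-resolved NiR spectra (50 uM nitrite, spectra every 1 s for 1 min)
basis <- make_basis(c("deoxy_6cLS", "deoxy_5cHS", "ferric_6cLS",
                      "ferrous_NO"))
traj <- simulate_scheme(
  build_scheme(wt4, assay_conditions("NiR", ligand_conc = 5e-5,
                                     dithionite_conc = 1e-2)),
  unique(c(0, seq(0, 60, by = 1))))
ser <- generate_spectrum_series(
  traj, basis,
  instrument_profile("scanning_spectrophotometer", duration = 60),
  seed = derive_seed(seed, 5))
write_spectrum_series(ser, file.path(out_dir, "wt4_nir_spectra.csv"))
message("wt4_nir_spectra.csv           1 series (451 x 61)")
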