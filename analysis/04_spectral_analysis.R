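#!/usr/bin/env Rscript
# Spectral analysis: second-derivative deconvolution of the deoxyferrous
# Soret region (hexa- vs pentacoordinate bands) and non-negative unmixing
# of the time-resolved nitrite-reduction series generated in step 01.

suppressPackageStartupMessages(library(glbkin))

dir.create("results", showWarnings = FALSE)

message("== D2 deconvolution of a 6cLS/5cHS Soret overlap ==")
cat_mod <- species_catalogue()
cat_mod$deoxy_6cLS$bands[1, "fwhm_nm"] <- 12
cat_mod$deoxy_5cHS$bands[1, "fwhm_nm"] <- 12
b <- make_basis(c("deoxy_6cLS", "deoxy_5cHS"), catalogue = cat_mod)
mix <- 0.6 * b$deoxy_6cLS$extinction + 0.4 * b$deoxy_5cHS$extinction
sp <- spectrum(250:700, mix * 2.5e-6)
d2 <- second_derivative(sp, window_points = 15)
mins <- d2_minima(d2)
soret_mins <- mins[mins > 400 & mins < 460]
message(sprintf("raw Soret maximum: %d nm (single band)",
                sp$wavelengths[which.max(sp$absorbance)]))
message(sprintf("D2 minima: %s nm (two bands resolved)",
                paste(soret_mins, collapse = " and ")))

message("== unmixing the time-resolved NiR series ==")
ser <- read_spectrum_series("results/datasets/wt4_nir_spectra.csv")
basis <- make_basis(c("deoxy_6cLS", "deoxy_5cHS", "ferric_6cLS",
                      "ferrous_NO"))
um <- unmix_series(ser, basis)
conc <- um$concentrations
deoxy <- conc[, "deoxy_6cLS"] + conc[, "deoxy_5cHS"]
fit <- fit_multiexponential(data.frame(ser$times, deoxy), max_phases = 1)
message(sprintf("deoxyferrous decay from unmixed spectra: %.4f /s",
                fit$rates[1]))
message(sprintf("(generating pseudo-first-order rate: %.4f /s)", 382 * 5e-5))
tot <- rowSums(conc)
message(sprintf("total heme drift over the series: %.2f%%",
                100 * max(abs(tot - tot[1])) / tot[1]))

df <- data.frame(time_s = um$times, conc * 1e6)
names(df)[-1] <- paste0(colnames(conc), "_uM")
write.csv(df, "results/nir_unmixed_concentrations.csv", row.names = FALSE)
jsonlite::write_json(
  list(d2_minima_nm = soret_mins,
       deoxy_decay_per_s = fit$rates[1],
       generating_rate_per_s = 382 * 5e-5,
       max_total_heme_drift_fraction = max(abs(tot - tot[1])) / tot[1]),
  "results/spectral_analysis.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote results/spectral_analysis.json and nir_unmixed_concentrations.csv")
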