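# Instrument-realistic trace generation: dead time, resampling, noise,
# seeding, replication.

basis_all <- make_basis(names(species_catalogue()))

test_that("instrument profiles carry the documented defaults", {
  sf <- instrument_profile("stopped_flow")
  expect_equal(sf$dead_time, 1.2e-3)
  expect_equal(sf$sampling_interval, 1.2e-3)
  lfp <- instrument_profile("lfp")
  expect_equal(lfp$dead_time, 5e-6)
  expect_error(instrument_profile("stopped_flow", sampling_interval = 0),
               "sampling_interval")
})

test_that("apply_instrument reproduces the projection when idealised", {
  p <- toy_gated_protein()
  cond <- assay_conditions("NO_binding", ligand_conc = 2e-5)
  instr <- instrument_profile("stopped_flow", dead_time = 0,
                              duration = 0.12, sampling_interval = 1.2e-3,
                              noise_sd = 0)
  tg <- unique(c(0, seq(0, 0.12, by = 1.2e-3)))
  traj <- simulate_scheme(build_scheme(p, cond), tg)
  tc <- apply_instrument(traj, basis_all, instr, 424, seed = 1)
  # signal equals the Beer-Lambert projection on the grid, and starts at 0
  expect_equal(tc$times[1], 0)
  expect_equal(tc$signal, tc$truth$noiseless)
  A0 <- tc$signal[1]
  expect_gt(A0, 0.2)  # deoxy Soret flank at 2.5 uM, 1 cm
})

test_that("dead time censors the early signal", {
  # a 5000/s reaction retains < 1% of its amplitude at the 1.2 ms dead time
  expect_lt(exp(-5000 * 1.2e-3), 0.01)
  p <- protein_model("fast5c", list(
    heme_site(has_distal_his = FALSE, k_prime_on_NO = 5000 / 2e-5)))
  cond <- assay_conditions("NO_binding", ligand_conc = 2e-5)
  instr <- instrument_profile("stopped_flow", duration = 0.06, noise_sd = 0)
  tg <- unique(c(0, 1e-5, seq(1.2e-3, 0.06, by = 1.2e-3)))
  traj <- simulate_scheme(build_scheme(p, cond), tg)
  tc <- apply_instrument(traj, basis_all, instr, 424, seed = 1)
  expect_gte(tc$times[1], 1.2e-3)
  A_full <- glbkin:::.project_absorbance(traj, basis_all, 424, 1)
  amp_total <- abs(A_full[1] - A_full[length(A_full)])
  amp_seen <- abs(tc$signal[1] - tc$signal[length(tc$signal)])
  expect_lt(amp_seen / amp_total, 0.02)
})

test_that("noise is reproducible, realistic and seed-derived", {
  p <- toy_gated_protein()
  cond <- assay_conditions("NO_binding", ligand_conc = 2e-5)
  instr <- instrument_profile("stopped_flow", duration = 0.5)
  tg <- unique(c(0, seq(1.2e-3, 0.5, by = 1.2e-3)))
  traj <- simulate_scheme(build_scheme(p, cond), tg)
  tc1 <- apply_instrument(traj, basis_all, instr, 424, seed = 77)
  tc2 <- apply_instrument(traj, basis_all, instr, 424, seed = 77)
  tc3 <- apply_instrument(traj, basis_all, instr, 424, seed = 78)
  expect_identical(tc1$signal, tc2$signal)
  expect_false(identical(tc1$signal, tc3$signal))
  # empirical residual SD within 10% of the nominal noise for >= 200 points
  resid <- tc1$signal - tc1$truth$noiseless
  expect_gt(length(resid), 200)
  expect_equal(sd(resid), 0.002, tolerance = 0.1)
})

test_that("seed derivation is deterministic, spread out, and in range", {
  s1 <- vapply(0:199, function(i) derive_seed(1, i), integer(1))
  s2 <- vapply(0:199, function(i) derive_seed(1, i), integer(1))
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 200)
  expect_true(all(s1 > 0 & s1 < 2^31 - 1))
  expect_false(any(s1 %in% vapply(0:199, function(i) derive_seed(2, i),
                                  integer(1))))
})

test_that("generate_assay_dataset builds the titration x replicate grid", {
  p <- glb_wt4()
  cond <- assay_conditions("O2_dissociation_trap")
  instr <- instrument_profile("stopped_flow", sampling_interval = 0.1,
                              duration = 20)
  d <- generate_assay_dataset(p, cond, "dithionite_conc",
                              c(6.75, 13.5, 27.5) * 1e-3,
                              n_replicates = 3, seed = 5, instr = instr)
  expect_length(d, 9)
  vals <- vapply(d, function(tc) tc$truth$value, numeric(1))
  expect_equal(as.integer(table(vals)), rep(3L, 3))
  # deterministic regeneration
  d2 <- generate_assay_dataset(p, cond, "dithionite_conc",
                               c(6.75, 13.5, 27.5) * 1e-3,
                               n_replicates = 3, seed = 5, instr = instr)
  expect_identical(lapply(d, `[[`, "signal"), lapply(d2, `[[`, "signal"))
  # single value, single replicate
  d1 <- generate_assay_dataset(p, cond, "dithionite_conc", 1e-2,
                               n_replicates = 1, seed = 5, instr = instr)
  expect_length(d1, 1)
  expect_error(generate_assay_dataset(p, cond, "dithionite_conc",
                                      numeric(0)),
               "empty value list")
  expect_error(generate_assay_dataset(p, cond, "not_a_field", 1),
               "not an assay_conditions field")
})

test_that("gated NO series is flat across the NO titration", {
  res <- no_binding_experiment(glb_wt1(), seed = 11)
  spread <- diff(range(res$kobs$kobs)) / mean(res$kobs$kobs)
  expect_lt(spread, 0.03)
})

test_that("spectral series round-trips through unmixing", {
  p <- glb_wt4()
  cond <- assay_conditions("NiR", ligand_conc = 5e-5, dithionite_conc = 1e-2)
  tg <- unique(c(0, seq(0, 60, by = 1)))
  traj <- simulate_scheme(build_scheme(p, cond), tg)
  basis <- make_basis(c("deoxy_6cLS", "deoxy_5cHS", "ferric_6cLS",
                        "ferrous_NO"))
  instr <- instrument_profile("scanning_spectrophotometer", duration = 60,
                              noise_sd = 0)
  ser <- generate_spectrum_series(traj, basis, instr, seed = 1)
  expect_s3_class(ser, "spectrum_series")
  expect_equal(dim(ser$absorbance), c(451, 61))
  # deoxy Soret decays over the series
  a423 <- ser$absorbance[ser$wavelengths == 423, ]
  expect_lt(a423[61], 0.75 * a423[1])
  # noiseless unmixing returns the generating trajectory to ~ machine level
  um <- unmix_series(ser, basis)
  truth <- attr(ser, "truth")$concentrations
  err <- max(abs(um$concentrations - truth[, colnames(um$concentrations)]))
  expect_lt(err / 2.5e-6, 1e-10)
  # zero-duration series: a single spectrum
  instr1 <- instrument_profile("scanning_spectrophotometer", duration = 1e-9,
                               noise_sd = 0)
  ser1 <- generate_spectrum_series(traj, basis, instr1, seed = 1)
  expect_length(ser1$times, 1)
})
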