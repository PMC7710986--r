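# The fitting chain: exponential decomposition, saturation and second-order
# fits, dependence classification, censoring, reference comparisons.

test_that("phase-count selection finds the generating model", {
  t <- seq(0, 30, by = 0.02)
  # constant trace -> 0 phases
  f0 <- fit_multiexponential(data.frame(t, rep(0.3, length(t))))
  expect_equal(f0$n_phases, 0L)
  # noiseless biphasic at the 0.319 / 0.190 pair: exact recovery
  y2 <- 0.1 + 0.43 * exp(-0.319 * t) + 0.29 * exp(-0.190 * t)
  f2 <- fit_multiexponential(data.frame(t, y2))
  expect_equal(f2$n_phases, 2L)
  expect_equal(f2$rates, c(0.319, 0.190), tolerance = 1e-6)
  expect_equal(f2$amplitudes, c(0.43, 0.29), tolerance = 1e-6)
  expect_equal(f2$baseline, 0.1, tolerance = 1e-8)
  # scale invariance: a 1e-7-amplitude trace fits identically
  f2s <- fit_multiexponential(data.frame(t, (y2 - 0.1) * 1e-6))
  expect_equal(f2s$rates, c(0.319, 0.190), tolerance = 1e-6)
  expect_error(fit_multiexponential(data.frame(t = 1:5, y = 1:5)),
               "at least 10 points")
})

test_that("noisy single-exponential rates are recovered and selected", {
  t <- seq(0, 30, by = 0.02)
  y0 <- 0.05 + 0.36 * exp(-0.277 * t)
  n_sel <- integer(0)
  errs <- numeric(0)
  for (s in 1:25) {
    tc <- timecourse(t, y0 + glbkin:::.with_seed(s, rnorm(length(t), 0, 0.002)),
                     instrument_profile("stopped_flow", dead_time = 0,
                                        sampling_interval = 0.02,
                                        duration = 30), 423)
    f <- fit_multiexponential(tc)
    n_sel <- c(n_sel, f$n_phases)
    errs <- c(errs, abs(f$rates[1] - 0.277) / 0.277)
  }
  expect_gte(mean(n_sel == 1L), 0.95)
  expect_lt(median(errs), 0.01)
  expect_lt(max(errs), 0.03)
})

test_that("identifiability guards demote marginal phases", {
  t <- seq(0, 30, by = 0.02)
  # rates closer than 1.5-fold collapse to one phase
  y <- 0.3 * exp(-0.30 * t) + 0.3 * exp(-0.25 * t)
  f <- fit_multiexponential(data.frame(t, y))
  expect_equal(f$n_phases, 1L)
  # a < 5% amplitude share is absorbed
  y2 <- 0.02 * exp(-3 * t) + 0.6 * exp(-0.2 * t)
  f2 <- fit_multiexponential(data.frame(t, y2))
  expect_equal(f2$n_phases, 1L)
})

test_that("hyperbolic saturation fit recovers its parameters", {
  # exact hyperbola: recovered to 1e-8
  conc <- c(1, 2, 5, 10, 20) * 1e-3
  kobs <- 1.0 * conc / (5e-3 + conc)
  fit <- fit_trap_saturation(data.frame(conc, kobs))
  expect_equal(fit$k_max, 1.0, tolerance = 1e-8)
  expect_equal(fit$c_half, 5e-3, tolerance = 1e-8)
  expect_false(fit$extrapolated)
  # constant k_obs: saturated limit, k_max = value, c_half -> 0
  fit2 <- fit_trap_saturation(data.frame(conc = conc[1:3],
                                         kobs = rep(0.27, 3)))
  expect_equal(fit2$k_max, 0.27)
  expect_equal(fit2$c_half, 0)
  expect_error(fit_trap_saturation(data.frame(conc = c(1, 1, 1),
                                              kobs = c(1, 2, 3))),
               "distinct")
  # c_half beyond the titration range is flagged as extrapolation
  expect_warning(
    fit3 <- fit_trap_saturation(data.frame(conc = c(1, 2, 4) * 1e-3,
                                           kobs = 1 * c(1, 2, 4) /
                                             c(11, 12, 14))),
    "extrapolation")
  expect_true(fit3$extrapolated)
})

test_that("end-to-end trap pipeline recovers k_off for one heme", {
  res <- trap_koff_experiment(glb_wt4(), seed = 101)
  expect_equal(res$n_phases_mode, 1L)
  expect_equal(res$k_off[["phase1"]], 0.277, tolerance = 0.05)
})

test_that("second-order regression matches exact and noisy lines", {
  conc <- c(0.05, 0.1, 0.25, 0.5, 1) * 1e-3
  so <- fit_second_order(data.frame(conc, kobs = 726 * conc))
  expect_equal(so$second_order_k, 726, tolerance = 1e-12)
  expect_equal(so$intercept, 0, tolerance = 1e-10)
  expect_false(so$censored)
  # flat data: slope 0; verdict belongs to classify_dependence
  so0 <- fit_second_order(data.frame(conc, kobs = rep(126, 5)))
  expect_equal(so0$second_order_k, 0, tolerance = 1e-10)
  expect_equal(classify_dependence(data.frame(conc, kobs = rep(126, 5))),
               "gated_independent")
  expect_error(fit_second_order(data.frame(conc = rep(1e-3, 3),
                                           kobs = 1:3)),
               "degenerate|distinct")
})

test_that("dependence classification separates gated from bimolecular", {
  # gated simulation over 10-160 uM NO: concentration independent
  res <- no_binding_experiment(glb_wt1(), seed = 31)
  expect_equal(res$verdict, "gated_independent")
  expect_equal(res$mean_kobs, 126, tolerance = 0.02)
  # NiR titration: bimolecular
  nir <- nir_experiment(glb_wt4(), seed = 31)
  expect_equal(nir$verdict, "bimolecular_dependent")
  # two concentrations only / narrow span: indeterminate
  expect_equal(classify_dependence(data.frame(conc = c(1, 2) * 1e-6,
                                              kobs = c(1, 2))),
               "indeterminate")
  expect_equal(classify_dependence(data.frame(conc = c(1, 1.5, 2) * 1e-6,
                                              kobs = c(1, 1.2, 1.3))),
               "indeterminate")
})

test_that("censoring flags dead-time-limited traces and only those", {
  # fast NOD reaction at 5 uM NO: censored with lower bound ln2 / 3 ms
  cen <- nod_censoring_experiment(glb_wt4(), no_conc = 5e-6, seed = 13)
  expect_true(cen$censored)
  expect_equal(cen$lower_bound, log(2) / (2.5 * 1.2e-3), tolerance = 1e-10)
  expect_null(cen$second_order_k)
  # distal-His-null mutant NO binding at 20 uM: censored
  mut <- nod_censoring_experiment(strip_distal_his(glb_wt4()),
                                  no_conc = 2e-5, seed = 13,
                                  assay_kind = "NO_binding")
  expect_true(mut$censored)
  expect_gt(mut$details$missing_amplitude_fraction, 0.95)
  # slow trace: not censored
  slow <- nod_censoring_experiment(glb_wt4(), no_conc = 2e-5, seed = 13,
                                   assay_kind = "NO_binding")
  expect_false(slow$censored)
  expect_equal(slow$details$k_obs, 114, tolerance = 0.03)
  # the container itself forbids censored + finite second-order constant
  expect_error(rate_determination(second_order_k = 1, censored = TRUE,
                                  lower_bound = 231),
               "cannot carry")
  expect_error(rate_determination(censored = TRUE), "lower bound")
})

test_that("reference comparisons report fold changes", {
  folds <- compare_to_references(382)
  expect_equal(unname(folds["sperm_whale_Mb"]), signif(382 / 2.9, 3))
  expect_equal(unname(compare_to_references(726)["human_neuroglobin"]),
               signif(726 / 0.25, 3))
  expect_equal(unname(compare_to_references(68)["SynHb"]), 1)
  expect_error(compare_to_references(-1), "k > 0")
  refs <- reference_nir_constants()
  expect_equal(unname(refs[c("SynHb", "sperm_whale_Mb",
                             "human_neuroglobin")]),
               c(68, 2.9, 0.25))
})
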