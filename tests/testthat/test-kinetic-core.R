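# Reaction schemes, ODE integration and closed-form kinetics.

test_that("domain constructors validate their invariants", {
  expect_error(heme_site(k_minus_H = -1), "must be >= 0")
  expect_error(protein_model("x", list()), "1 or 2 heme sites")
  expect_error(assay_conditions("NO_binding", pH = 2), "pH")
  expect_error(assay_conditions("NO_binding", protein_conc = -1),
               "concentrations")
  expect_error(assay_conditions("frobnicate"), "arg")
  p <- glb_wt1()
  expect_length(p$sites, 2)
  expect_false(p$heme_equivalent)
  expect_equal(sum(p$signal_weights), 1)
})

test_that("build_scheme assembles the expected assay chemistry", {
  # one-site gated NO binding: 3 heme species, gating + capture
  sch <- build_scheme(toy_gated_protein(),
                      assay_conditions("NO_binding", ligand_conc = 1e-5))
  heme_sp <- grep("^s1\\.", sch$species, value = TRUE)
  expect_setequal(heme_sp, c("s1.deoxy6c", "s1.deoxy5c", "s1.ferrous_no"))
  expect_length(sch$rates, 3)

  # two-site trap: two independent chains, shared O2 pool, one trap step
  sch2 <- build_scheme(glb_wt1(),
                       assay_conditions("O2_dissociation_trap",
                                        dithionite_conc = 1e-2))
  expect_true(all(c("s1.oxy", "s2.oxy", "O2", "DT") %in% sch2$species))
  expect_length(grep("O2_trap", sch2$reaction_names), 1)
  expect_length(sch2$site_species, 2)

  # missing parameter is a configuration error naming the parameter
  bare <- protein_model("bare", list(heme_site(has_distal_his = FALSE)))
  expect_error(build_scheme(bare, assay_conditions("O2_dissociation_trap")),
               "k_off_O2")
})

test_that("stoichiometry validation rejects malformed reactions", {
  expect_error(
    reaction_scheme("A", list(list(reactants = c(A = -1), products = c(A = 1),
                                   rate = 1)), c(A = 1)),
    "non-negative integers")
  expect_error(
    reaction_scheme("A", list(list(reactants = c(B = 1), products = c(),
                                   rate = 1)), c(A = 1)),
    "known species")
})

test_that("simulation matches closed forms and conserves heme", {
  # no reactions: constant trajectories
  sch <- reaction_scheme(c("A", "B"), list(), c(A = 1e-6, B = 2e-6))
  tr <- simulate_scheme(sch, seq(0, 1, by = 0.1))
  expect_equal(tr$A, rep(1e-6, 11))
  expect_equal(tr$B, rep(2e-6, 11))

  # irreversible A -> B: exact exponential (unit amplitude so the relative
  # tolerance, not the absolute molar floor, governs the comparison)
  k <- 3.7
  sch <- reaction_scheme(c("A", "B"),
                         list(list(reactants = c(A = 1), products = c(B = 1),
                                   rate = k)),
                         c(A = 1))
  tg <- seq(0, 2, by = 0.05)
  tr <- simulate_scheme(sch, tg)
  expect_lt(max(abs(tr$A - exp(-k * tg))), 1e-8)

  # NiR assay at 50 uM nitrite: deoxy pool decays near k_NiR * [NO2-]
  site <- heme_site(TRUE, k_minus_H = 126, k_H = 500, k_prime_on_NO = 5e9,
                    k_NiR_pH7 = 726)
  p1 <- protein_model("one", list(site))
  cond <- assay_conditions("NiR", ligand_conc = 5e-5,
                           dithionite_conc = 1e-2)
  tr <- simulate_scheme(build_scheme(p1, cond), seq(0, 200, by = 0.5))
  deoxy <- tr$s1.deoxy5c + tr$s1.deoxy6c
  fit <- fit_multiexponential(data.frame(tr$time, deoxy), max_phases = 1)
  expect_equal(fit$rates[1], 726 * 5e-5, tolerance = 0.05)

  # per-site heme conservation in every assay
  for (kind in assay_kinds()) {
    cond <- assay_conditions(kind, ligand_conc = 2e-5,
                             dithionite_conc = 1e-2, CO_conc = 5e-4,
                             O2_conc = 2e-5)
    tr <- simulate_scheme(build_scheme(glb_wt1(), cond),
                          seq(0, 2, length.out = 101))
    expect_lt(max(heme_conservation_error(tr)), 1e-8)
    expect_gt(min(as.matrix(tr[, -1])), -1e-10)
  }
})

test_that("t_grid and initial-state contracts are enforced", {
  sch <- reaction_scheme("A", list(), c(A = 1))
  expect_error(simulate_scheme(sch, c(1, 2)), "start at 0")
  expect_error(simulate_scheme(sch, c(0, 1, 1)), "strictly increasing")
  expect_error(simulate_scheme(sch, c(0, 1), init = c(A = -1)),
               "non-negative")
})

test_that("gated k_obs closed form behaves as specified", {
  expect_equal(hexacoordinate_kobs(126, 1000, 1e8, 0), 0)
  expect_equal(hexacoordinate_kobs(126, 0, 1e8, 1e-6), 126)
  expect_equal(hexacoordinate_kobs(0, 0, 0, 0), 0)
  # worked value: 126/s gate, 1000/s re-association, 16000/s capture flux
  expect_equal(hexacoordinate_kobs(126, 1000, 1e8, 160e-6),
               126 * 16000 / 17000, tolerance = 1e-12)
  # monotone non-decreasing in ligand, bounded by k_minus_H
  L <- 10^seq(-7, -2, length.out = 30)
  ko <- hexacoordinate_kobs(126, 1000, 1e8, L)
  expect_true(all(diff(ko) >= 0))
  expect_true(all(ko <= 126))
})

test_that("closed-form gated rate matches the full ODE within 1%", {
  # worked case, plus a (k_H, k'L) grid spanning > 4 decades in the
  # gate-saturating regime; the exact slow eigenvalue is a second,
  # independent oracle
  cf <- hexacoordinate_kobs(126, 1000, 1e8, 160e-6)
  expect_equal(cf, 118.6, tolerance = 1e-3)
  fit <- fitted_gated_rate(126, 1000, 1e8, 160e-6)
  expect_equal(fit, cf, tolerance = 0.01)
  expect_equal(fit, gated_slow_eigenvalue(126, 1000, 1e8, 160e-6),
               tolerance = 0.01)
  for (kH in 10^c(1, 3)) {
    for (kL in c(2e3, 2e5, 2e7)) {
      cf <- hexacoordinate_kobs(10, kH, 1e8, kL / 1e8)
      fit <- fitted_gated_rate(10, kH, 1e8, kL / 1e8)
      expect_equal(fit, cf, tolerance = 0.01)
    }
  }
})

test_that("gating saturates: capture flux >= 100x k_H pins k_obs at k_-H", {
  for (kL in c(100 * 500, 1000 * 500)) {
    fit <- fitted_gated_rate(126, 500, 1e8, kL / 1e8)
    expect_gte(fit, 0.985 * 126)
    expect_lte(fit, 1.001 * 126)
  }
})

test_that("trap k_obs rises with dithionite and converges to k_off", {
  instr <- noiseless(default_instrument("O2_dissociation_trap"))
  concs <- c(0.2, 1, 5, 27.5) * 1e-3
  traces <- generate_assay_dataset(glb_wt4(),
                                   assay_conditions("O2_dissociation_trap"),
                                   "dithionite_conc", concs,
                                   n_replicates = 1, seed = 1, instr = instr)
  kobs <- vapply(traces, function(tc) {
    fit_multiexponential(tc, max_phases = 1)$rates[1]
  }, numeric(1))
  expect_true(all(diff(kobs) > 0))
  expect_true(all(kobs < 0.277))
  expect_equal(kobs[length(kobs)], 0.277, tolerance = 0.01)
})

test_that("CO displacement proceeds at the O2 dissociation rate", {
  # photolysed carboxy + O2: O2 capture wins the fast phase, then CO
  # displaces O2 at k_off(O2) once the liberated O2 is scavenged
  cond <- assay_conditions("CO_rebinding_LFP", CO_conc = 500e-6,
                           O2_conc = 20e-6, dithionite_conc = 1e-3)
  tr <- simulate_scheme(build_scheme(glb_wt4(), cond),
                        unique(c(0, 10^seq(-6, -2, length.out = 30),
                                 seq(0.02, 30, by = 0.02))))
  expect_gt(max(tr$s1.oxy) / 2.5e-6, 0.9)  # transient oxy population
  slow <- tr$time > 0.1
  fit <- fit_multiexponential(data.frame(tr$time[slow], tr$s1.carboxy[slow]),
                              max_phases = 2)
  expect_equal(fit$rates[fit$n_phases], 0.277, tolerance = 0.05)
})

test_that("NiR needs the reductant to reach the nitrosyl end state", {
  p <- glb_wt4()
  with_red <- simulate_scheme(
    build_scheme(p, assay_conditions("NiR", ligand_conc = 5e-5,
                                     dithionite_conc = 1e-2)),
    seq(0, 200, by = 2))
  no_red <- simulate_scheme(
    build_scheme(p, assay_conditions("NiR", ligand_conc = 5e-5,
                                     dithionite_conc = 0)),
    seq(0, 200, by = 2))
  last <- nrow(with_red)
  expect_gt(with_red$s1.ferrous_no[last], 0.9 * 2.5e-6)
  expect_lt(with_red$s1.ferric[last], 0.01 * 2.5e-6)
  expect_gt(no_red$s1.ferric[last], 0.4 * 2.5e-6)
})

test_that("nitrous-acid pH scaling is exact at its anchors and log-linear", {
  expect_equal(nitrite_rate(726, pH = 7, nitrite = 1e-3), 0.726)
  # f(pKa) = 0.5 by definition
  f <- function(p, pKa = 3.25) 1 / (1 + 10^(p - pKa))
  expect_equal(f(3.25), 0.5)
  # k_app(6) / k_app(7) = (1 + 10^3.75) / (1 + 10^2.75)
  r <- nitrite_rate(726, pH = 6, nitrite = 1) /
    nitrite_rate(726, pH = 7, nitrite = 1)
  expect_equal(r, (1 + 10^3.75) / (1 + 10^2.75), tolerance = 1e-12)
  expect_equal(r, 9.98, tolerance = 1e-3)
  # strictly decreasing in pH; log-slope -1 on pH 5-7
  ks <- vapply(seq(5, 7, 0.25), function(p) nitrite_rate(726, p, nitrite = 1),
               numeric(1))
  expect_true(all(diff(ks) < 0))
  sweep <- nir_ph_sweep(726)
  expect_equal(sweep$log_slope, -1, tolerance = 0.02)
})

test_that("affinity constants follow K = k_on / k_off", {
  a <- affinity_constants(5e8, 0.319)
  expect_equal(a$K_2sf, 1.6e9)
  expect_equal(a$Kd, 1 / a$K)
  expect_equal(affinity_constants(5e8, 0.277)$Kd * 1e9, 0.554,
               tolerance = 1e-3)
  expect_equal(affinity_constants(3, 3)$K, 1)
  expect_error(affinity_constants(0, 1), "positive")
  expect_error(affinity_constants(1, -2), "positive")
  # monotone decreasing in k_off
  Ks <- vapply(c(0.1, 0.2, 0.4), function(koff) {
    affinity_constants(5e8, koff)$K
  }, numeric(1))
  expect_true(all(diff(Ks) < 0))
})
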