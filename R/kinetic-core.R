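# Domain objects and closed-form kinetics for hexacoordinate globins.
#
# Rates are in s^-1 (first order) or M^-1 s^-1 (second order); concentrations
# in molar; times in seconds throughout the package.

#' Describe one heme site of a globin
#'
#' A heme site carries the per-site rate constants used to assemble assay
#' reaction schemes. Hexacoordinate sites carry an endogenous distal-histidine
#' (His_d) on/off equilibrium that gates exogenous ligand binding; sites
#' without a distal His are permanently pentacoordinate and the gating
#' constants are ignored.
#'
#' @param has_distal_his logical; does the site carry a distal histidine?
#' @param k_minus_H His_d dissociation rate constant (s^-1). This is the
#'   ceiling for gated exogenous ligand binding.
#' @param k_H His_d re-association rate constant (s^-1).
#' @param k_prime_on_NO intrinsic NO association to the pentacoordinate iron
#'   (M^-1 s^-1).
#' @param k_on_O2 O2 association to the pentacoordinate iron (M^-1 s^-1).
#' @param k_off_O2 O2 dissociation rate constant (s^-1).
#' @param k_on_CO apparent CO association rate constant (M^-1 s^-1).
#' @param k_NOD NO dioxygenase rate constant: oxyferrous + NO -> ferric +
#'   nitrate (M^-1 s^-1).
#' @param k_NiR_pH7 apparent nitrite reduction rate constant at pH 7, per heme
#'   (M^-1 s^-1).
#' @return An object of class `heme_site`.
#' @export
heme_site <- function(has_distal_his = TRUE,
                      k_minus_H = NA_real_,
                      k_H = 500,
                      k_prime_on_NO = 5e9,
                      k_on_O2 = 1e9,
                      k_off_O2 = NA_real_,
                      k_on_CO = NA_real_,
                      k_NOD = 7e7,
                      k_NiR_pH7 = NA_real_) {
  stopifnot(is.logical(has_distal_his), length(has_distal_his) == 1L)
  site <- list(has_distal_his = has_distal_his,
               k_minus_H = k_minus_H, k_H = k_H,
               k_prime_on_NO = k_prime_on_NO,
               k_on_O2 = k_on_O2, k_off_O2 = k_off_O2,
               k_on_CO = k_on_CO, k_NOD = k_NOD,
               k_NiR_pH7 = k_NiR_pH7)
  for (nm in setdiff(names(site), "has_distal_his")) {
    v <- site[[nm]]
    if (!is.na(v) && v < 0) {
      stop("heme_site: rate constant '", nm, "' must be >= 0", call. = FALSE)
    }
  }
  structure(site, class = "heme_site")
}

#' Define a globin with one or two heme sites
#'
#' @param name protein label.
#' @param sites list of one or two [heme_site()] objects, ordered.
#' @param signal_weights relative contribution of each site to the optical
#'   signal; normalised to sum to 1. Defaults to equal weights.
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(name, sites, signal_weights = NULL) {
  if (inherits(sites, "heme_site")) sites <- list(sites)
  n <- length(sites)
  if (n < 1L || n > 2L) {
    stop("protein_model: a globin must have 1 or 2 heme sites", call. = FALSE)
  }
  if (!all(vapply(sites, inherits, logical(1), "heme_site"))) {
    stop("protein_model: 'sites' must be heme_site objects", call. = FALSE)
  }
  if (is.null(signal_weights)) signal_weights <- rep(1 / n, n)
  stopifnot(length(signal_weights) == n, all(signal_weights >= 0))
  signal_weights <- signal_weights / sum(signal_weights)
  heme_equivalent <- n == 1L || isTRUE(all.equal(sites[[1]], sites[[2]]))
  structure(list(name = name, sites = sites,
                 signal_weights = signal_weights,
                 heme_equivalent = heme_equivalent),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat("<protein_model> ", x$name, ": ", length(x$sites), " heme site(s)",
      if (x$heme_equivalent && length(x$sites) == 2L) " (equivalent)" else "",
      "\n", sep = "")
  for (i in seq_along(x$sites)) {
    s <- x$sites[[i]]
    cat(sprintf("  site %d: %s, k_off_O2=%s/s, k_on_CO=%s/M/s, k_NiR(pH7)=%s/M/s\n",
                i,
                if (s$has_distal_his)
                  sprintf("gated (k_-H=%g/s, k_H=%g/s)", s$k_minus_H, s$k_H)
                else "pentacoordinate",
                format(s$k_off_O2), format(s$k_on_CO), format(s$k_NiR_pH7)))
  }
  invisible(x)
}

#' Assay conditions for a kinetic experiment
#'
#' @param assay_kind one of `"O2_dissociation_trap"`, `"CO_rebinding_LFP"`,
#'   `"NO_binding"`, `"NOD"`, `"NiR"`.
#' @param protein_conc protein (per molecule) concentration, M.
#' @param ligand_conc concentration of the varied ligand (NO for the
#'   NO-binding and NOD assays, nitrite for the NiR assay), M.
#' @param dithionite_conc sodium dithionite concentration, M.
#' @param CO_conc,O2_conc dissolved CO and O2, M.
#' @param pH assay pH (must lie in \[3, 10\]).
#' @param temperature nominal temperature, degrees C (metadata only).
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(assay_kind,
                             protein_conc = 2.5e-6,
                             ligand_conc = 0,
                             dithionite_conc = 0,
                             CO_conc = 0,
                             O2_conc = 0,
                             pH = 7,
                             temperature = 25) {
  assay_kind <- match.arg(assay_kind, assay_kinds())
  conc <- c(protein_conc = protein_conc, ligand_conc = ligand_conc,
            dithionite_conc = dithionite_conc, CO_conc = CO_conc,
            O2_conc = O2_conc)
  if (any(conc < 0)) stop("assay_conditions: concentrations must be >= 0",
                          call. = FALSE)
  if (pH < 3 || pH > 10) stop("assay_conditions: pH must be in [3, 10]",
                              call. = FALSE)
  structure(list(assay_kind = assay_kind, protein_conc = protein_conc,
                 ligand_conc = ligand_conc,
                 dithionite_conc = dithionite_conc, CO_conc = CO_conc,
                 O2_conc = O2_conc, pH = pH, temperature = temperature),
            class = "assay_conditions")
}

#' Supported assay kinds
#' @return Character vector of assay identifiers.
#' @export
assay_kinds <- function() {
  c("O2_dissociation_trap", "CO_rebinding_LFP", "NO_binding", "NOD", "NiR")
}

#' Observed rate of gated (hexacoordinate) ligand binding
#'
#' For a hexacoordinate heme, exogenous ligand binding proceeds through the
#' transient pentacoordinate state and the observed pseudo-first-order rate is
#' limited by distal-His dissociation:
#' `k_obs = k_minus_H * k_prime_on * L / (k_H + k_prime_on * L)`.
#' The rate is monotone non-decreasing in the ligand concentration and bounded
#' above by `k_minus_H`, which produces the hallmark concentration
#' independence once ligand capture outcompetes His re-association.
#'
#' @param k_minus_H,k_H distal-His dissociation / re-association rates (s^-1).
#' @param k_prime_on intrinsic ligand association rate (M^-1 s^-1).
#' @param ligand ligand concentration (M).
#' @return Observed rate, s^-1. Vectorised over `ligand`.
#' @export
hexacoordinate_kobs <- function(k_minus_H, k_H, k_prime_on, ligand) {
  stopifnot(k_minus_H >= 0, k_H >= 0, k_prime_on >= 0, all(ligand >= 0))
  flux <- k_prime_on * ligand
  out <- ifelse(flux == 0, 0,
                ifelse(k_H + flux == 0, 0, k_minus_H * flux / (k_H + flux)))
  # k_H == 0 with ligand present: no re-association limit, gate fully open
  out[flux > 0 & k_H == 0] <- k_minus_H
  out
}

#' pH-dependent apparent nitrite reduction rate
#'
#' Nitrous acid (HNO2), not the nitrite anion, is the species reduced at the
#' ferrous heme, so the apparent rate scales with the protonated fraction
#' `f(pH) = 1 / (1 + 10^(pH - pKa))`. The constant measured at pH 7 is
#' rescaled by `f(pH) / f(7)`, giving the characteristic logarithmic increase
#' in rate as the pH drops (log-slope -1 per pH unit well above the pKa).
#'
#' @param k_NiR_pH7 apparent bimolecular constant at pH 7 (M^-1 s^-1).
#' @param pH assay pH.
#' @param pKa acid dissociation constant of nitrous acid; default 3.25 (25 C).
#' @param nitrite nitrite concentration (M).
#' @return Pseudo-first-order rate `k_app(pH) * nitrite`, s^-1.
#' @export
nitrite_rate <- function(k_NiR_pH7, pH = 7, pKa = 3.25, nitrite) {
  stopifnot(all(nitrite >= 0), k_NiR_pH7 >= 0)
  f <- function(p) 1 / (1 + 10^(p - pKa))
  k_NiR_pH7 * f(pH) / f(7) * nitrite
}

#' Oxygen affinity constants from association and dissociation rates
#'
#' @param k_on association rate constant (M^-1 s^-1), > 0.
#' @param k_off dissociation rate constant (s^-1), > 0.
#' @return List with the association equilibrium constant `K = k_on / k_off`
#'   (M^-1), the dissociation equilibrium constant `Kd = 1 / K` (M), and both
#'   rounded to two significant figures (`K_2sf`, `Kd_2sf`), the convention
#'   used when reporting affinities.
#' @export
affinity_constants <- function(k_on, k_off) {
  if (!is.finite(k_on) || !is.finite(k_off) || k_on <= 0 || k_off <= 0) {
    stop("affinity_constants: k_on and k_off must be positive", call. = FALSE)
  }
  K <- k_on / k_off
  list(K = K, Kd = 1 / K, K_2sf = signif(K, 2), Kd_2sf = signif(1 / K, 2))
}
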