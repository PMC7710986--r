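# Instrument-realistic synthetic data: stopped-flow and laser-flash
# photolysis time courses and scanning-spectrophotometer series generated
# from simulated trajectories.

#' Instrument acquisition profile
#'
#' @param kind `"stopped_flow"`, `"lfp"` or `"scanning_spectrophotometer"`.
#' @param dead_time interval after mixing / flash during which no signal can
#'   be recorded, s. Defaults: 1.2 ms (stopped flow), 5 us (flash photolysis
#'   detector), 0 (scanning).
#' @param sampling_interval spacing of acquired points, s.
#' @param duration total observation window, s.
#' @param noise_sd additive Gaussian noise, absorbance units (default
#'   0.002 AU, typical diode-array noise).
#' @param pathlength optical path, cm.
#' @return Object of class `instrument_profile`.
#' @export
instrument_profile <- function(kind = c("stopped_flow", "lfp",
                                        "scanning_spectrophotometer"),
                               dead_time = NULL, sampling_interval = NULL,
                               duration = NULL, noise_sd = 0.002,
                               pathlength = 1) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    stopped_flow = list(dead_time = 1.2e-3, sampling_interval = 1.2e-3,
                        duration = 2),
    lfp = list(dead_time = 5e-6, sampling_interval = 1e-4, duration = 0.2),
    scanning_spectrophotometer = list(dead_time = 0, sampling_interval = 1,
                                      duration = 60))
  dead_time <- dead_time %||% defaults$dead_time
  sampling_interval <- sampling_interval %||% defaults$sampling_interval
  duration <- duration %||% defaults$duration
  stopifnot(dead_time >= 0, sampling_interval > 0, noise_sd >= 0,
            duration > dead_time, pathlength > 0)
  structure(list(kind = kind, dead_time = dead_time,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_sd = noise_sd, pathlength = pathlength),
            class = "instrument_profile")
}

#' Default instrument profile for an assay
#'
#' Observation windows reflect how each assay is run: NO binding is followed
#' for up to 2 s at the 1.2 ms stopped-flow sampling; the dithionite-trap
#' O2 dissociation is followed for 30 s on the photometric channel (20 ms
#' sampling, fine enough to separate rates less than 2-fold apart); nitrite
#' reduction is followed for 200 s; the NO dioxygenase reaction completes
#' within milliseconds; flash-photolysis traces resolve 0.1 ms.
#'
#' @param assay_kind one of [assay_kinds()].
#' @return An [instrument_profile()].
#' @export
default_instrument <- function(assay_kind) {
  assay_kind <- match.arg(assay_kind, assay_kinds())
  switch(assay_kind,
    O2_dissociation_trap = instrument_profile("stopped_flow",
                                              sampling_interval = 0.02,
                                              duration = 30),
    NO_binding = instrument_profile("stopped_flow", duration = 2),
    NOD = instrument_profile("stopped_flow", duration = 0.06),
    NiR = instrument_profile("scanning_spectrophotometer",
                             sampling_interval = 0.2, duration = 200),
    CO_rebinding_LFP = instrument_profile("lfp", sampling_interval = 1e-4,
                                          duration = 0.2))
}

#' Default observation wavelength for an assay
#'
#' Chosen for contrast between the initial and final heme species: the
#' deoxyferrous Soret region (423-424 nm) for the trap, NO-binding, NiR and
#' CO assays, and the oxyferrous flank (417 nm) for the NOD reaction where
#' the oxyferrous and ferric Sorets nearly coincide.
#'
#' @param assay_kind one of [assay_kinds()].
#' @return Wavelength, nm.
#' @export
default_wavelength <- function(assay_kind) {
  assay_kind <- match.arg(assay_kind, assay_kinds())
  switch(assay_kind,
    O2_dissociation_trap = 423, NO_binding = 424, NOD = 417,
    NiR = 424, CO_rebinding_LFP = 424)
}

#' Derive a per-trace seed from a master seed
#'
#' Counter-hash derivation (multiplicative congruential mixing modulo
#' 2^31 - 1): deterministic, collision-sparse and independent of R's global
#' RNG state. Recorded in each trace's metadata.
#'
#' @param master master seed (integer).
#' @param index trace counter (0, 1, 2, ...).
#' @return Derived seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  mulmod <- function(a, b) {
    b1 <- b %/% 65536
    b0 <- b %% 65536
    (((a * b1) %% m) * 65536 + a * b0) %% m
  }
  s <- (abs(master) %% (m - 1)) + 1
  s <- mulmod(s, 48271)
  s <- mulmod((s + index) %% m + 1, 69621)
  s <- mulmod(s, 48271)
  as.integer(s)
}

# Evaluate noise reproducibly without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Beer-Lambert projection of a trajectory at one wavelength.
.project_absorbance <- function(traj, basis, wavelength, pathlength) {
  map <- attr(traj, "basis_species")
  if (is.null(map)) {
    stop("apply_instrument: trajectory lacks a basis_species attribute",
         call. = FALSE)
  }
  scale <- attr(traj, "signal_scale")
  A <- numeric(nrow(traj))
  for (sp in names(map)) {
    lbl <- map[[sp]]
    if (is.na(lbl) || !sp %in% names(traj)) next
    w <- if (!is.null(scale) && sp %in% names(scale)) scale[[sp]] else 1
    b <- basis[[lbl]]
    if (is.null(b)) {
      stop("apply_instrument: basis is missing species '", lbl, "'",
           call. = FALSE)
    }
    if (wavelength < min(b$wavelengths) || wavelength > max(b$wavelengths)) {
      stop("apply_instrument: wavelength ", wavelength,
           " nm outside basis support", call. = FALSE)
    }
    eps <- stats::approx(b$wavelengths, b$extinction, xout = wavelength)$y
    A <- A + eps * w * traj[[sp]] * pathlength
  }
  A
}

#' Record a simulated trajectory through an instrument
#'
#' Converts species concentrations to absorbance at one wavelength
#' (Beer-Lambert), discards everything before the dead time, resamples at
#' the instrument's sampling interval and adds zero-mean Gaussian noise
#' generated from `seed`.
#'
#' @param traj trajectory from [simulate_scheme()]; must cover
#'   `[0, duration]`.
#' @param basis a `basis_set` covering the heme species in the trajectory.
#' @param instr an [instrument_profile()].
#' @param wavelength observation wavelength, nm.
#' @param seed integer noise seed.
#' @param truth optional list of generating parameters, stored verbatim.
#' @return Object of class `timecourse`: `times`, `signal`, `instrument`,
#'   `wavelength`, `seed`, `truth` (with the noiseless signal in
#'   `truth$noiseless`).
#' @export
apply_instrument <- function(traj, basis, instr, wavelength, seed,
                             truth = NULL) {
  stopifnot(inherits(instr, "instrument_profile"))
  times <- seq(instr$dead_time, instr$duration, by = instr$sampling_interval)
  if (max(traj$time) < max(times) - 1e-12) {
    stop("apply_instrument: trajectory does not cover the instrument duration",
         call. = FALSE)
  }
  A_traj <- .project_absorbance(traj, basis, wavelength, instr$pathlength)
  noiseless <- stats::approx(traj$time, A_traj, xout = times)$y
  noise <- if (instr$noise_sd > 0) {
    .with_seed(seed, stats::rnorm(length(times), 0, instr$noise_sd))
  } else {
    numeric(length(times))
  }
  truth <- truth %||% list()
  truth$noiseless <- noiseless
  timecourse(times, noiseless + noise, instr, wavelength, seed, truth)
}

#' A recorded (or synthetic) kinetic time course
#'
#' @param times sample times, s; start at or after the dead time and are
#'   evenly spaced.
#' @param signal absorbance, AU.
#' @param instrument an [instrument_profile()].
#' @param wavelength observation wavelength, nm.
#' @param seed noise seed (metadata).
#' @param truth optional generating-parameter record.
#' @return Object of class `timecourse`.
#' @export
timecourse <- function(times, signal, instrument, wavelength,
                       seed = NA_integer_, truth = NULL) {
  stopifnot(length(times) == length(signal), all(is.finite(signal)))
  if (times[1] < instrument$dead_time - 1e-12) {
    stop("timecourse: samples precede the instrument dead time",
         call. = FALSE)
  }
  structure(list(times = times, signal = signal, instrument = instrument,
                 wavelength = wavelength, seed = seed, truth = truth),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf(
    "<timecourse> %d points, %g-%g s at %g nm (%s, dead %g s, noise %g AU)\n",
    length(x$times), min(x$times), max(x$times), x$wavelength,
    x$instrument$kind, x$instrument$dead_time, x$instrument$noise_sd))
  invisible(x)
}

#' Generate a replicated assay dataset
#'
#' Simulates the assay once per condition value (the deterministic
#' trajectory) and pushes it through the instrument once per replicate with
#' per-trace seeds derived from the master seed, mirroring how a titration
#' series is measured in triplicate.
#'
#' @param protein a [protein_model()].
#' @param cond template [assay_conditions()].
#' @param vary name of the `assay_conditions` field to vary (or `NULL` to
#'   keep the template as is).
#' @param values numeric vector of values for `vary`.
#' @param n_replicates replicates per value.
#' @param seed master seed.
#' @param instr instrument profile; default [default_instrument()].
#' @param wavelength observation wavelength; default [default_wavelength()].
#' @param basis basis set; default built from the catalogue.
#' @param ... passed to [build_scheme()].
#' @return List of [timecourse()] objects with `truth` blocks recording the
#'   assay, varied value, replicate and per-trace seed.
#' @export
generate_assay_dataset <- function(protein, cond, vary = NULL, values = NULL,
                                   n_replicates = 1, seed = 1,
                                   instr = NULL, wavelength = NULL,
                                   basis = NULL, ...) {
  stopifnot(inherits(cond, "assay_conditions"))
  if (is.null(vary)) {
    vary <- "protein_conc"
    values <- cond$protein_conc
  }
  if (!vary %in% names(cond)) {
    stop("generate_assay_dataset: '", vary,
         "' is not an assay_conditions field", call. = FALSE)
  }
  if (!length(values)) {
    stop("generate_assay_dataset: empty value list", call. = FALSE)
  }
  instr <- instr %||% default_instrument(cond$assay_kind)
  wavelength <- wavelength %||% default_wavelength(cond$assay_kind)
  basis <- basis %||% make_basis(names(species_catalogue()))
  out <- vector("list", length(values) * n_replicates)
  idx <- 0L
  for (v in seq_along(values)) {
    cond_v <- cond
    cond_v[[vary]] <- values[v]
    scheme <- build_scheme(protein, cond_v, ...)
    t_grid <- unique(c(0, seq(instr$dead_time, instr$duration,
                              by = instr$sampling_interval)))
    traj <- simulate_scheme(scheme, t_grid)
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1L
      tr_seed <- derive_seed(seed, idx - 1L)
      truth <- list(assay = cond$assay_kind, protein = protein$name,
                    vary = vary, value = values[v], replicate = r,
                    conditions = unclass(cond_v))
      out[[idx]] <- apply_instrument(traj, basis, instr, wavelength,
                                     seed = tr_seed, truth = truth)
    }
  }
  out
}

#' Generate a time-resolved spectral series
#'
#' Like [apply_instrument()] but over the full wavelength grid of the basis,
#' with independent Gaussian noise per (wavelength, time) cell.
#'
#' @param traj trajectory from [simulate_scheme()].
#' @param basis a `basis_set`.
#' @param instr an [instrument_profile()].
#' @param seed noise seed.
#' @return A [spectrum_series()]; attribute `truth` holds the generating
#'   concentration matrix.
#' @export
generate_spectrum_series <- function(traj, basis, instr, seed) {
  stopifnot(inherits(instr, "instrument_profile"))
  times <- if (instr$duration <= instr$dead_time) {
    instr$dead_time
  } else {
    seq(instr$dead_time, instr$duration, by = instr$sampling_interval)
  }
  map <- attr(traj, "basis_species")
  wl <- basis[[1]]$wavelengths
  E <- basis_matrix(basis)
  heme_sp <- names(map)[!is.na(map) & names(map) %in% names(traj)]
  scale <- attr(traj, "signal_scale")
  C <- sapply(heme_sp, function(sp) {
    w <- if (!is.null(scale) && sp %in% names(scale)) scale[[sp]] else 1
    w * stats::approx(traj$time, traj[[sp]], xout = times)$y
  })
  C <- matrix(C, nrow = length(times),
              dimnames = list(NULL, heme_sp))
  # sum concentrations per basis label, then project
  labels <- unique(unname(map[heme_sp]))
  Cb <- sapply(labels, function(l) {
    rowSums(C[, heme_sp[map[heme_sp] == l], drop = FALSE])
  })
  Cb <- matrix(Cb, nrow = length(times), dimnames = list(NULL, labels))
  missing <- setdiff(labels, colnames(E))
  if (length(missing)) {
    stop("generate_spectrum_series: basis is missing species ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  A <- E[, labels, drop = FALSE] %*% t(Cb) * instr$pathlength
  if (instr$noise_sd > 0) {
    A <- A + .with_seed(seed,
      matrix(stats::rnorm(length(A), 0, instr$noise_sd), nrow(A), ncol(A)))
  }
  out <- spectrum_series(wl, times, A, instr$pathlength)
  attr(out, "truth") <- list(times = times, concentrations = Cb, seed = seed)
  out
}
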