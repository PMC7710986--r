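# Species basis spectra, Beer-Lambert quantitation, Savitzky-Golay second
# derivatives and non-negative spectral unmixing.
#
# Band shapes are Gaussian, parameterised by centre (nm), full width at half
# maximum (nm) and peak extinction (M^-1 cm^-1). Every globin Soret band is
# anchored to 150 mM^-1 cm^-1, the coefficient used for heme quantitation;
# Q-band amplitudes default to a tenth of the Soret.

.soret_eps <- 1.5e5  # M^-1 cm^-1

#' Catalogue of species band positions
#'
#' Band centres for the ferric, deoxyferrous (hexa- and pentacoordinate)
#' states follow the measured positions: ferric 6cLS Soret ~410 nm with Q
#' bands at 532 nm and a 563 nm shoulder; deoxyferrous 6cLS Soret 423 nm
#' (a single catalogue value resolves the 422-424 nm spread across
#' experiments) with Q bands at 527 and 556 nm; pentacoordinate high-spin
#' deoxy Soret at 435 nm. Band positions of the remaining complexes
#' (oxyferrous, carboxy, ferrous-NO, ferric-NO) are generic globin values,
#' flagged `non_measured` in the catalogue. `proli_nonoate` is included for
#' reagent quantitation (252 nm, 8400 M^-1 cm^-1).
#'
#' @return Named list; each entry has a `bands` matrix (columns `center_nm`,
#'   `fwhm_nm`, `peak_eps`) and a logical `non_measured`.
#' @export
species_catalogue <- function() {
  q <- 0.1 * .soret_eps
  band <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center_nm", "fwhm_nm", "peak_eps")
    m
  }
  list(
    ferric_6cLS = list(bands = band(410, 10, .soret_eps,
                                    532, 14, q, 563, 14, 0.5 * q),
                       non_measured = FALSE),
    deoxy_6cLS = list(bands = band(423, 10, .soret_eps,
                                   527, 14, q, 556, 14, q),
                      non_measured = FALSE),
    deoxy_5cHS = list(bands = band(435, 14, .soret_eps, 556, 18, q),
                      non_measured = FALSE),
    oxyferrous = list(bands = band(412, 10, .soret_eps,
                                   541, 14, q, 577, 14, q),
                      non_measured = TRUE),
    carboxy = list(bands = band(419, 10, .soret_eps,
                                540, 14, q, 569, 14, q),
                   non_measured = TRUE),
    ferrous_NO = list(bands = band(417, 10, .soret_eps,
                                   545, 14, q, 575, 14, q),
                      non_measured = TRUE),
    ferric_NO = list(bands = band(420, 10, .soret_eps,
                                  533, 14, q, 565, 14, q),
                     non_measured = TRUE),
    proli_nonoate = list(bands = band(252, 60, 8400),
                         non_measured = FALSE)
  )
}

.eval_bands <- function(bands, wl) {
  out <- numeric(length(wl))
  for (b in seq_len(nrow(bands))) {
    out <- out + bands[b, "peak_eps"] *
      exp(-4 * log(2) * (wl - bands[b, "center_nm"])^2 / bands[b, "fwhm_nm"]^2)
  }
  out
}

#' Build basis spectra for a set of species
#'
#' @param species character vector of catalogue labels.
#' @param wavelengths wavelength grid, nm (default 250-700 nm at 1 nm).
#' @param catalogue band catalogue, defaults to [species_catalogue()];
#'   override entries to change band positions, widths or amplitudes.
#' @return Object of class `basis_set`: list of per-species basis spectra
#'   (`species`, `bands`, `wavelengths`, `extinction` in M^-1 cm^-1,
#'   `non_measured`).
#' @export
make_basis <- function(species, wavelengths = 250:700,
                       catalogue = species_catalogue()) {
  stopifnot(length(species) >= 1, all(diff(wavelengths) > 0))
  unknown <- setdiff(species, names(catalogue))
  if (length(unknown)) {
    stop("make_basis: unknown species label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  basis <- lapply(species, function(sp) {
    entry <- catalogue[[sp]]
    centers <- entry$bands[, "center_nm"]
    if (any(centers < min(wavelengths) | centers > max(wavelengths))) {
      stop("make_basis: band centre of '", sp,
           "' outside the wavelength grid", call. = FALSE)
    }
    list(species = sp, bands = entry$bands, wavelengths = wavelengths,
         extinction = .eval_bands(entry$bands, wavelengths),
         non_measured = isTRUE(entry$non_measured))
  })
  names(basis) <- species
  structure(basis, class = "basis_set")
}

#' Extinction matrix of a basis set
#'
#' @param basis a `basis_set` from [make_basis()].
#' @return Matrix (wavelengths x species) of extinction coefficients.
#' @export
basis_matrix <- function(basis) {
  stopifnot(inherits(basis, "basis_set"))
  sapply(basis, function(b) b$extinction)
}

#' A single absorbance spectrum
#'
#' @param wavelengths nm grid, strictly increasing.
#' @param absorbance absorbance values (AU).
#' @param pathlength optical path, cm.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, absorbance, pathlength = 1) {
  stopifnot(length(wavelengths) == length(absorbance),
            all(diff(wavelengths) > 0), pathlength > 0)
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 pathlength = pathlength), class = "spectrum")
}

#' Quantify a species from its peak absorbance
#'
#' Beer-Lambert inversion at the species' quantitation wavelength (its
#' strongest catalogued band): `c = A_peak / (eps * pathlength)`. Globins are
#' quantified at the Soret with 150 mM^-1 cm^-1; the NO-donor reagent at
#' 252 nm with 8400 M^-1 cm^-1.
#'
#' @param spec a [spectrum()].
#' @param species catalogue label.
#' @param catalogue band catalogue.
#' @return Concentration (M); attribute `saturated` is `TRUE` (with a
#'   warning) when the peak absorbance exceeds 3.0 and the photometric
#'   estimate is unreliable.
#' @export
quantify <- function(spec, species, catalogue = species_catalogue()) {
  stopifnot(inherits(spec, "spectrum"))
  entry <- catalogue[[species]]
  if (is.null(entry)) {
    stop("quantify: unknown species '", species, "'", call. = FALSE)
  }
  peak <- entry$bands[which.max(entry$bands[, "peak_eps"]), , drop = TRUE]
  wl <- peak[["center_nm"]]
  if (wl < min(spec$wavelengths) || wl > max(spec$wavelengths)) {
    stop("quantify: spectrum does not cover the quantitation wavelength ",
         wl, " nm", call. = FALSE)
  }
  A <- stats::approx(spec$wavelengths, spec$absorbance, xout = wl)$y
  conc <- A / (peak[["peak_eps"]] * spec$pathlength)
  saturated <- A > 3
  if (saturated) {
    warning("quantify: absorbance ", signif(A, 3),
            " exceeds 3.0; estimate flagged as saturated", call. = FALSE)
  }
  structure(conc, saturated = saturated)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Second-derivative spectra sharpen overlapping Soret bands: the D2 minima
#' locate band centres that are unresolved in the raw absorbance. The filter
#' is a least-squares local polynomial (Savitzky-Golay); edges, where the
#' moving window is incomplete, are trimmed by half a window.
#'
#' @param spec a [spectrum()].
#' @param window_points odd window length in grid points (default 15).
#' @param poly_order polynomial order, `>= 2` and `< window_points`
#'   (default 4).
#' @return A [spectrum()] holding D2 (AU / nm^2) on the trimmed grid.
#' @export
second_derivative <- function(spec, window_points = 15, poly_order = 4) {
  stopifnot(inherits(spec, "spectrum"))
  n <- length(spec$wavelengths)
  if (window_points %% 2 != 1) {
    stop("second_derivative: window_points must be odd", call. = FALSE)
  }
  if (poly_order < 2 || poly_order >= window_points) {
    stop("second_derivative: need window_points > poly_order >= 2",
         call. = FALSE)
  }
  if (window_points > n) {
    stop("second_derivative: window larger than the wavelength grid",
         call. = FALSE)
  }
  step <- unique(round(diff(spec$wavelengths), 10))
  if (length(step) != 1L) {
    stop("second_derivative: wavelength grid must be evenly spaced",
         call. = FALSE)
  }
  d2 <- signal::sgolayfilt(spec$absorbance, p = poly_order,
                           n = window_points, m = 2, ts = step)
  half <- (window_points - 1L) / 2L
  keep <- (half + 1L):(n - half)
  spectrum(spec$wavelengths[keep], d2[keep], spec$pathlength)
}

#' Locate D2 minima (band centres)
#'
#' @param d2 a second-derivative [spectrum()].
#' @param prominence keep only minima deeper than `prominence * max(-D2)`
#'   (default 0.02) to suppress noise wiggles.
#' @return Wavelengths (nm) of the local minima, ascending.
#' @export
d2_minima <- function(d2, prominence = 0.02) {
  stopifnot(inherits(d2, "spectrum"))
  y <- d2$absorbance
  n <- length(y)
  idx <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  depth <- -y[idx]
  idx <- idx[depth > prominence * max(-y)]
  d2$wavelengths[idx]
}

#' Time-resolved spectral series
#'
#' @param wavelengths nm grid, strictly increasing.
#' @param times acquisition times, s.
#' @param absorbance matrix (wavelength x time), AU.
#' @param pathlength optical path, cm.
#' @return Object of class `spectrum_series`.
#' @export
spectrum_series <- function(wavelengths, times, absorbance, pathlength = 1) {
  absorbance <- as.matrix(absorbance)
  stopifnot(all(diff(wavelengths) > 0),
            nrow(absorbance) == length(wavelengths),
            ncol(absorbance) == length(times), pathlength > 0)
  structure(list(wavelengths = wavelengths, times = times,
                 absorbance = absorbance, pathlength = pathlength),
            class = "spectrum_series")
}

#' Unmix a spectral series into species concentrations
#'
#' Per time point, solves the non-negativity-constrained linear least-squares
#' projection of the spectrum onto the basis extinction matrix
#' (Beer-Lambert), returning species concentration time courses.
#'
#' @param series a [spectrum_series()].
#' @param basis a `basis_set` with at least two linearly independent spectra.
#' @return List: `times`, `concentrations` (time x species matrix, M),
#'   `residual` (per-time relative residual norm).
#' @export
unmix_series <- function(series, basis) {
  stopifnot(inherits(series, "spectrum_series"), inherits(basis, "basis_set"))
  if (length(basis) < 2L) {
    stop("unmix_series: need at least two basis spectra", call. = FALSE)
  }
  E <- sapply(basis, function(b) {
    stats::approx(b$wavelengths, b$extinction, xout = series$wavelengths,
                  rule = 2)$y
  })
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) {
    cors <- stats::cor(E)
    pairs <- which(abs(cors) > 0.999 & upper.tri(cors), arr.ind = TRUE)
    desc <- apply(pairs, 1, function(ij) {
      paste(colnames(E)[ij[1]], "~", colnames(E)[ij[2]])
    })
    stop("unmix_series: rank-deficient basis; collinear pairs: ",
         paste(desc, collapse = ", "), call. = FALSE)
  }
  M <- E * series$pathlength
  nt <- length(series$times)
  conc <- matrix(0, nt, ncol(E), dimnames = list(NULL, colnames(E)))
  resid <- numeric(nt)
  for (j in seq_len(nt)) {
    a <- series$absorbance[, j]
    sol <- pracma::lsqnonneg(M, a)
    conc[j, ] <- sol$x
    nrm <- sqrt(sum(a^2))
    resid[j] <- if (nrm > 0) sqrt(sol$resid.norm) / nrm else 0
  }
  list(times = series$times, concentrations = conc, residual = resid)
}
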