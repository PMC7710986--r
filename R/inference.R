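# The fitting chain: multi-exponential decomposition with phase-count
# selection, hyperbolic trap-saturation fits, second-order regression,
# concentration-independence classification, dead-time censoring bounds and
# reference comparisons.

.tc_data <- function(tc) {
  if (inherits(tc, "timecourse")) {
    data.frame(time = tc$times, signal = tc$signal)
  } else {
    df <- as.data.frame(tc)
    names(df)[1:2] <- c("time", "signal")
    df
  }
}

# Residual sum of squares of baseline + sum_i a_i exp(-k_i t) with the
# linear coefficients (baseline, amplitudes) profiled out.
.vp_rss <- function(logk, t, y) {
  k <- exp(logk)
  X <- cbind(1, exp(-outer(t, k)))
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

.vp_coef <- function(logk, t, y) {
  k <- exp(logk)
  X <- cbind(1, exp(-outer(t, k)))
  stats::lm.fit(X, y)$coefficients
}

.aicc <- function(rss, n, p) {
  # p counts mean-function parameters; +1 for the noise variance
  p <- p + 1
  if (n - p - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Fit a multi-exponential decay with phase-count selection
#'
#' Fits `baseline + sum(a_i * exp(-k_i * t))` for 0 to `max_phases` phases
#' by separable (variable-projection) least squares with deterministic
#' multi-start over log-spaced rate seeds. The phase count is chosen by the
#' corrected Akaike information criterion, after which phases that are not
#' identifiable are demoted: a phase whose amplitude is below
#' `amp_frac_min` of the total signal change, or whose rate is within a
#' factor `rate_sep_min` of another phase, is absorbed into the simpler
#' model. Standard errors come from the local quadratic approximation at
#' the optimum.
#'
#' @param tc a [timecourse()] or a two-column (time, signal) data frame.
#' @param max_phases maximum number of exponential phases (default 2).
#' @param n_starts number of multi-start rate seeds per phase count.
#' @param amp_frac_min identifiability guard: minimum amplitude share.
#' @param rate_sep_min identifiability guard: minimum rate separation
#'   factor between phases.
#' @return Object of class `exp_fit`: `n_phases`, `rates` (sorted
#'   descending, s^-1), `amplitudes` (signed, AU), `baseline`, standard
#'   errors, `objective` (residual sum of squares), `selection_scores`
#'   (AICc per candidate phase count) and a `converged` flag.
#' @export
fit_multiexponential <- function(tc, max_phases = 2, n_starts = 5,
                                 amp_frac_min = 0.05, rate_sep_min = 1.5) {
  d <- .tc_data(tc)
  t <- d$time
  y_raw <- d$signal
  n <- length(t)
  if (n < 10L) {
    stop("fit_multiexponential: need at least 10 points after the dead time",
         call. = FALSE)
  }
  # work on a unit-scale signal so convergence is amplitude-invariant
  y_shift <- mean(y_raw)
  y_scale <- diff(range(y_raw))
  if (y_scale == 0) y_scale <- 1
  y <- (y_raw - y_shift) / y_scale
  t_span <- max(t) - min(t)
  dt <- min(diff(t))
  k_lo <- log(0.2 / t_span)
  k_hi <- log(2 / dt)
  grid <- seq(k_lo, k_hi, length.out = max(n_starts, 3))

  fits <- list()
  rss0 <- sum((y - mean(y))^2)
  fits[["0"]] <- list(n_phases = 0L, logk = numeric(0), rss = rss0)
  for (nph in seq_len(max_phases)) {
    starts <- if (nph == 1L) {
      lapply(grid[seq_len(n_starts)], function(g) g)
    } else {
      sep <- (k_hi - k_lo) / 3
      lapply(grid[seq_len(n_starts)], function(g) {
        c(pmin(g + sep, k_hi), pmax(g - sep, k_lo))
      })
    }
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(
        stats::nlminb(s, .vp_rss, t = t, y = y,
                      lower = k_lo - 14, upper = k_hi + 7),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
        best <- opt
      }
    }
    if (is.null(best)) next
    fits[[as.character(nph)]] <- list(n_phases = nph, logk = best$par,
                                      rss = best$objective)
  }
  if (length(fits) == 1L && max_phases > 0L) {
    return(structure(list(n_phases = 0L, rates = numeric(0),
                          amplitudes = numeric(0), baseline = y_shift,
                          converged = FALSE), class = "exp_fit"))
  }
  sel <- data.frame(
    n_phases = vapply(fits, `[[`, integer(1), "n_phases"),
    rss = vapply(fits, `[[`, numeric(1), "rss"))
  sel$aicc <- mapply(.aicc, sel$rss, n, 1 + 2 * sel$n_phases)
  pick <- fits[[which.min(sel$aicc)]]

  # identifiability demotion
  repeat {
    nph <- pick$n_phases
    if (nph < 1L) break
    coefs <- .vp_coef(pick$logk, t, y)
    a <- coefs[-1]
    k <- exp(pick$logk)
    drop_phase <- FALSE
    if (any(!is.finite(a))) drop_phase <- TRUE
    if (!drop_phase && nph >= 1L) {
      share <- abs(a) / sum(abs(a))
      if (nph >= 2L && any(share < amp_frac_min)) drop_phase <- TRUE
    }
    if (!drop_phase && nph >= 2L) {
      ks <- sort(k)
      if (any(ks[-1] / ks[-nph] < rate_sep_min)) drop_phase <- TRUE
    }
    if (!drop_phase) break
    pick <- fits[[as.character(nph - 1L)]]
    if (is.null(pick)) pick <- fits[["0"]]
  }

  sel$rss <- sel$rss * y_scale^2
  nph <- pick$n_phases
  if (nph == 0L) {
    return(structure(list(
      n_phases = 0L, rates = numeric(0), amplitudes = numeric(0),
      se_rates = numeric(0), se_amplitudes = numeric(0),
      baseline = y_shift, se_baseline = stats::sd(y_raw) / sqrt(n),
      objective = pick$rss * y_scale^2, selection_scores = sel,
      converged = TRUE), class = "exp_fit"))
  }
  k <- exp(pick$logk)
  coefs <- .vp_coef(pick$logk, t, y)
  b <- coefs[1]
  a <- coefs[-1]
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]
  a <- a[ord]
  # local quadratic uncertainties on (b, a_i, k_i)
  E <- exp(-outer(t, k))
  J <- cbind(1, E, -sweep(t * E, 2, a, `*`))
  dof <- n - (2 * nph + 1)
  covm <- tryCatch(pick$rss / dof * solve(crossprod(J)),
                   error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, ncol(J)) else sqrt(diag(covm))
  structure(list(
    n_phases = nph, rates = unname(k),
    amplitudes = unname(a) * y_scale,
    se_rates = unname(se[(nph + 2):(2 * nph + 1)]),
    se_amplitudes = unname(se[2:(nph + 1)]) * y_scale,
    baseline = unname(b) * y_scale + y_shift,
    se_baseline = unname(se[1]) * y_scale,
    objective = pick$rss * y_scale^2, selection_scores = sel,
    converged = TRUE), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> ", x$n_phases, " phase(s)\n", sep = "")
  if (x$n_phases > 0) {
    for (i in seq_len(x$n_phases)) {
      cat(sprintf("  k%d = %.6g +/- %.2g /s, amplitude %.4g AU\n", i,
                  x$rates[i], x$se_rates[i], x$amplitudes[i]))
    }
  }
  cat(sprintf("  baseline %.4g AU, RSS %.3g\n", x$baseline, x$objective))
  invisible(x)
}

#' Hyperbolic trap-saturation fit
#'
#' In the dithionite-trap assay the observed O2 release rate rises with trap
#' concentration as rebinding is outcompeted and saturates at the true
#' dissociation rate; `k_obs = k_max * c / (c_half + c)` is fitted and
#' `k_max` reported as the maximum (true) `k_off`.
#'
#' @param kobs_by_conc data frame or matrix with columns `conc` (M) and
#'   `kobs` (s^-1); at least 3 distinct concentrations.
#' @return List: `k_max`, `se_k_max`, `ci_k_max` (95%), `c_half`,
#'   `extrapolated` (`TRUE` when `c_half` exceeds the largest measured
#'   concentration, with a warning), and the `fit` object.
#' @export
fit_trap_saturation <- function(kobs_by_conc) {
  d <- as.data.frame(kobs_by_conc)
  names(d)[1:2] <- c("conc", "kobs")
  if (length(unique(d$conc)) < 3L) {
    stop("fit_trap_saturation: need >= 3 distinct concentrations",
         call. = FALSE)
  }
  spread <- stats::sd(d$kobs) / mean(d$kobs)
  if (!is.finite(spread) || spread < 1e-8) {
    return(list(k_max = mean(d$kobs), se_k_max = 0,
                ci_k_max = rep(mean(d$kobs), 2), c_half = 0,
                extrapolated = FALSE, fit = NULL))
  }
  start <- list(k_max = 1.05 * max(d$kobs),
                c_half = stats::median(d$conc) *
                  max(max(d$kobs) / stats::median(d$kobs) - 1, 0.05))
  fit <- minpack.lm::nlsLM(kobs ~ k_max * conc / (c_half + conc),
                           data = d, start = start,
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  extrapolated <- est[["c_half"]] > max(d$conc)
  if (extrapolated) {
    warning("fit_trap_saturation: c_half exceeds the largest concentration; ",
            "k_max is an extrapolation", call. = FALSE)
  }
  list(k_max = unname(est[["k_max"]]), se_k_max = unname(se[["k_max"]]),
       ci_k_max = unname(est[["k_max"]] + c(-1.96, 1.96) * se[["k_max"]]),
       c_half = unname(est[["c_half"]]), extrapolated = extrapolated,
       fit = fit)
}

#' A second-order rate determination
#'
#' Container for the outcome of regressing observed rates on ligand
#' concentration, or for a censored (dead-time-limited) observation. A
#' censored determination never carries a finite second-order constant.
#'
#' @param second_order_k slope, M^-1 s^-1 (NULL when censored).
#' @param intercept intercept, s^-1.
#' @param slope_ci 95% confidence interval on the slope.
#' @param intercept_p p-value for intercept != 0.
#' @param verdict `"gated_independent"`, `"bimolecular_dependent"`,
#'   `"indeterminate"` or `NA`.
#' @param censored logical.
#' @param lower_bound censored lower bound on the first-order rate, s^-1.
#' @param details free-form list.
#' @return Object of class `rate_determination`.
#' @export
rate_determination <- function(second_order_k = NULL, intercept = NA_real_,
                               slope_ci = c(NA_real_, NA_real_),
                               intercept_p = NA_real_,
                               verdict = NA_character_, censored = FALSE,
                               lower_bound = NA_real_, details = list()) {
  if (censored && !is.null(second_order_k)) {
    stop("rate_determination: a censored result cannot carry a ",
         "second-order constant", call. = FALSE)
  }
  if (censored && !is.finite(lower_bound)) {
    stop("rate_determination: a censored result must carry a lower bound",
         call. = FALSE)
  }
  structure(list(second_order_k = second_order_k, intercept = intercept,
                 slope_ci = slope_ci, intercept_p = intercept_p,
                 verdict = verdict, censored = censored,
                 lower_bound = lower_bound, details = details),
            class = "rate_determination")
}

#' @export
print.rate_determination <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<rate_determination> censored: rate > %.4g /s\n",
                x$lower_bound))
  } else {
    cat(sprintf(
      "<rate_determination> k2 = %.6g /M/s (95%% CI slope [%.4g, %.4g])%s\n",
      x$second_order_k %||% NA_real_, x$slope_ci[1], x$slope_ci[2],
      if (!is.na(x$verdict)) paste0(", verdict ", x$verdict) else ""))
  }
  invisible(x)
}

#' Second-order rate constant from a k_obs titration
#'
#' Ordinary least squares of observed pseudo-first-order rates on ligand
#' concentration; the slope is the bimolecular rate constant.
#'
#' @param kobs_by_conc data frame with columns `conc` (M), `kobs` (s^-1).
#' @param through_origin force a zero intercept.
#' @return A [rate_determination()].
#' @export
fit_second_order <- function(kobs_by_conc, through_origin = FALSE) {
  d <- as.data.frame(kobs_by_conc)
  names(d)[1:2] <- c("conc", "kobs")
  if (length(unique(d$conc)) < 3L) {
    stop("fit_second_order: need >= 3 distinct concentrations", call. = FALSE)
  }
  if (stats::sd(d$conc) == 0) {
    stop("fit_second_order: degenerate concentration spread", call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(kobs ~ 0 + conc, data = d)
         else stats::lm(kobs ~ conc, data = d)
  # an exactly linear input triggers a harmless perfect-fit warning
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["conc", "Estimate"]
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["conc", ]),
                 error = function(e) c(NA_real_, NA_real_))
  rate_determination(
    second_order_k = unname(slope),
    intercept = if (through_origin) 0 else unname(co["(Intercept)",
                                                     "Estimate"]),
    slope_ci = unname(ci),
    intercept_p = if (through_origin) NA_real_
                  else unname(co["(Intercept)", "Pr(>|t|)"]),
    details = list(fit = fit))
}

#' Classify concentration dependence of observed rates
#'
#' Distinguishes gated (His_d-limited, concentration-independent) binding
#' from ordinary bimolecular binding. The verdict is `gated_independent`
#' when either (a) the slope is statistically indistinguishable from zero
#' — its 95% confidence interval contains zero and the linear model does
#' not improve on the constant model by more than `aicc_margin` AICc units
#' — or (b) the dependence is kinetically negligible: the fitted line
#' predicts less than `rel_change_min` relative change in `k_obs` across
#' the measured range (a truly bimolecular rate scales with the
#' concentration span itself, so a few-percent change over a many-fold
#' range is independence in the mechanistic sense, however precisely it is
#' measured). Otherwise `bimolecular_dependent`. Fewer than 3
#' concentrations or less than a 4-fold span give `indeterminate`.
#'
#' @param kobs_by_conc data frame with columns `conc`, `kobs`.
#' @param aicc_margin AICc improvement needed to accept the linear model.
#' @param rel_change_min practical-equivalence bound on the predicted
#'   relative change of `k_obs` across the titration (default 0.05).
#' @return `"gated_independent"`, `"bimolecular_dependent"` or
#'   `"indeterminate"`.
#' @export
classify_dependence <- function(kobs_by_conc, aicc_margin = 2,
                                rel_change_min = 0.05) {
  d <- as.data.frame(kobs_by_conc)
  names(d)[1:2] <- c("conc", "kobs")
  concs <- unique(d$conc)
  if (length(concs) < 3L || max(concs) / min(concs[concs > 0]) < 4) {
    return("indeterminate")
  }
  n <- nrow(d)
  fit <- stats::lm(kobs ~ conc, data = d)
  ci <- suppressWarnings(stats::confint(fit)["conc", ])
  rss_line <- sum(stats::resid(fit)^2)
  rss_const <- sum((d$kobs - mean(d$kobs))^2)
  d_aicc <- .aicc(rss_const, n, 1) - .aicc(rss_line, n, 2)
  slope <- stats::coef(fit)[["conc"]]
  rel_change <- abs(slope) * diff(range(d$conc)) / mean(d$kobs)
  if ((ci[1] <= 0 && ci[2] >= 0 && d_aicc < aicc_margin) ||
      rel_change < rel_change_min) {
    "gated_independent"
  } else {
    "bimolecular_dependent"
  }
}

#' Dead-time censoring of a fast reaction
#'
#' Reactions faster than the instrument can resolve leave little or no
#' observable amplitude: with samples every `dt`, a time course whose half
#' time is below `t_half_factor * dt` cannot be characterised and only a
#' lower bound `ln(2) / (t_half_factor * dt)` on the rate is reported. A
#' trace is censored when at least `missing_frac` of the expected amplitude
#' is already lost at the first observable sample, or when the apparent
#' half time estimated from the trace falls below that resolution limit.
#'
#' @param tc a [timecourse()].
#' @param expected_amplitude expected total absorbance change, AU (from the
#'   initial and final species spectra).
#' @param t_half_factor resolution limit in sampling intervals (default
#'   2.5, i.e. 3 ms at 1.2 ms sampling).
#' @param missing_frac amplitude-missing fraction that triggers censoring.
#' @return A [rate_determination()]; when not censored, `details$fit`
#'   carries the exponential fit and `details$k_obs` the observed rate.
#' @export
censored_bound <- function(tc, expected_amplitude, t_half_factor = 2.5,
                           missing_frac = 0.95) {
  stopifnot(inherits(tc, "timecourse"), expected_amplitude > 0)
  dt <- tc$instrument$sampling_interval
  t_half_min <- t_half_factor * dt
  fit <- fit_multiexponential(tc, max_phases = 1)
  n <- length(tc$signal)
  plateau <- if (fit$n_phases >= 1L) fit$baseline
             else mean(tc$signal[max(1, n - 9):n])
  k_obs <- if (fit$n_phases >= 1L) fit$rates[1] else NA_real_
  # apparent half time read off the trace: first crossing of half the
  # expected amplitude above the plateau (robust to non-exponential tails)
  dev <- abs(tc$signal - plateau)
  below <- which(dev <= expected_amplitude / 2)
  t_half_obs <- if (!length(below)) {
    Inf
  } else if (below[1] == 1L) {
    tc$times[1]  # already half complete at the first observable sample
  } else {
    i <- below[1]
    stats::approx(dev[c(i - 1, i)], tc$times[c(i - 1, i)],
                  xout = expected_amplitude / 2)$y
  }
  remaining <- abs(tc$signal[1] - plateau)
  missing <- 1 - remaining / expected_amplitude
  if (missing >= missing_frac || t_half_obs < t_half_min) {
    rate_determination(censored = TRUE,
                       lower_bound = log(2) / t_half_min,
                       details = list(missing_amplitude_fraction = missing,
                                      t_half_observed = t_half_obs))
  } else {
    rate_determination(second_order_k = NULL, censored = FALSE,
                       lower_bound = NA_real_,
                       details = list(fit = fit, k_obs = k_obs,
                                      t_half_observed = t_half_obs,
                                      missing_amplitude_fraction = missing))
  }
}

#' Reference nitrite-reductase constants
#'
#' Published apparent NiR constants (M^-1 s^-1, pH 7) of hemoglobins used
#' as comparators: cyanobacterial SynHb, the class 1 phytoglobins of
#' Arabidopsis and rice, sperm whale myoglobin, human neuroglobin and the
#' distal-His mutant of neuroglobin.
#'
#' @return Named numeric vector.
#' @export
reference_nir_constants <- function() {
  c(SynHb = 68, arabidopsis_Glb1 = 58, rice_Glb1 = 83,
    sperm_whale_Mb = 2.9, human_neuroglobin = 0.25,
    neuroglobin_Hisd_mutant = 956)
}

#' Fold-change of a rate constant over reference hemoglobins
#'
#' @param k measured constant (M^-1 s^-1), > 0.
#' @param table named reference vector; default
#'   [reference_nir_constants()].
#' @return Named vector of `k / reference`, three significant figures.
#' @export
compare_to_references <- function(k, table = reference_nir_constants()) {
  stopifnot(k > 0)
  signif(k / table, 3)
}
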