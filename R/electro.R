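#' Voltammogram container
#'
#' A single potential sweep with its current response. Square-wave
#' voltammetry (SWV) traces carry the net peak current used for
#' quantification; cyclic voltammetry (CV) sweeps additionally carry the
#' scan rate so currents can be integrated to charge.
#'
#' @param potential Strictly monotone potential vector, V.
#' @param current Current vector, A (same length, at least 10 points).
#' @param technique `"SWV"` or `"CV"`.
#' @param scan_rate Scan rate, V/s (required for CV).
#' @return A `voltammogram` object.
#' @export
voltammogram <- function(potential, current, technique = c("SWV", "CV"),
                         scan_rate = NULL) {
  technique <- match.arg(technique)
  potential <- as.numeric(potential); current <- as.numeric(current)
  if (length(potential) != length(current) || length(potential) < 10L)
    stop("potential and current must have equal length >= 10")
  d <- diff(potential)
  if (!(all(d > 0) || all(d < 0)))
    stop("potential must be strictly monotone within a sweep")
  if (technique == "CV") {
    if (is.null(scan_rate) || scan_rate <= 0)
      stop("CV voltammograms need a positive scan_rate")
  }
  structure(list(potential = potential, current = current,
                 technique = technique, scan_rate = scan_rate),
            class = "voltammogram")
}

#' Detect a square-wave voltammetric peak
#'
#' Fits a linear baseline through the current minima flanking the search
#' window (the minimum of the first and of the last third of the window),
#' subtracts it, and reports the interior maximum of the corrected
#' current. The peak potential is refined by 3-point parabolic
#' interpolation. When the corrected trace has no interior maximum (for
#' example a flat trace, the behaviour of a non-responding interferent)
#' the peak is reported as not detected.
#'
#' @param v A [voltammogram()].
#' @param window Potential interval `c(lo, hi)` inside the sweep, V.
#' @return List with `detected` (logical), `Ep` (peak potential, V) and
#'   `ip` (baseline-corrected peak current, A); `Ep`/`ip` are `NA` when
#'   not detected.
#' @export
detect_swv_peak <- function(v, window = range(v$potential)) {
  stopifnot(inherits(v, "voltammogram"), length(window) == 2L)
  window <- sort(window)
  sel <- which(v$potential >= window[1] & v$potential <= window[2])
  if (length(sel) < 5L)
    stop("window contains fewer than 5 points of the sweep")
  E <- v$potential[sel]; i <- v$current[sel]
  ord <- order(E)
  E <- E[ord]; i <- i[ord]
  n <- length(E)
  third <- max(2L, floor(n / 3))
  li <- which.min(i[seq_len(third)])
  ri <- n - third + which.min(i[(n - third + 1L):n])
  if (ri == li) return(list(detected = FALSE, Ep = NA_real_, ip = NA_real_))
  slope <- (i[ri] - i[li]) / (E[ri] - E[li])
  corrected <- i - (i[li] + slope * (E - E[li]))
  pk <- which.max(corrected)
  tol <- 1e-12 + 1e-9 * max(abs(i))
  if (pk <= 1L || pk >= n || corrected[pk] <= tol ||
      corrected[pk] <= corrected[pk - 1L] + tol && corrected[pk] <= corrected[pk + 1L] + tol)
    return(list(detected = FALSE, Ep = NA_real_, ip = NA_real_))
  y <- corrected[(pk - 1L):(pk + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  offset <- if (abs(denom) > 1e-15 * max(abs(y))) {
    0.5 * (y[1] - y[3]) / denom
  } else 0
  offset <- max(-0.5, min(0.5, offset))
  dE <- mean(diff(E[(pk - 1L):(pk + 1L)]))
  Ep <- E[pk] + offset * dE
  ip <- y[2] - 0.25 * (y[1] - y[3]) * offset
  list(detected = TRUE, Ep = Ep, ip = ip)
}

#' Fit a linear calibration and compute detection limits
#'
#' Ordinary least squares of peak current on concentration. The limits of
#' detection and quantification follow the ICH-style rules
#' `LOD = 3.3 s / slope`, `LOQ = 10 s / slope`, where `s` is either the
#' standard error of the intercept (default) or a supplied blank standard
#' deviation; their ratio is fixed at 3.3 : 10 by construction.
#'
#' @param concentrations Concentrations, mol/L (at least 3 distinct).
#' @param peak_currents Peak currents, A.
#' @param lod_rule `"intercept_se"` or `"blank_sd"`.
#' @param s_blank Blank standard deviation, A (required for
#'   `lod_rule = "blank_sd"`).
#' @return A `calibration_result`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r_squared`, `n`, `lod`, `loq`.
#' @examples
#' x <- c(5, 10, 25, 50, 100) * 1e-6
#' fit_calibration(x, 567e-4 * x + 1e-8)
#' @export
fit_calibration <- function(concentrations, peak_currents,
                            lod_rule = c("intercept_se", "blank_sd"),
                            s_blank = NULL) {
  lod_rule <- match.arg(lod_rule)
  x <- as.numeric(concentrations); y <- as.numeric(peak_currents)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct concentrations")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; exact recovery of
  # noiseless data is a legitimate use here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) * diff(range(x)) <= 1e-12 * max(abs(y), 1e-300))
    stop("zero calibration slope")
  se <- sm$coefficients[, "Std. Error"]
  s <- if (lod_rule == "blank_sd") {
    if (is.null(s_blank) || s_blank < 0)
      stop("lod_rule = 'blank_sd' needs a non-negative s_blank")
    s_blank
  } else unname(se[1])
  lod <- 3.3 * s / abs(slope)
  loq <- 10 * s / abs(slope)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 r_squared = sm$r.squared, n = length(x),
                 lod = lod, loq = loq, lod_rule = lod_rule),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> ip = (%.4g +/- %.2g) [C] + (%.4g +/- %.2g), r^2 = %.5f (n = %d)\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se, x$r_squared, x$n))
  cat(sprintf("  LOD = %.3g mol/L, LOQ = %.3g mol/L (%s rule)\n",
              x$lod, x$loq, x$lod_rule))
  invisible(x)
}

#' Electrochemical impedance spectrum
#'
#' @param frequency Positive, strictly monotone frequencies, Hz; stored
#'   descending (high to low frequency, the usual sweep direction).
#' @param z_real,z_imag Real and imaginary impedance components, ohm.
#' @return An `eis_spectrum` object.
#' @export
eis_spectrum <- function(frequency, z_real, z_imag) {
  frequency <- as.numeric(frequency)
  z_real <- as.numeric(z_real); z_imag <- as.numeric(z_imag)
  if (length(frequency) < 5L ||
      length(z_real) != length(frequency) ||
      length(z_imag) != length(frequency))
    stop("frequency, z_real, z_imag must have equal length >= 5")
  if (any(frequency <= 0)) stop("frequencies must be positive")
  d <- diff(frequency)
  if (!(all(d > 0) || all(d < 0)))
    stop("frequencies must be strictly monotone")
  ord <- order(frequency, decreasing = TRUE)
  structure(list(frequency = frequency[ord], z_real = z_real[ord],
                 z_imag = z_imag[ord]),
            class = "eis_spectrum")
}

#' Randles equivalent-circuit parameters
#'
#' Solution resistance in series with a charge-transfer resistance in
#' parallel with a constant-phase element (CPE):
#' \deqn{Z(\omega) = R_s + \frac{R_{ct}}{1 + R_{ct} Q (j\omega)^n}.}
#' The semicircle diameter of the Nyquist plot equals \eqn{R_{ct}}, the
#' charge-transfer resistance of the polymer film.
#'
#' @param r_s Solution resistance, ohm (> 0).
#' @param r_ct Charge-transfer resistance, ohm (> 0).
#' @param cpe_q CPE magnitude, S s^n (> 0).
#' @param cpe_n CPE exponent in (0, 1]; 1 is an ideal capacitor.
#' @return A `randles_model` object.
#' @export
randles_model <- function(r_s, r_ct, cpe_q, cpe_n = 0.9) {
  stopifnot(r_s > 0, r_ct > 0, cpe_q > 0, cpe_n > 0, cpe_n <= 1)
  structure(list(r_s = r_s, r_ct = r_ct, cpe_q = cpe_q, cpe_n = cpe_n),
            class = "randles_model")
}

randles_impedance <- function(model, frequency) {
  w <- 2 * pi * frequency
  jw_n <- complex(modulus = w^model$cpe_n,
                  argument = model$cpe_n * pi / 2)
  model$r_s + model$r_ct / (1 + model$r_ct * model$cpe_q * jw_n)
}

#' Simulate a Randles-circuit impedance spectrum
#'
#' @param model A [randles_model()].
#' @param frequencies Frequencies, Hz.
#' @return An [eis_spectrum()] of the noiseless model impedance.
#' @export
simulate_randles <- function(model, frequencies) {
  stopifnot(inherits(model, "randles_model"))
  z <- randles_impedance(model, frequencies)
  eis_spectrum(frequencies, Re(z), Im(z))
}

#' Fit a Randles circuit to an impedance spectrum
#'
#' Complex nonlinear least squares with modulus weighting: minimizes
#' \eqn{\sum |Z_{obs} - Z_{model}|^2 / |Z_{obs}|^2}, the standard choice
#' for spectra spanning decades of impedance magnitude. Parameters are
#' bounded positive (and `cpe_n <= 1`); parameters pinned at a bound are
#' flagged. Asymptotic standard errors come from the Jacobian at the
#' solution.
#'
#' @param spectrum An [eis_spectrum()] with at least 8 points spanning at
#'   least 3 decades of frequency.
#' @param start Optional [randles_model()] initial guess; by default a
#'   heuristic guess is taken from the high- and low-frequency limits and
#'   the semicircle apex.
#' @return A list: `model` ([randles_model()]), `se` (named standard
#'   errors), `residual_norm` (weighted), `converged`, `pinned`
#'   (character vector of parameters at bounds).
#' @export
fit_randles <- function(spectrum, start = NULL) {
  stopifnot(inherits(spectrum, "eis_spectrum"))
  f <- spectrum$frequency
  if (length(f) < 8L) stop("need at least 8 frequency points")
  if (log10(max(f) / min(f)) < 3)
    stop("spectrum must span at least 3 decades of frequency")
  zobs <- complex(real = spectrum$z_real, imaginary = spectrum$z_imag)
  wts <- 1 / Mod(zobs)
  if (is.null(start)) {
    r_s0 <- max(min(spectrum$z_real), 1e-3)
    r_ct0 <- max(max(spectrum$z_real) - r_s0, 1e-3)
    apex <- f[which.max(-spectrum$z_imag)]
    q0 <- 1 / (r_ct0 * 2 * pi * max(apex, min(f)))
    start <- randles_model(r_s0, r_ct0, q0, 0.9)
  }
  lower <- c(1e-9, 1e-9, 1e-15, 0.05)
  upper <- c(1e12, 1e12, 1e3, 1)
  par0 <- pmin(pmax(c(start$r_s, start$r_ct, start$cpe_q, start$cpe_n),
                    lower), upper)
  resid_fn <- function(p) {
    m <- list(r_s = p[1], r_ct = p[2], cpe_q = p[3], cpe_n = p[4])
    zm <- randles_impedance(m, f)
    c(Re(zobs - zm) * wts, Im(zobs - zm) * wts)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  converged <- fit$info %in% 1:4
  resid <- resid_fn(p)
  dof <- max(length(resid) - 4L, 1L)
  s2 <- sum(resid^2) / dof
  jt <- fit$hessian  # J'J from the Levenberg-Marquardt run
  se <- rep(NA_real_, 4)
  # parameters span ~18 orders of magnitude; rescale before inverting
  d <- sqrt(diag(jt))
  ok <- is.finite(d) & d > 0
  if (all(ok)) {
    cov_try <- try(solve(jt / outer(d, d)), silent = TRUE)
    if (!inherits(cov_try, "try-error"))
      se <- sqrt(pmax(diag(cov_try), 0) * s2) / d
  }
  names(se) <- c("r_s", "r_ct", "cpe_q", "cpe_n")
  at_lower <- p <= lower * (1 + 1e-6) + 1e-15
  at_upper <- p >= upper * (1 - 1e-6)
  pinned <- names(se)[at_lower | at_upper]
  if (!converged)
    warning("Randles fit did not converge; final residual norm ",
            format(sqrt(sum(resid^2))))
  list(model = randles_model(max(p[1], 1e-12), max(p[2], 1e-12),
                             max(p[3], 1e-15), min(max(p[4], 1e-6), 1)),
       se = se, residual_norm = sqrt(sum(resid^2)),
       converged = converged, pinned = pinned)
}

#' Polymer film thickness from the electropolymerization charge
#'
#' \deqn{h = \frac{q M}{\rho A n F}} with `q` the charge passed during
#' electropolymerization (C), `M` the monomer molar mass (g/mol),
#' \eqn{\rho} the polymer density (g/cm^3), `A` the electrode geometric
#' area (cm^2), `n` the electrons transferred per monomer and `F` the
#' Faraday constant. The result is returned in nanometres.
#'
#' @param q Charge, C.
#' @param M Monomer molar mass, g/mol (o-PD: 108.14).
#' @param rho Polymer density, g/cm^3 (1.2 is the usual assumption for
#'   poly(o-PD)).
#' @param A Electrode geometric area, cm^2 (a 4.0 mm disc: 0.1257).
#' @param n_electrons Electrons per monomer oxidized.
#' @param faraday Faraday constant, C/mol.
#' @return Film thickness, nm.
#' @examples
#' film_thickness(q = 1.75e-5, M = 108.14, rho = 1.2, A = 0.1257,
#'                n_electrons = 2)
#' @export
film_thickness <- function(q, M, rho = 1.2, A, n_electrons,
                           faraday = 96485) {
  vals <- c(q = q, M = M, rho = rho, A = A, n_electrons = n_electrons,
            faraday = faraday)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all film-thickness inputs must be strictly positive")
  h_cm <- q * M / (rho * A * n_electrons * faraday)
  h_cm * 1e7
}

#' Charge needed for a target film thickness
#'
#' Algebraic inverse of [film_thickness()], useful for planning
#' electropolymerization runs.
#'
#' @param h Film thickness, nm.
#' @inheritParams film_thickness
#' @return Charge, C.
#' @export
charge_for_thickness <- function(h, M, rho = 1.2, A, n_electrons,
                                 faraday = 96485) {
  vals <- c(h = h, M = M, rho = rho, A = A, n_electrons = n_electrons,
            faraday = faraday)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be strictly positive")
  (h / 1e7) * rho * A * n_electrons * faraday / M
}

#' Integrate the polymerization charge from a CV sweep
#'
#' Baseline-corrected trapezoidal integral of the current over the
#' potential window, divided by the scan rate. The baseline is the line
#' through the first and last points of the window (or zero with
#' `baseline = "none"`). Supply a list of sweeps to sum over cycles.
#'
#' @param cv A CV [voltammogram()] (with `scan_rate`), or a list of them.
#' @param window Potential interval `c(lo, hi)`, V.
#' @param baseline `"endpoints"` or `"none"`.
#' @return Charge, C.
#' @export
integrate_polymerization_charge <- function(cv, window = NULL,
                                            baseline = c("endpoints",
                                                         "none")) {
  baseline <- match.arg(baseline)
  if (is.list(cv) && !inherits(cv, "voltammogram")) {
    return(sum(vapply(cv, integrate_polymerization_charge, 0,
                      window = window, baseline = baseline)))
  }
  stopifnot(inherits(cv, "voltammogram"))
  if (cv$technique != "CV" || is.null(cv$scan_rate))
    stop("charge integration needs a CV trace with a scan rate")
  if (cv$scan_rate == 0) stop("zero scan_rate")
  if (is.null(window)) window <- range(cv$potential)
  window <- sort(window)
  sel <- which(cv$potential >= window[1] & cv$potential <= window[2])
  if (length(sel) < 2L) stop("window contains fewer than 2 points")
  E <- cv$potential[sel]; i <- cv$current[sel]
  ord <- order(E); E <- E[ord]; i <- i[ord]
  if (baseline == "endpoints") {
    n <- length(E)
    slope <- (i[n] - i[1]) / (E[n] - E[1])
    i <- i - (i[1] + slope * (E - E[1]))
  }
  sum(diff(E) * (utils::head(i, -1) + utils::tail(i, -1)) / 2) / cv$scan_rate
}

#' Monomer:template mixing ratio of a polymerization recipe
#'
#' Reduces the two concentrations (same units) to the smallest integer
#' ratio, the conventional way imprinting recipes are quoted.
#'
#' @param monomer_conc,template_conc Concentrations in the same unit.
#' @return List with integer `monomer` and `template` parts and a `text`
#'   rendering.
#' @examples
#' monomer_template_ratio(0.5, 2.5)$text  # "1:5"
#' @export
monomer_template_ratio <- function(monomer_conc, template_conc) {
  stopifnot(monomer_conc > 0, template_conc > 0)
  scale <- 10^max(0, -floor(log10(min(monomer_conc, template_conc))) + 6)
  a <- round(monomer_conc * scale)
  b <- round(template_conc * scale)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(a, b)
  list(monomer = a / d, template = b / d,
       text = paste0(a / d, ":", b / d))
}
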