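gaussian_swv <- function(Ep = 0.78, ip = 10e-6, width = 0.05,
                         ramp = c(2e-6, 1e-6), n = 201,
                         range_v = c(0.4, 1.1)) {
  E <- seq(range_v[1], range_v[2], length.out = n)
  i <- ramp[1] + ramp[2] * E + ip * exp(-(E - Ep)^2 / (2 * width^2))
  voltammogram(E, i, "SWV")
}

test_that("SWV peak detection recovers generator truth", {
  v <- gaussian_swv()
  pk <- detect_swv_peak(v, c(0.55, 1.0))
  expect_true(pk$detected)
  expect_lt(abs(pk$Ep - 0.78), 0.002)
  expect_lt(abs(pk$ip - 10e-6), 0.1e-6)
})

test_that("flat traces report no peak, mirroring non-detected entries", {
  E <- seq(0, 1, length.out = 50)
  flat <- voltammogram(E, rep(1e-6, 50), "SWV")
  pk <- detect_swv_peak(flat, c(0.2, 0.8))
  expect_false(pk$detected)
  expect_true(is.na(pk$Ep))
  ramp <- voltammogram(E, 1e-6 + 2e-6 * E, "SWV")
  expect_false(detect_swv_peak(ramp, c(0.2, 0.8))$detected)
})

test_that("two peaks in disjoint windows are recovered independently", {
  E <- seq(0, 1.2, length.out = 481)
  i <- 1e-6 + 15.2e-6 * exp(-(E - 0.78)^2 / (2 * 0.04^2)) +
    23.4e-6 * exp(-(E - 0.554)^2 / (2 * 0.035^2))
  v <- voltammogram(E, i, "SWV")
  p1 <- detect_swv_peak(v, c(0.65, 0.95))
  p2 <- detect_swv_peak(v, c(0.43, 0.67))
  expect_lt(abs(p1$Ep - 0.780), 0.004)
  expect_lt(abs(p2$Ep - 0.554), 0.004)
  expect_lt(abs(p1$ip - 15.2e-6) / 15.2e-6, 0.05)
  expect_lt(abs(p2$ip - 23.4e-6) / 23.4e-6, 0.05)
})

test_that("calibration is exact on noiseless data with the printed preset", {
  x <- c(5, 10, 25, 50, 100) * 1e-6
  y <- 567e-4 * x + 1e-8
  fit <- fit_calibration(x, y)
  expect_equal(fit$slope, 567e-4, tolerance = 1e-12)
  expect_equal(fit$intercept, 1e-8, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 5L)
  # LOD/LOQ ratio is fixed at 3.3:10
  fitn <- fit_calibration(x, y + rnorm(5, 0, 1e-8))
  expect_equal(fitn$loq / fitn$lod, 10 / 3.3, tolerance = 1e-9)
  expect_lt(fitn$lod, fitn$loq)
})

test_that("calibration rejects degenerate designs", {
  expect_error(fit_calibration(c(1e-6, 1e-6), c(1, 2)), "3 distinct")
  expect_error(fit_calibration(c(1, 1, 1) * 1e-6, c(1, 2, 3) * 1e-6),
               "3 distinct")
  expect_error(fit_calibration(c(1, 2, 3) * 1e-6, rep(5e-6, 3)),
               "zero calibration slope")
})

test_that("blank-SD detection limits follow 3.3 s/slope on average", {
  slope <- 567e-4; s_blank <- 2e-8
  lods <- vapply(1:400, function(k) {
    dat <- gen_calibration(slope = slope, intercept = 1e-8,
                           s_blank = s_blank, seed = k)
    fit_calibration(dat$concentration, dat$current,
                    lod_rule = "blank_sd", s_blank = s_blank)$lod
  }, 0)
  expect_lt(abs(mean(lods) - 3.3 * s_blank / slope) /
              (3.3 * s_blank / slope), 0.02)
})

test_that("Randles impedance has the right closed-form limits", {
  m <- randles_model(r_s = 100, r_ct = 2820, cpe_q = 2e-6, cpe_n = 1)
  hi <- simulate_randles(m, 10^seq(9, 5))
  expect_equal(hi$z_real[1], 100, tolerance = 1e-3)
  lo <- simulate_randles(m, 10^seq(-3, -7))
  expect_equal(lo$z_real[5], 2920, tolerance = 1e-3)
  # ideal capacitor: -Im(Z) peaks at omega = 1/(r_ct cpe_q)
  f_apex <- 1 / (m$r_ct * m$cpe_q) / (2 * pi)
  f <- 10^seq(log10(f_apex) - 3, log10(f_apex) + 3, length.out = 6001)
  sp <- simulate_randles(m, f)
  apex <- sp$frequency[which.max(-sp$z_imag)]
  expect_equal(apex / f_apex, 1, tolerance = 1e-3)
})

test_that("Randles fit inverts noiseless simulation to high precision", {
  truth <- randles_model(r_s = 150, r_ct = 2820, cpe_q = 3.2e-6,
                         cpe_n = 0.88)
  sp <- gen_eis(truth, noise_fraction = 0, seed = 1)
  fit <- fit_randles(sp)
  expect_true(fit$converged)
  expect_equal(fit$model$r_s, truth$r_s, tolerance = 1e-6)
  expect_equal(fit$model$r_ct, truth$r_ct, tolerance = 1e-6)
  expect_equal(fit$model$cpe_q, truth$cpe_q, tolerance = 1e-6)
  expect_equal(fit$model$cpe_n, truth$cpe_n, tolerance = 1e-6)
  expect_length(fit$pinned, 0L)
})

test_that("a pure-resistor spectrum pins r_ct at its bound and is flagged", {
  f <- 10^seq(5, 0, length.out = 26)
  sp <- eis_spectrum(f, rep(500, 26), rep(0, 26))
  fit <- suppressWarnings(fit_randles(sp))
  expect_true("r_ct" %in% fit$pinned || "cpe_q" %in% fit$pinned)
})

test_that("film thickness follows Eq.-style scaling and inverts exactly", {
  h0 <- film_thickness(q = 2e-5, M = 108.14, rho = 1.2, A = 0.1257,
                       n_electrons = 2)
  expect_equal(film_thickness(q = 4e-5, M = 108.14, rho = 1.2, A = 0.1257,
                              n_electrons = 2), 2 * h0, tolerance = 1e-12)
  expect_equal(film_thickness(q = 2e-5, M = 108.14, rho = 2.4, A = 0.1257,
                              n_electrons = 2), h0 / 2, tolerance = 1e-12)
  # algebraic inversion: the charge that gives h = 13 nm reproduces 13 nm
  q13 <- charge_for_thickness(13, M = 108.14, rho = 1.2, A = 0.1257,
                              n_electrons = 2)
  expect_equal(film_thickness(q = q13, M = 108.14, rho = 1.2, A = 0.1257,
                              n_electrons = 2), 13, tolerance = 1e-12)
  expect_error(film_thickness(q = -1, M = 108.14, rho = 1.2, A = 0.1,
                              n_electrons = 2), "positive")
})

test_that("polymerization charge integrates pulses and Gaussian peaks", {
  # rectangular 1 uA pulse over 0.1 V at 0.05 V/s -> 2 uC
  E <- seq(0, 0.5, by = 0.001)
  i <- ifelse(E >= 0.2 & E <= 0.3, 1e-6, 0)
  cv <- voltammogram(E, i, "CV", scan_rate = 0.05)
  q <- integrate_polymerization_charge(cv, c(0.1, 0.4), baseline = "none")
  expect_equal(q, 2e-6, tolerance = 1e-2)
  # zero-current trace integrates to zero
  cv0 <- voltammogram(E, rep(0, length(E)), "CV", scan_rate = 0.05)
  expect_equal(integrate_polymerization_charge(cv0), 0)
  # Gaussian anodic peak with known area, on a linear background the
  # endpoint baseline removes
  area <- 5e-7  # A V
  ig <- 1e-7 + 2e-7 * E + area / (0.03 * sqrt(2 * pi)) *
    exp(-(E - 0.25)^2 / (2 * 0.03^2))
  cvg <- voltammogram(E, ig, "CV", scan_rate = 0.05)
  qg <- integrate_polymerization_charge(cvg, c(0.05, 0.45))
  expect_equal(qg, area / 0.05, tolerance = 5e-3)
  # cycles sum
  expect_equal(integrate_polymerization_charge(list(cvg, cvg), c(0.05, 0.45)),
               2 * qg, tolerance = 1e-12)
})

test_that("the optimal recipe reduces to a 1:5 monomer:template ratio", {
  r <- monomer_template_ratio(0.5, 2.5)
  expect_equal(r$monomer, 1)
  expect_equal(r$template, 5)
  expect_equal(r$text, "1:5")
  expect_equal(monomer_template_ratio(0.25, 7.5)$text, "1:30")
})
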