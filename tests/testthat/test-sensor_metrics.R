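# Readout proxies, RMSE machinery, calibration metrics, sensitivity table.

test_that("absorbance proxy: zero input, band-centre maximum, monotone response", {
  z <- absorbance_spectra(0)
  expect_true(all(z$absorbance == 0))

  sp <- absorbance_spectra(c(0.01, 0.05), center = 652)
  imax <- apply(sp$absorbance, 2, which.max)
  expect_true(all(abs(sp$wavelengths[imax] - 652) <= 2))
  expect_error(absorbance_spectra(-1), "nonnegative")

  # band-centre absorbance strictly increasing across preset concentrations
  cfg <- preset_cfg()
  g <- small_grid()
  cons <- vapply(c(0.5, 5, 10), function(cb)
    solve_colorimetric_coupled(cfg, cb, g)$h2o2$J_eff, 0) * 2400
  sp <- absorbance_spectra(cons, labels = c(0.5, 5, 10))
  peaks <- apply(sp$absorbance, 2, max)
  expect_true(all(diff(peaks) > 0))
})

test_that("spectral RMSE: metric properties, closed forms, brute-force oracle", {
  wl <- seq(500, 800, by = 3)
  mk <- function(A) structure(list(wavelengths = wl, absorbance = A),
                              class = "spectrum_set")
  set.seed(3)
  A <- matrix(runif(length(wl) * 3), ncol = 3)
  B <- A + matrix(rnorm(length(A), sd = 0.05), ncol = 3)
  expect_equal(rmse_spectra(mk(A), mk(A)), 0)
  expect_equal(rmse_spectra(mk(A), mk(A + 0.37)), 0.37, tolerance = 1e-12)
  # brute-force loop-summed oracle
  acc <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    acc <- acc + (A[i, j] - B[i, j])^2
  expect_equal(rmse_spectra(mk(A), mk(B)), sqrt(acc / length(A)),
               tolerance = 1e-12)
  expect_equal(rmse_spectra(mk(A), mk(B)), rmse_spectra(mk(B), mk(A)))
  expect_gt(rmse_spectra(mk(A), mk(B)), 0)
  expect_error(rmse_spectra(mk(A), structure(list(wavelengths = wl + 1, absorbance = A),
                                             class = "spectrum_set")),
               "identical wavelength")
})

test_that("amperometric current is the Faradaic conversion of the effective flux", {
  expect_equal(amperometric_current(0), 0)
  expect_equal(amperometric_current(1e-6, n = 2, electrode_area = 1e-4),
               2 * 96485 * 1e-4 * 1e-6)
  expect_equal(amperometric_current(1e-6, electrode_area = 3e-4),
               3 * amperometric_current(1e-6, electrode_area = 1e-4))
})

test_that("calibration metrics: exact LOD on a linear curve, MM deviation point, scalings", {
  C <- exp(seq(log(0.001), log(20), length.out = 400))
  lin <- data.frame(C = C, signal = 4.2 * C)
  m <- calibration_metrics(lin, sigma_blank = 0.021)
  expect_equal(m$LOD_uM, 3 * 0.021 / 4.2 * 1e3, tolerance = 1e-12)
  expect_equal(m$linear_range_upper_mM, max(C))

  Km <- 2.5
  mm <- data.frame(C = C, signal = C / (Km + C))
  m2 <- calibration_metrics(mm, sigma_blank = 1e-4)
  # slope comes from the finite low-concentration points, so the crossing
  # carries a small bias relative to the exact tangent result Km/19
  expect_equal(m2$linear_range_upper_mM, Km / 19, tolerance = 1e-2)

  # LOD inversely proportional to slope, linear in sigma
  m3 <- calibration_metrics(data.frame(C = C, signal = 8.4 * C), sigma_blank = 0.021)
  expect_equal(m3$LOD_uM, m$LOD_uM / 2, tolerance = 1e-10)
  m4 <- calibration_metrics(lin, sigma_blank = 0.042)
  expect_equal(m4$LOD_uM, 2 * m$LOD_uM, tolerance = 1e-10)
  expect_error(calibration_metrics(data.frame(C = C, signal = -C), 0.1),
               "slope")
})

test_that("sensitivity sweep: structure, uniform degenerate cell, loading trend", {
  cfg <- preset_cfg()
  g <- small_grid(nx = 20, ny = 60)
  sens <- sensitivity_sweep(cfg, g)
  expect_equal(nrow(sens), 15)          # five parameters, three variations each
  expect_true(all(is.na(sens$error)))

  base <- sens[sens$variation_pct == 0, ][1, ]
  # removing the heterogeneity recovers the intrinsic Michaelis constant,
  # and the cell equals the 1D pipeline run directly
  a0 <- sens[sens$parameter == "A_gamma" & sens$variation_pct == -100, ]
  expect_equal(a0$Km_eff_mM, cfg$kinetics$Km, tolerance = 1e-5)
  cfg_u <- uniform_cfg()
  sw1 <- sweep_steady(cfg_u, g, "1d")
  f1 <- fit_effective_mm(data.frame(C_s = sw1$C_eff_s, J = sw1$J_eff))
  expect_equal(a0$Km_eff_mM, f1$Km_eff, tolerance = 1e-6)

  # baseline LOD reproduces its calibration target exactly
  expect_equal(base$LOD_uM, 1.37, tolerance = 1e-9)
  # higher catalyst loading lowers the detection limit
  up <- sens[sens$parameter == "Gamma_mean" & sens$variation_pct == 50, ]
  dn <- sens[sens$parameter == "Gamma_mean" & sens$variation_pct == -50, ]
  expect_lt(up$LOD_uM, base$LOD_uM)
  expect_gt(dn$LOD_uM, base$LOD_uM)
})
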