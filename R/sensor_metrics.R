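# Sensor-level readouts: colorimetric absorbance proxy, RMSE validation
# machinery, amperometric current, calibration metrics (LOD, linear range)
# and the one-at-a-time parameter sensitivity sweep.

#' Colorimetric absorbance proxy spectra
#'
#' Proxy for the chromogen (oxTMB) signal: the cumulative peroxide
#' consumption per unit area over the incubation window maps linearly onto a
#' Gaussian absorbance band centred near 652 nm. This is plumbing for
#' validation workflows, not a mechanistic chromophore model: it preserves
#' the monotone increase of the band-centre absorbance with glucose
#' concentration and the single-band spectral shape.
#'
#' @param consumed Cumulative peroxide consumed per concentration
#'   (mol m^-2), nonnegative.
#' @param wavelengths Wavelength grid (nm).
#' @param center,width Band centre and Gaussian width (nm).
#' @param scale Absorbance per consumed amount (AU per mol m^-2).
#' @param labels Optional concentration labels for the columns.
#' @return A list of class `"spectrum_set"`: `wavelengths`, matrix
#'   `absorbance` (rows = wavelengths), band parameters.
#' @export
absorbance_spectra <- function(consumed, wavelengths = seq(450, 850, by = 2),
                               center = 652, width = 30, scale = 15,
                               labels = NULL) {
  if (any(consumed < 0)) stop("consumed amounts must be nonnegative", call. = FALSE)
  band <- exp(-(wavelengths - center)^2 / (2 * width^2))
  A <- outer(band, scale * consumed)
  colnames(A) <- if (!is.null(labels)) as.character(labels) else NULL
  structure(list(wavelengths = wavelengths, absorbance = A,
                 center = center, width = width, scale = scale,
                 consumed = consumed),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d wavelengths x %d spectra, band %g nm (width %g)\n",
              length(x$wavelengths), ncol(x$absorbance), x$center, x$width))
  cat(sprintf("  band-centre absorbance: %s\n",
              paste(sprintf("%.4g", apply(x$absorbance, 2, max)), collapse = ", ")))
  invisible(x)
}

#' Root-mean-square error between two spectrum sets
#'
#' `sqrt(mean((A_sim - A_ref)^2))` over all wavelength points (and spectra).
#'
#' @param sim,ref `"spectrum_set"` objects on identical wavelength grids.
#' @return RMSE (absorbance units).
#' @export
rmse_spectra <- function(sim, ref) {
  if (!isTRUE(all.equal(sim$wavelengths, ref$wavelengths)) ||
      !all(dim(sim$absorbance) == dim(ref$absorbance)))
    stop("spectrum sets are not on identical wavelength grids", call. = FALSE)
  sqrt(mean((sim$absorbance - ref$absorbance)^2))
}

#' Amperometric current from the effective electrooxidation flux
#'
#' `i = n F A J_eff`: Faradaic conversion of the laterally averaged glucose
#' electrooxidation flux into a chronoamperometric current.
#'
#' @param J_eff Effective areal flux (mol m^-2 s^-1).
#' @param n Electrons per molecule (default 2).
#' @param F_const Faraday constant (C mol^-1).
#' @param electrode_area Electrode area (m^2; default 1 cm^2 = 1e-4 m^2).
#' @return Current (A).
#' @examples
#' amperometric_current(1e-6)  # 1.93e-5 A over 1 cm^2
#' @export
amperometric_current <- function(J_eff, n = 2, F_const = 96485,
                                 electrode_area = 1e-4) {
  if (any(J_eff < 0) || electrode_area < 0) stop("inputs must be nonnegative", call. = FALSE)
  n * F_const * electrode_area * J_eff
}

#' Calibration metrics: detection limit and linear range
#'
#' Standard analytical-chemistry conventions: the low-concentration
#' sensitivity is the through-origin slope over the `n_low` lowest
#' concentrations; `LOD = 3 sigma_blank / slope` (reported in uM); the upper
#' linear-range limit is the smallest concentration at which the response
#' deviates from that line by more than `dev_tol` (relative, default 5%),
#' located by interpolation of the deviation and capped at the largest
#' simulated concentration.
#'
#' @param curve Data frame with columns `C` (mM) and `signal`.
#' @param sigma_blank Blank noise, in signal units.
#' @param n_low Number of low-concentration points for the sensitivity fit.
#' @param dev_tol Relative deviation defining departure from linearity.
#' @return A list of class `"sensor_readout"`: `LOD_uM`,
#'   `linear_range_upper_mM`, `sensitivity` (signal per mM), the fitted line
#'   and deviations.
#' @export
calibration_metrics <- function(curve, sigma_blank, n_low = 3, dev_tol = 0.05) {
  stopifnot(all(c("C", "signal") %in% names(curve)), nrow(curve) >= 8)
  o <- order(curve$C); C <- curve$C[o]; s <- curve$signal[o]
  if (any(C <= 0)) stop("concentrations must be positive", call. = FALSE)
  low <- seq_len(min(n_low, length(C)))
  slope <- sum(s[low] * C[low]) / sum(C[low]^2)   # through-origin LS fit
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope; no detection limit defined", call. = FALSE)
  dev <- 1 - s / (slope * C)                       # sublinear deviation
  adev <- abs(dev)
  above <- which(adev > dev_tol)
  upper <- if (!length(above)) max(C) else {
    j <- above[1]
    if (j == 1) C[1] else {
      # interpolate the |deviation| = dev_tol crossing in concentration
      C[j - 1] + (dev_tol - adev[j - 1]) * (C[j] - C[j - 1]) / (adev[j] - adev[j - 1])
    }
  }
  structure(list(LOD_uM = 3 * sigma_blank / slope * 1e3,
                 linear_range_upper_mM = min(upper, max(C)),
                 sensitivity = slope, sigma_blank = sigma_blank,
                 deviation = dev, curve = data.frame(C = C, signal = s)),
            class = "sensor_readout")
}

#' @export
print.sensor_readout <- function(x, ...) {
  cat(sprintf("<sensor_readout> LOD = %.4g uM, linear range up to %.4g mM, sensitivity %.5g per mM\n",
              x$LOD_uM, x$linear_range_upper_mM, x$sensitivity))
  invisible(x)
}

# response signal for calibration: the effective analyte turnover flux,
# which both readout modes transduce (current ~ J_eff; colour development
# rate ~ peroxide production ~ consumption at steady state)
calibration_curve <- function(cfg, grid, C_bulk_list = cfg$C_bulk_list) {
  sw <- sweep_steady(cfg, grid, "2d", C_bulk_list)
  data.frame(C = sw$C_bulk, signal = sw$J_eff)
}

#' Calibrate the blank noise to a target baseline detection limit
#'
#' The model predicts signals, not instrument noise; `sigma_blank` is the one
#' free readout parameter. It is set once so that the baseline scenario
#' reproduces a stated detection limit, after which all sensitivity
#' variations share the same noise level and their LOD shifts are genuine
#' model predictions.
#'
#' @param baseline_curve Data frame with `C`, `signal` for the baseline.
#' @param lod_target_uM Target LOD of the baseline (uM).
#' @param n_low Points in the low-concentration sensitivity fit.
#' @return `sigma_blank` in signal units.
#' @export
calibrate_sigma_blank <- function(baseline_curve, lod_target_uM = 1.37, n_low = 3) {
  o <- order(baseline_curve$C)
  C <- baseline_curve$C[o]; s <- baseline_curve$signal[o]
  low <- seq_len(min(n_low, length(C)))
  slope <- sum(s[low] * C[low]) / sum(C[low]^2)
  lod_target_uM * 1e-3 * slope / 3
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Reruns the full steady pipeline (concentration sweep, apparent-kinetics
#' fit, calibration metrics) for the standard variation grid: mean site
#' density +/-50%, heterogeneity amplitude -100%/+50%, Michaelis constant
#' +/-50%, maximal turnover +/-50%, glucose diffusivity +/-50%. The blank
#' noise is calibrated once on the baseline cell ([calibrate_sigma_blank()])
#' and shared by all cells, so relative LOD and linear-range shifts are model
#' predictions.
#'
#' @param cfg Baseline [scenario()] (the calibrated preset by default).
#' @param grid A [grid_2d()] used for every cell.
#' @param lod_target_uM Baseline detection limit used to fix the blank noise.
#' @param C_bulk_list Concentration sweep per cell.
#' @return A data frame of class `"sensitivity_sweep"` with one row per
#'   (parameter, variation): `Km_eff_mM`, `LOD_uM`, `linear_range_upper_mM`,
#'   plus fit and error diagnostics. Solver failures in a cell are recorded
#'   in the `error` column and leave the other cells intact.
#' @export
sensitivity_sweep <- function(cfg = scenario(),
                              grid = grid_2d(cfg$transport$L, cfg$transport$H),
                              lod_target_uM = 1.37,
                              C_bulk_list = cfg$C_bulk_list) {
  vary <- list(
    Gamma_mean = c(-50, 0, 50),
    A_gamma    = c(-100, 0, 50),
    Km         = c(-50, 0, 50),
    Vmax       = c(-50, 0, 50),
    D_Glu      = c(-50, 0, 50)
  )
  make_cfg <- function(param, pct) {
    f <- 1 + pct / 100
    kin <- cfg$kinetics; tr <- cfg$transport
    if (param == "Gamma_mean") kin$Gamma_mean <- kin$Gamma_mean * f
    if (param == "A_gamma")    kin$A_gamma <- kin$A_gamma * f
    if (param == "Km")         kin$Km <- kin$Km * f
    if (param == "Vmax") { kin$Vmax <- kin$Vmax * f; kin$Vmax_el <- kin$Vmax_el * f }
    if (param == "D_Glu")      tr$D_glu <- tr$D_glu * f
    scenario(transport = do.call(transport_params, tr[c("D_glu", "D_h2o2", "H", "L")]),
             kinetics = do.call(surface_kinetics,
                                kin[c("Km", "Vmax", "Gamma_mean", "A_gamma",
                                      "lambda_het", "phase", "kGOD", "delta_enz",
                                      "Km_el", "Vmax_el")]),
             mode = cfg$mode, C_bulk_list = C_bulk_list,
             sim_time = cfg$sim_time, seed = cfg$seed)
  }
  run_cell <- function(cfg_i) {
    curve <- calibration_curve(cfg_i, grid, C_bulk_list)
    sw2 <- sweep_steady(cfg_i, grid, "2d", C_bulk_list)
    fit <- fit_effective_mm(data.frame(C_s = sw2$C_eff_s, J = sw2$J_eff))
    list(curve = curve, Km_eff = fit$Km_eff, Vmax_eff = fit$Vmax_eff)
  }
  base <- run_cell(cfg)
  sigma <- calibrate_sigma_blank(base$curve, lod_target_uM)
  metric_row <- function(cell) {
    m <- calibration_metrics(cell$curve, sigma)
    c(Km_eff_mM = unname(cell$Km_eff),
      LOD_uM = m$LOD_uM, linear_range_upper_mM = m$linear_range_upper_mM)
  }
  base_m <- metric_row(base)
  rows <- list()
  for (param in names(vary)) for (pct in vary[[param]]) {
    if (pct == 0) {
      rows[[length(rows) + 1]] <- data.frame(parameter = param, variation_pct = 0,
                                             t(base_m), error = NA_character_)
      next
    }
    res <- tryCatch({
      cell <- run_cell(make_cfg(param, pct))
      data.frame(parameter = param, variation_pct = pct, t(metric_row(cell)),
                 error = NA_character_)
    }, error = function(e)
      data.frame(parameter = param, variation_pct = pct, Km_eff_mM = NA_real_,
                 LOD_uM = NA_real_, linear_range_upper_mM = NA_real_,
                 error = conditionMessage(e)))
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma_blank") <- sigma
  class(out) <- c("sensitivity_sweep", class(out))
  out
}
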