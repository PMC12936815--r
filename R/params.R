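# Scenario configuration: transport, kinetics, heterogeneity, calibration.
#
# Unit conventions used throughout the package:
#   concentrations  mM  (numerically identical to mol m^-3)
#   lengths         m
#   areal fluxes    mol m^-2 s^-1  (= mM * m/s with the above conventions)
#   site densities  mol cm^-2 (metadata; the solvers work with the calibrated
#                   areal rate scale, see `scenario()` details)

# Table-style default parameter set. Kept in one place so constructors,
# calibration and the sensitivity sweep all refer to the same baseline.
.defaults <- list(
  D_glu = 6.7e-10, D_h2o2 = 1.5e-9, H = 100e-6, L = 10e-6,
  Km = 2.5, Vmax = 1.2e5, Gamma_mean = 1.2e-9, A_gamma = 0.5,
  kGOD = 0.015, Km_el = 3.8, Vmax_el = 8.5e4,
  E_op = 0.7, T = 310,
  # calibration anchors for the preset (see vignette): the 1D steady surface
  # glucose ratio and the 1D steady near-surface peroxide peak, both at 10 mM
  anchor_C_bulk = 10, anchor_surface_ratio = 0.17, anchor_peak_ratio = 0.05
)

#' Transport parameter set
#'
#' Diffusivities of the two tracked species and the geometry of the quiescent
#' diffusion layer above the catalytic plane.
#'
#' @param D_glu Glucose diffusivity (m^2 s^-1).
#' @param D_h2o2 Hydrogen-peroxide diffusivity (m^2 s^-1).
#' @param H Diffusion-layer thickness (m); the bulk reservoir sits at `y = H`.
#' @param L Lateral domain length (m), one representative surface segment.
#' @return A list of class `"transport_params"`.
#' @examples
#' transport_params()          # quiescent-assay defaults
#' transport_params(H = 50e-6) # thinner boundary layer
#' @export
transport_params <- function(D_glu = .defaults$D_glu, D_h2o2 = .defaults$D_h2o2,
                             H = .defaults$H, L = .defaults$L) {
  p <- list(D_glu = D_glu, D_h2o2 = D_h2o2, H = H, L = L)
  stop_if_violations(validate_transport(p))
  structure(p, class = "transport_params")
}

validate_transport <- function(p) {
  v <- character()
  for (f in c("D_glu", "D_h2o2", "H", "L"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) || p[[f]] <= 0)
      v <- c(v, sprintf("transport$%s must be a single strictly positive number", f))
  if (!length(v) && p$H < p$L / 1000)
    v <- c(v, "transport$H must be at least L/1000")
  v
}

#' Surface kinetics and heterogeneity parameter set
#'
#' Intrinsic Michaelis-Menten constants of the peroxidase-like surface, the
#' first-order glucose-oxidase source, and the sinusoidal description of
#' lateral catalyst (site-density) heterogeneity.
#'
#' @param Km Intrinsic Michaelis constant, colorimetric rate law (mM).
#' @param Vmax Maximum turnover per site, colorimetric (s^-1). Enters the
#'   solvers only through the calibrated areal rate scale (see [scenario()]).
#' @param Gamma_mean Mean catalytic site density (mol cm^-2).
#' @param A_gamma Relative amplitude of the sinusoidal site-density modulation
#'   (0 = uniform surface, 1 = density touching zero).
#' @param lambda_het Heterogeneity wavelength (m). `NULL` means one full period
#'   across the lateral domain (`lambda_het = L`).
#' @param phase Phase of the modulation (radians). The default 0 puts extrema
#'   at the lateral walls, consistent with the no-flux boundaries.
#' @param kGOD Effective first-order glucose-oxidase rate constant (s^-1).
#' @param delta_enz Effective conversion-layer thickness for the enzymatic
#'   source (m). `NULL` means calibrated from the 1D peroxide-peak anchor;
#'   see [preset_enzyme_layer()].
#' @param Km_el,Vmax_el Electrochemical-mode Michaelis constant (mM) and
#'   turnover (s^-1).
#' @return A list of class `"surface_kinetics"`.
#' @export
surface_kinetics <- function(Km = .defaults$Km, Vmax = .defaults$Vmax,
                             Gamma_mean = .defaults$Gamma_mean,
                             A_gamma = .defaults$A_gamma,
                             lambda_het = NULL, phase = 0,
                             kGOD = .defaults$kGOD, delta_enz = NULL,
                             Km_el = .defaults$Km_el, Vmax_el = .defaults$Vmax_el) {
  p <- list(Km = Km, Vmax = Vmax, Gamma_mean = Gamma_mean, A_gamma = A_gamma,
            lambda_het = lambda_het, phase = phase, kGOD = kGOD,
            delta_enz = delta_enz, Km_el = Km_el, Vmax_el = Vmax_el)
  stop_if_violations(validate_kinetics(p))
  structure(p, class = "surface_kinetics")
}

validate_kinetics <- function(p) {
  v <- character()
  pos <- c("Km", "Vmax", "Gamma_mean", "kGOD", "Km_el", "Vmax_el")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) || p[[f]] < 0)
      v <- c(v, sprintf("kinetics$%s must be a single nonnegative number", f))
  if (!is.numeric(p$A_gamma) || length(p$A_gamma) != 1 || is.na(p$A_gamma) ||
      p$A_gamma < 0 || p$A_gamma > 1)
    v <- c(v, "kinetics$A_gamma must lie in [0, 1]: amplitudes above 1 imply negative site density")
  if (!is.null(p$lambda_het) && (!is.numeric(p$lambda_het) || p$lambda_het <= 0))
    v <- c(v, "kinetics$lambda_het must be strictly positive (or NULL for one period per domain)")
  if (!is.null(p$delta_enz) && (!is.numeric(p$delta_enz) || p$delta_enz <= 0))
    v <- c(v, "kinetics$delta_enz must be strictly positive (or NULL to use the calibrated preset)")
  if (p$Km <= 0) v <- c(v, "kinetics$Km must be strictly positive")
  if (p$Km_el <= 0) v <- c(v, "kinetics$Km_el must be strictly positive")
  v
}

#' Preset areal rate scale from the surface-depletion anchor
#'
#' The dimensional per-site turnover and site density, taken literally,
#' give a maximal areal rate (`Vmax * Gamma_mean` ~ 1.4 mol m^-2 s^-1) whose
#' Damkoehler number (~1e8) would deplete surface glucose to ~1e-8 of bulk --
#' orders of magnitude away from the mild depletion the model is meant to
#' describe. The working rate scale is therefore anchored: the maximal areal
#' rate `J_max` is chosen so that the uniform 1D steady model gives a surface
#' glucose ratio `C_s / C_bulk = 0.17` at `C_bulk = 10` mM, via the closed-form
#' flux balance `(D/H)(C_b - C_s) = J_max C_s / (Km + C_s)`.
#'
#' @return Maximal areal reaction rate at mean site density (mol m^-2 s^-1).
#' @seealso [preset_enzyme_layer()], [dimensionless_groups()]
#' @export
preset_areal_rate <- function() {
  d <- .defaults
  k0 <- d$D_glu / d$H
  Cs <- d$anchor_surface_ratio * d$anchor_C_bulk
  k0 * (d$anchor_C_bulk - Cs) * (d$Km + Cs) / Cs
}

#' Preset enzyme-layer thickness from the peroxide-peak anchor
#'
#' The glucose-oxidase source enters as an areal flux
#' `kGOD * delta_enz * C_glu,s`; `delta_enz` is the effective thickness of the
#' enzymatic conversion layer. Its preset value is calibrated so that the
#' uniform 1D steady model yields a near-surface peroxide peak of
#' `0.05 * C_bulk` at 10 mM bulk glucose: with a linear peroxide profile and a
#' zero top boundary the balance reads
#' `kGOD * delta_enz * C_glu,s = J_max Cp/(Km + Cp) + (D_p/H) Cp`.
#'
#' @return Effective enzyme-layer thickness (m).
#' @export
preset_enzyme_layer <- function() {
  d <- .defaults
  Cs <- d$anchor_surface_ratio * d$anchor_C_bulk
  Cp <- d$anchor_peak_ratio * d$anchor_C_bulk
  Jm <- preset_areal_rate()
  (Jm * Cp / (d$Km + Cp) + d$D_h2o2 / d$H * Cp) / (d$kGOD * Cs)
}

#' Scenario configuration
#'
#' Bundles transport, kinetics, detection mode and the simulated bulk
#' concentration sweep into a single validated object, and derives the
#' calibrated quantities the solvers consume:
#'
#' * `j_max` -- maximal areal rate at mean site density (mol m^-2 s^-1),
#'   `preset_areal_rate()` scaled by `(Gamma_mean / Gamma_0) * (Vmax / Vmax_0)`
#'   so that loading and turnover variations act proportionally;
#' * `j_max_el` -- the electrochemical analogue, scaled by `Vmax_el`;
#' * `delta_enz` -- enzyme-layer thickness, calibrated unless given;
#' * `da_glu`, `da_p` -- Damkoehler numbers (see [dimensionless_groups()]).
#'
#' Operating potential `E_op` and temperature `T` appear in no governing
#' equation of the model; they are carried as metadata only.
#'
#' @param transport A [transport_params()] object.
#' @param kinetics A [surface_kinetics()] object.
#' @param mode `"colorimetric"` (peroxidase pathway, glucose consumed with the
#'   colorimetric rate law) or `"electrochemical"` (direct electrooxidation,
#'   `Km_el`/`Vmax_el` active).
#' @param C_bulk_list Bulk glucose concentrations for sweeps (mM); default a
#'   12-point log-spaced sweep over 0.01-12 mM.
#' @param sim_time Transient horizon (s).
#' @param E_op Operating potential (V), metadata.
#' @param T Temperature (K), metadata.
#' @param seed Integer seed for stochastic fixtures (solvers are deterministic).
#' @return A list of class `"scenario"`.
#' @examples
#' cfg <- scenario()                      # calibrated preset
#' cfg$da_glu                             # ~8.2
#' cfg1d <- scenario(kinetics = surface_kinetics(A_gamma = 0))
#' @export
scenario <- function(transport = transport_params(),
                     kinetics = surface_kinetics(),
                     mode = c("colorimetric", "electrochemical"),
                     C_bulk_list = default_sweep(),
                     sim_time = 400, E_op = .defaults$E_op, T = .defaults$T,
                     seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(transport = transport, kinetics = kinetics, mode = mode,
              C_bulk_list = C_bulk_list, sim_time = sim_time,
              E_op = E_op, T = T, seed = as.integer(seed))
  stop_if_violations(validate_scenario(cfg))
  if (is.null(cfg$kinetics$lambda_het)) cfg$kinetics$lambda_het <- transport$L
  d <- .defaults
  scale_col <- (kinetics$Gamma_mean / d$Gamma_mean) * (kinetics$Vmax / d$Vmax)
  scale_el  <- (kinetics$Gamma_mean / d$Gamma_mean) * (kinetics$Vmax_el / d$Vmax)
  cfg$j_max    <- preset_areal_rate() * scale_col
  cfg$j_max_el <- preset_areal_rate() * scale_el
  if (is.null(cfg$kinetics$delta_enz)) cfg$kinetics$delta_enz <- preset_enzyme_layer()
  cfg$da_glu <- cfg$j_max * transport$H / (transport$D_glu * kinetics$Km)
  cfg$da_p   <- cfg$da_glu * transport$D_glu / transport$D_h2o2
  structure(cfg, class = "scenario")
}

#' Default bulk-concentration sweep (12 points, log-spaced, 0.01-12 mM)
#' @return Numeric vector of bulk glucose concentrations (mM).
#' @export
default_sweep <- function() exp(seq(log(0.01), log(12), length.out = 12))

validate_scenario <- function(cfg) {
  v <- c(validate_transport(cfg$transport), validate_kinetics(cfg$kinetics))
  cb <- cfg$C_bulk_list
  if (!is.numeric(cb) || length(cb) == 0)
    v <- c(v, "C_bulk_list must be a nonempty numeric vector")
  else if (any(!is.finite(cb)) || any(cb <= 0) || any(cb > 50))
    v <- c(v, "C_bulk_list entries must lie in (0, 50] mM")
  if (!is.numeric(cfg$sim_time) || cfg$sim_time <= 0)
    v <- c(v, "sim_time must be strictly positive")
  if (!cfg$mode %in% c("colorimetric", "electrochemical"))
    v <- c(v, "mode must be 'colorimetric' or 'electrochemical'")
  v
}

stop_if_violations <- function(v) {
  if (length(v))
    stop("invalid configuration:\n", paste0("  - ", v, collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}

# Rate law active for glucose under the scenario's detection mode:
# list(j_max, Km) in areal units.
active_rate_params <- function(cfg) {
  if (cfg$mode == "electrochemical")
    list(j_max = cfg$j_max_el, Km = cfg$kinetics$Km_el)
  else
    list(j_max = cfg$j_max, Km = cfg$kinetics$Km)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> pseudo-2D nanozyme biosensor model\n")
  cat(sprintf("  mode        : %s\n", x$mode))
  cat(sprintf("  domain      : L = %.3g um, H = %.3g um\n",
              x$transport$L * 1e6, x$transport$H * 1e6))
  cat(sprintf("  diffusion   : D_glu = %.3g, D_h2o2 = %.3g m^2/s\n",
              x$transport$D_glu, x$transport$D_h2o2))
  cat(sprintf("  kinetics    : Km = %.3g mM, j_max = %.4g mol m^-2 s^-1 (Da = %.3f)\n",
              x$kinetics$Km, x$j_max, x$da_glu))
  cat(sprintf("  heterogeneity: A = %.2f, lambda = %.3g um, phase = %.2f rad\n",
              x$kinetics$A_gamma, x$kinetics$lambda_het * 1e6, x$kinetics$phase))
  cat(sprintf("  GOD source  : kGOD = %.3g /s, delta_enz = %.4g m\n",
              x$kinetics$kGOD, x$kinetics$delta_enz))
  cat(sprintf("  sweep       : %d points, %.3g-%.3g mM\n",
              length(x$C_bulk_list), min(x$C_bulk_list), max(x$C_bulk_list)))
  invisible(x)
}
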