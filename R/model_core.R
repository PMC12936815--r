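# Local rate laws, heterogeneity profile, dimensionless groups and the
# pseudo-2D validity calculator.

#' Sinusoidal catalytic site-density profile
#'
#' `Gamma(x) = Gamma_mean * (1 + A_gamma * cos(2 pi x / lambda_het + phase))`.
#' With the default zero phase the profile has zero slope at both lateral
#' walls, consistent with the no-flux boundary conditions.
#'
#' @param x Lateral coordinates (m), within `[0, L]`.
#' @param kin A [surface_kinetics()] object (or a [scenario()], whose kinetics
#'   are used); `lambda_het = NULL` is resolved to `L` when a scenario is given.
#' @return Site density at `x` (mol cm^-2), nonnegative for `A_gamma <= 1`.
#' @examples
#' kin <- surface_kinetics(A_gamma = 0.5, lambda_het = 10e-6)
#' gamma_profile(c(0, 2.5e-6, 5e-6), kin)
#' @export
gamma_profile <- function(x, kin) {
  if (inherits(kin, "scenario")) kin <- kin$kinetics
  lam <- kin$lambda_het
  if (is.null(lam))
    stop("lambda_het is NULL; supply it or pass a full scenario()", call. = FALSE)
  if (kin$A_gamma > 1)
    stop("A_gamma > 1 implies negative site density", call. = FALSE)
  kin$Gamma_mean * het_factor(x, kin$A_gamma, lam, kin$phase)
}

# dimensionless modulation g(x) = 1 + A cos(2 pi x / lambda + phase)
het_factor <- function(x, A, lambda, phase = 0) 1 + A * cos(2 * pi * x / lambda + phase)

#' Michaelis-Menten areal surface rate
#'
#' `R = Vmax * Gamma * C_s / (Km + C_s)`: saturable consumption at the
#' catalytic plane, monotone and concave in the surface concentration and
#' bounded by `Vmax * Gamma`.
#'
#' @param C_s Surface concentration (mM), nonnegative.
#' @param Gamma Site density (mol cm^-2 if `Vmax` is per site in s^-1, giving
#'   mol cm^-2 s^-1; any consistent pairing works, e.g. `Gamma = 1` with an
#'   areal `Vmax`).
#' @param Vmax Maximum turnover per site (s^-1).
#' @param Km Michaelis constant (mM).
#' @return Areal rate, same units as `Vmax * Gamma`.
#' @examples
#' mm_surface_rate(2.5, Gamma = 1, Vmax = 1, Km = 2.5)  # half-saturation: 0.5
#' @export
mm_surface_rate <- function(C_s, Gamma, Vmax, Km) {
  if (any(C_s < 0)) stop("surface concentration must be nonnegative", call. = FALSE)
  if (Km <= 0) stop("Km must be strictly positive", call. = FALSE)
  Vmax * Gamma * C_s / (Km + C_s)
}

#' Enzymatic (glucose-oxidase) peroxide production flux
#'
#' First-order areal source: `flux = kGOD * delta_enz * C_glu_s`. The
#' conversion-layer thickness `delta_enz` restores unit consistency of the
#' first-order surface source (a bare `kGOD * C` has units of a volumetric,
#' not areal, rate).
#'
#' @param C_glu_s Surface glucose concentration (mM = mol m^-3).
#' @param kGOD First-order rate constant (s^-1).
#' @param delta_enz Effective conversion-layer thickness (m).
#' @return Areal production flux (mol m^-2 s^-1).
#' @examples
#' god_production_flux(1.7, kGOD = 0.015, delta_enz = 1e-4)  # 2.55e-6
#' @export
god_production_flux <- function(C_glu_s, kGOD, delta_enz) {
  if (any(C_glu_s < 0) || kGOD < 0 || delta_enz < 0)
    stop("god_production_flux: inputs must be nonnegative", call. = FALSE)
  kGOD * delta_enz * C_glu_s
}

#' Dimensionless groups of a scenario
#'
#' * `Da_glu = j_max * H / (D_glu * Km)` -- Damkoehler number of the
#'   glucose-consuming mode (maximal surface rate over diffusive supply);
#' * `Da_p = Da_glu * D_glu / D_h2o2` -- its peroxide-consumption analogue
#'   (same areal rate scale and Km applied to the faster-diffusing species);
#' * `Pi = (lambda_het / H)^2` -- lateral-to-vertical diffusion ratio;
#' * `het_index = A_gamma`; `lam_over_H = lambda_het / H`.
#'
#' @param cfg A [scenario()].
#' @return A list of class `"dimensionless_groups"`.
#' @examples
#' dimensionless_groups(scenario())$Da_glu   # ~8.2 for the calibrated preset
#' @export
dimensionless_groups <- function(cfg) {
  stopifnot(inherits(cfg, "scenario"))
  loh <- cfg$kinetics$lambda_het / cfg$transport$H
  structure(list(Da_glu = cfg$da_glu, Da_p = cfg$da_p,
                 Pi = loh^2, het_index = cfg$kinetics$A_gamma,
                 lam_over_H = loh),
            class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf("Da_glu = %.4g, Da_p = %.4g, Pi = %.3g, lambda/H = %.3g, A = %.2f\n",
              x$Da_glu, x$Da_p, x$Pi, x$lam_over_H, x$het_index))
  invisible(x)
}

#' Pseudo-2D validity report
#'
#' Evaluates the scale-separation criteria under which confining reactions to
#' the `y = 0` plane while resolving only two diffusion directions is
#' accurate: heterogeneity wavelength small against the diffusion layer
#' (`lambda/H < 0.01` for rapid lateral equilibration), small lateral-to-
#' vertical diffusion ratio (`Pi < 0.01`), cluster size small against `H`
#' (`d_pt/H < 0.01`), and surface coverage above 5% (no isolated
#' micro-domains). The regime is `"breakdown"` for `lambda/H >= 0.1`,
#' `"marginal"` for `0.01 <= lambda/H < 0.1`, `"pseudo2D_valid"` below.
#'
#' @param cfg A [scenario()].
#' @param d_pt Catalyst cluster size (m); default 50 nm.
#' @param theta Fractional surface coverage; default 0.25.
#' @return A list of class `"validity_report"` with per-criterion flags.
#' @examples
#' validity_report(scenario(kinetics = surface_kinetics(lambda_het = 200e-9)))
#' @export
validity_report <- function(cfg, d_pt = 50e-9, theta = 0.25) {
  stopifnot(inherits(cfg, "scenario"))
  g <- dimensionless_groups(cfg)
  H <- cfg$transport$H
  flags <- list(
    lateral_equilibration = list(value = g$lam_over_H, threshold = 0.01,
                                 pass = g$lam_over_H < 0.01),
    lateral_diffusion_ratio = list(value = g$Pi, threshold = 0.01,
                                   pass = g$Pi < 0.01),
    cluster_size = list(value = d_pt / H, threshold = 0.01,
                        pass = d_pt / H < 0.01),
    coverage = list(value = theta, threshold = 0.05, pass = theta > 0.05)
  )
  regime <- if (g$lam_over_H >= 0.1) "breakdown"
            else if (g$lam_over_H >= 0.01) "marginal"
            else "pseudo2D_valid"
  structure(list(Pi = g$Pi, lam_over_H = g$lam_over_H, theta_coverage = theta,
                 d_pt = d_pt, flags = flags, regime = regime),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> pseudo-2D scale separation\n")
  for (nm in names(x$flags)) {
    f <- x$flags[[nm]]
    cat(sprintf("  %-24s %-10.3g (threshold %g): %s\n", nm, f$value, f$threshold,
                if (f$pass) "ok" else "FAIL"))
  }
  cat("  regime:", x$regime, "\n")
  invisible(x)
}
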