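# Uniform-surface one-dimensional reference model. The steady state is
# available in closed form (linear profiles, a quadratic flux balance for the
# surface value); the transient shares the implicit BDF2 core on a one-column
# grid so that the uniform 2D limit is an exact consistency check.

# closed-form surface concentration of the uniform steady flux balance
#   (D/H)(C_b - C_s) = j_max C_s / (Km + C_s)
# numerically stable root of  C_s^2 + b C_s - Km C_b = 0, b = Km - C_b + j_max H / D
steady_surface_1d <- function(C_bulk, j_max, Km, D, H) {
  if (j_max == 0) return(C_bulk)
  b <- Km - C_bulk + j_max * H / D
  q <- sqrt(b^2 + 4 * Km * C_bulk)
  Cs <- 2 * Km * C_bulk / (b + q)            # stable for b > 0; equals (-b+q)/2
  # one Newton polish against the flux balance
  for (i in 1:3) {
    f <- D / H * (C_bulk - Cs) - j_max * Cs / (Km + Cs)
    fp <- -D / H - j_max * Km / (Km + Cs)^2
    Cs <- Cs - f / fp
  }
  Cs
}

#' Steady uniform 1D solve
#'
#' Reference model with laterally uniform catalytic activity: the steady
#' glucose profile is exactly linear across the diffusion layer and the
#' surface value solves the Michaelis-Menten flux balance
#' `(D/H)(C_bulk - C_s) = j_max C_s/(Km + C_s)` (closed form plus a Newton
#' polish, residual below 1e-10 relative). In colorimetric mode the peroxide
#' balance `kGOD delta_enz C_glu,s = j_max Cp/(Km + Cp) + (D_p/H) Cp` is
#' solved the same way, giving a linear peroxide profile decaying to the zero
#' top boundary.
#'
#' @param cfg A [scenario()].
#' @param C_bulk Bulk glucose concentration (mM).
#' @param ny Number of output nodes for the (analytic) profiles.
#' @return An object of class `"steady_1d"`: `y`, glucose profile `C`,
#'   surface value `C_s`, surface flux `J` (mol m^-2 s^-1); in colorimetric
#'   mode also `C_p` (peroxide profile) and `C_p_s`.
#' @examples
#' sol <- solve_steady_1d(scenario(), 10)
#' sol$C_s / 10      # 0.17 at the calibrated preset
#' @export
solve_steady_1d <- function(cfg, C_bulk, ny = 160) {
  stopifnot(inherits(cfg, "scenario"), C_bulk > 0)
  tr <- cfg$transport; kin <- cfg$kinetics
  act <- active_rate_params(cfg)
  Cs <- steady_surface_1d(C_bulk, act$j_max, act$Km, tr$D_glu, tr$H)
  y <- seq(0, tr$H, length.out = ny)
  C <- Cs + (C_bulk - Cs) * y / tr$H
  J <- act$j_max * Cs / (act$Km + Cs)
  out <- list(y = y, C = C, C_s = Cs, J = J, C_bulk = C_bulk,
              Da = act$j_max * tr$H / (tr$D_glu * act$Km), species = "glucose")
  if (cfg$mode == "colorimetric") {
    P <- god_production_flux(Cs, kin$kGOD, kin$delta_enz)
    # production balances consumption plus diffusive escape through the layer
    Cp <- if (P == 0) 0 else {
      fb <- function(Cp) P - cfg$j_max * Cp / (kin$Km + Cp) - tr$D_h2o2 / tr$H * Cp
      hi <- P * tr$H / tr$D_h2o2 * (1 + 1e-9)   # pure-escape bound
      stats::uniroot(fb, c(0, hi), tol = 1e-15)$root
    }
    out$C_p_s <- Cp
    out$C_p <- Cp * (1 - y / tr$H)
    out$production <- P
  }
  structure(out, class = "steady_1d")
}

#' @export
print.steady_1d <- function(x, ...) {
  cat(sprintf("<steady_1d> C_bulk = %.4g mM: C_s = %.5g mM (%.4f of bulk), J = %.5g mol m^-2 s^-1\n",
              x$C_bulk, x$C_s, x$C_s / x$C_bulk, x$J))
  if (!is.null(x$C_p_s))
    cat(sprintf("  surface H2O2 = %.5g mM (%.4f of bulk glucose)\n",
                x$C_p_s, x$C_p_s / x$C_bulk))
  invisible(x)
}

#' Transient uniform 1D solve
#'
#' One-column version of the implicit transient integrator (see
#' [solve_transient_2d()] for the initial-condition protocols and the
#' peroxide surface-film capacitance). Used as the reference for response
#' times and for normalizing pseudo-2D transients.
#'
#' @inheritParams solve_transient_2d
#' @param ny,stretch Vertical grid (see [grid_2d()]); the transient default
#'   trades the extreme steady-state refinement for a milder stretch.
#' @return A list of class `"transient_2d"` (one lateral column).
#' @export
solve_transient_1d <- function(cfg, C_bulk_step, ny = 100, stretch = 100,
                               coupled = cfg$mode == "colorimetric",
                               ic = c("step", "bathed"),
                               t_end = cfg$sim_time, times = NULL,
                               n_snapshots = 12) {
  ic <- match.arg(ic)
  grid <- grid_2d(cfg$transport$L, cfg$transport$H, nx = 1, ny = ny,
                  stretch = stretch)
  if (is.null(times)) times <- time_grid(t_end)
  structure(transient_core(cfg, C_bulk_step, grid, uniform = TRUE,
                           coupled = coupled, ic = ic, times = times,
                           n_snapshots = n_snapshots),
            class = c("transient_1d", "transient_2d"))
}
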